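---
title: "Models and methods behind truthemg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind truthemg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(truthemg)
```

## The scientific problem

People judge repeated statements as more likely true than new ones — the
*illusory truth effect* — and the dominant account attributes this to
processing fluency: repeated material is processed more easily, and that
ease is (mis)read as evidence of truth. Fluency and the affective states
accompanying it leave traces in the face. Surface electromyography (EMG)
over three muscles indexes these traces: *corrugator supercilii* (brow
furrowing; negative affect and mental effort), *zygomaticus major*
(mouth-corner raising; positive affect) and *frontalis* (brow raising;
novelty). `truthemg` implements a complete, testable pipeline for this kind
of experiment: a synthetic-data generator with known ground truth, the
standard EMG conditioning chain, trial-wise burst/feature extraction, and a
multilevel inference layer with bootstrap mediation.

The design emulated throughout is a two-session repetition paradigm: an
exposure phase of 72 statements (the first and last 6 are primacy/recency
buffers, never repeated), then two judgment phases — 10 minutes and 1 week
after exposure — each presenting 30 new and 30 repeated statements in
random order while three-channel EMG is recorded at 1 kHz. Participants
judge each statement true or false and rate their confidence (1–6).

## The generative model

`generate_design()` builds the statement bookkeeping (per-subject exposure
lists, disjoint repeated sets across phases, randomized orders, a 50/50
true/false split). `simulate_behavior()` then draws, per trial $i$ of
subject $j$ in phase $p$ (rep $=1$ for repeated statements):

* latent corrugator activation (log-feature units):
  $L_{ij} = \mu_L + u_j + \delta_{L,p}\,\mathrm{rep} + \epsilon_{ij}$,
  with $u_j \sim N(0, \tau_L^2)$, $\epsilon_{ij} \sim N(0, \sigma_L^2)$;
* log response time (seconds):
  $\log T_{ij} = \mu_T + v_j + \delta_{T,p}\,\mathrm{rep} + e_{ij}$
  (log-normal RTs: positive and right-skewed, as judgment latencies are);
* judgment: $Y_{ij} \sim \mathrm{Bernoulli}\big(\mathrm{logit}^{-1}(\beta_0
  + w_j + \beta_{\mathrm{rep},p}\,\mathrm{rep} + \beta_M (L_{ij} -
  \mu_L))\big)$.

The single latent $L_{ij}$ feeds both the corrugator burst amplitude (via
`simulate_emg()`) and the judgment logit. This is the minimal structure
that makes *partial mediation* — repetition relaxes the corrugator, and
corrugator relaxation predicts "true" judgments — a recoverable ground
truth rather than an emergent accident.

### Default effect sizes (the stated world)

Defaults were fixed once, to mirror the direction and scale of published
repetition effects, and are not tuned thereafter:

| parameter | default | meaning |
|---|---|---|
| `judgment_rep_logodds` | (0.924, 0.320) | repetition log-odds on "true", phase 1 / phase 2 |
| `latent_rep_delta` | (−0.233, 0.006) | repetition effect on log corrugator feature |
| `judgment_latent_weight` | −0.135 | logit weight of centered latent activation |
| `rt_rep_delta` | (−0.10, −0.005) | repetition effect on log RT |
| `latent_mean`, `latent_subject_sd`, `latent_noise_sd` | 2.8, 0.7, 0.9 | latent location and spread |
| `judgment_subject_sd` | 0.5 | between-subject logit SD |

Raw-signal amplitudes have no published reference statistics, so the
microvolt-scale defaults (8/5/6 µV mean bursts, 1.5 µV noise floor,
burst onset 150–400 ms after stimulus onset, duration 55–85% of the RT)
are plausibility choices for facial surface EMG, declared here once. They
are *not* matched to any real recording, and tests treat them accordingly
(directional and calibration checks, not amplitude reproduction).

### What the generator does not emulate

No electrode artifacts, blinks, cross-talk between channels, 16-bit
quantization, or drifting baselines; trials never overlap by construction.
A green end-to-end test therefore establishes that the pipeline implements
its definitions correctly and recovers known effects from clean data — not
that it is robust to every failure mode of real recordings.

## Signal conditioning

The chain is band-pass → notch → rectification → envelope:

* **Band-pass**: Butterworth, 10–400 Hz, 4th-order analog prototype. The
  filter family is a documented choice (maximally flat passband — the
  standard for surface EMG), not a given.
* **Notch**: second-order IIR at 50 Hz with quality factor 30, narrow
  enough to leave 45/55 Hz essentially untouched.
* **Phase handling**: both filters run forward–backward (zero phase). The
  analysis is offline, and zero-phase filtering keeps burst latencies
  unshifted at the cost of doubling the effective attenuation order. Edge
  transients are suppressed by odd-symmetric padding (600 samples for the
  band-pass; `3·fs·q/freq` samples for the notch, matching its longer
  ringing).
* **Envelope**: centered moving average of the rectified signal over 30 ms;
  at the edges the window shrinks to the available samples (no systematic
  onset bias, output length preserved).

Because no DSP package is available as a dependency, the IIR design
(analog prototype → lowpass-to-bandpass transform → bilinear transform →
second-order sections) is implemented in the package and verified in the
test suite by two independent routes: the closed-form frequency response
evaluated on the unit circle, and empirical steady-state amplitudes of
filtered sines.

## Activity extraction

Per trial, the baseline is the 1000 ms window ending at stimulus onset
(the fixation period) and the activity window runs from stimulus onset to
the response keypress. The activity threshold is the baseline envelope's
**median plus one sample standard deviation** (n−1 denominator, the
default of mainstream statistical software). Samples **strictly above**
the threshold form maximal runs; runs shorter than 50 ms are discarded and
gaps are never merged. Strict inequality makes the constant-baseline case
unambiguous (a flat baseline yields zero active samples).

The per-trial feature is the area under the **envelope** over active
samples (rectangle rule, µV·ms), divided by the trial's response time in
ms — so AUC/RT is in microvolts. Integrating the envelope rather than the
raw rectified signal is a deliberate resolution of an ambiguity: the
threshold and the activity definition both operate on the envelope, and
the envelope is itself the smoothed rectified signal, so the envelope is
the consistent integrand. Since a moving average preserves integrals away
from window edges, the two readings differ only at run boundaries.

One numerical caveat established during testing: a mathematically
rectangular burst has genuine out-of-band energy at its edges, which the
10–400 Hz passband reshapes (about +2.5% rectified area for a 200 ms
burst). The chain-transparency fixture therefore uses a constant-amplitude
burst with 30 ms cosine on/off ramps — physiologically realistic, and the
chain is then integral-transparent to 0.01%.

## Feature assembly

Relativized AUCs get `ln(x + 1)` (natural log; the +1 keeps zero-activity
trials defined). Outliers are values lying strictly more than 3
interquartile ranges below Q1 or above Q3 of the logarithmized
distribution, computed **per muscle, pooled across subjects and phases**
(the distributions are muscle-specific; the grouping is configurable to
per-muscle-per-phase). Outlier rows are flagged, not dropped: models with
EMG outcomes or predictors exclude them (their wide-format values are
`NA`), behavior-only models keep all trials — outlier screening is a
property of the EMG distributions, not of the behavior.

Predictor codings are fixed: repetition dummy-coded with *new* as
reference; judgment phase −0.5/+0.5 (first/second); veridicality −0.5/+0.5
(factually incorrect/correct); judgment 0/1 (false/true); RT in seconds.
Response times enter their models untransformed (in seconds) by default —
no transform is prescribed for them, and the `log_rt` switch provides the
alternative.

## Inference

All models are random-intercept-only (subject) and fit by **maximum
likelihood**, never REML, so AIC/BIC and likelihoods are comparable across
nested fits. The logistic family integrates the random intercept out by
adaptive Gauss–Hermite quadrature; the default single node is the Laplace
approximation, and the test suite verifies that 1-node and 21-node fits
agree to < 0.02 at analysis scale. Fitting is delegated to lme4 — the
field-standard engine — behind this package's contracts: convergence and
separation (`|b| > 15`) surfaced as flags, singular boundary fits treated
as legitimate ML solutions, and `pin_variance_zero = TRUE` available to
fit the exact zero-variance boundary model (which *is* OLS / plain
logistic regression; the tests compare it against hand-written
normal-equation and IRLS oracles).

Fixed-effect p-values are Wald: normal approximation of the t statistic
for Gaussian models, Wald z for logistic models. This approximates
finite-df corrections well at the cluster counts targeted here (tens of
subjects, thousands of trials) and is recorded in every fit object rather
than hidden.

### Mediation

`mediate_effect()` estimates the average causal mediation effect (ACME)
and average direct effect (ADE) in the potential-outcomes framework:
counterfactual mediator values are drawn under treatment and control
(conditional means, subject intercepts included, plus Gaussian residual
draws), predicted outcomes are contrasted, and effects are averaged over
both treatment regimes. Uncertainty comes from resampling **subjects**
with replacement — the cluster is the exchangeable unit in a
within-subject design — with percentile intervals and a two-sided
bootstrap p-value. Resampled subjects get fresh ids so a twice-drawn
subject contributes two independent clusters. In the all-Gaussian case the
estimator reduces exactly to the product of path coefficients, which the
tests exploit as an oracle.

## Numerical and scaling choices

* Determinism: every stochastic stage takes a seed; stream seeds for
  sub-stages are derived with a fixed congruential map, and the caller's
  RNG state is always restored.
* Convergence: lme4 defaults (relative tolerances around 1e-8 on the
  deviance) are used unchanged and recorded via the engine object.
* Simulation studies in the test suite run at the stated scaled-down
  designs (e.g. 200 replicates of 40 subjects × 60 trials for parameter
  recovery); the mediation calibration checks are additionally scaled
  (40 null replicates × 120 bootstrap draws; 6 recovery replicates at 50
  subjects) to stay inside a desk-scale compute budget, with binomial
  acceptance bands widened accordingly. Replicate counts are fixed in the
  tests and were not adjusted after observing outcomes.
* Large calibration studies use `simulate_features()`, which emits the
  analysis table directly from the generative model instead of rendering
  1 kHz raw signals — rendering hundreds of full-signal datasets is not
  affordable, and the signal route is validated separately by closed-form
  fixtures and a small end-to-end consistency test.

## Known limitations

* Random intercepts only; crossed random effects for statements are out of
  scope, as are REML, Bayesian fitting and multiplicity corrections.
* The generator's microvolt scale is conventional, not estimated from
  data; absolute amplitudes carry no evidential weight.
* Percentile bootstrap intervals with few clusters (≲ 15 subjects)
  undercover somewhat; the tiny profile is a smoke test, not an analysis
  setting.
* Confidence ratings are generated but never analyzed.
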