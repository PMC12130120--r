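# Synthetic experiments with known ground truth.
#
# The generator emulates a two-session repetition/truth-judgment design:
# an exposure phase of 72 statements (6 + 6 primacy/recency buffers that are
# never repeated), then two judgment phases (10 minutes and 1 week after
# exposure) of 30 new + 30 repeated statements each, shown in random order.
# Three facial muscles are recorded at 1 kHz: corrugator supercilii,
# zygomaticus major, frontalis.
#
# A single per-trial latent "corrugator activation" links the three outcome
# families: it feeds the corrugator burst amplitude and, weighted, the
# judgment logit. That makes partial mediation
# (repetition -> corrugator relaxation -> "true" judgment) a recoverable
# ground truth rather than an emergent accident.

MUSCLES <- c("corrugator", "zygomaticus", "frontalis")

#' Experiment design configuration
#'
#' Sizes and timing constants of the simulated experiment. Defaults encode
#' the full design: 75 subjects, two judgment phases with 30 new + 30
#' repeated statements each, a 72-statement exposure list whose first and
#' last 6 items are primacy/recency buffers excluded from repetition, a 50/50
#' split of factually true and false statements, 1 kHz sampling and a
#' 1000 ms pre-stimulus fixation that doubles as the EMG baseline window.
#'
#' @param n_subjects number of simulated participants.
#' @param n_new_per_phase,n_repeated_per_phase trials per judgment phase.
#' @param n_exposure exposure-phase list length, including buffers.
#' @param n_buffer buffer statements at each end of the exposure list
#'   (never eligible for repetition).
#' @param veridicality_split fraction of factually true statements.
#' @param sampling_rate EMG sampling rate in Hz.
#' @param fixation_ms fixation-cross duration before each statement (ms);
#'   also the baseline period used for activity thresholds.
#' @param intertrial_ms simulated pause after the response (confidence
#'   rating and inter-trial interval) before the next fixation (ms).
#' @return a `design_config` list, validated.
#' @export
design_config <- function(n_subjects = 75,
                          n_new_per_phase = 30,
                          n_repeated_per_phase = 30,
                          n_exposure = 72,
                          n_buffer = 6,
                          veridicality_split = 0.5,
                          sampling_rate = 1000,
                          fixation_ms = 1000,
                          intertrial_ms = 1500) {
  check_count(n_subjects, "n_subjects")
  check_count(n_new_per_phase, "n_new_per_phase")
  check_count(n_repeated_per_phase, "n_repeated_per_phase")
  check_count(n_exposure, "n_exposure")
  check_count(n_buffer, "n_buffer", lower = 0L)
  check_number(veridicality_split, "veridicality_split", 0, 1)
  check_number(sampling_rate, "sampling_rate", lower = 1)
  check_number(fixation_ms, "fixation_ms", lower = 1)
  check_number(intertrial_ms, "intertrial_ms", lower = 0)
  n_repeatable <- n_exposure - 2L * n_buffer
  if (n_repeatable < 2L * n_repeated_per_phase) {
    stop2(paste0("design needs %d repeatable exposure statements but only %d",
                 " are available after removing 2 x %d buffers"),
          2L * n_repeated_per_phase, n_repeatable, n_buffer)
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_new_per_phase = as.integer(n_new_per_phase),
    n_repeated_per_phase = as.integer(n_repeated_per_phase),
    n_exposure = as.integer(n_exposure),
    n_buffer = as.integer(n_buffer),
    veridicality_split = veridicality_split,
    sampling_rate = sampling_rate,
    fixation_ms = fixation_ms,
    intertrial_ms = intertrial_ms
  ), class = "design_config")
}

#' Generative effect-size configuration
#'
#' Ground-truth parameters of the simulated behavior and EMG. The defaults
#' qualitatively mirror the direction and scale of published repetition
#' effects: a strong illusory truth effect shortly after exposure that
#' shrinks after a week (repetition log-odds 0.924 vs 0.320), corrugator
#' relaxation for repeated statements that likewise fades (-0.233 vs 0.006
#' on the log-feature scale), and faster judgments for repeated statements.
#' Raw signal amplitudes (microvolts) are plausibility choices, not values
#' estimated from any real recording.
#'
#' @param latent_mean,latent_subject_sd,latent_noise_sd mean, between-subject
#'   SD and trial-level SD of the latent corrugator activation on the
#'   log-feature scale (ln(AUC/RT + 1) units).
#' @param latent_rep_delta length-2 numeric: additive repetition effect on
#'   the latent activation in phase 1 and phase 2.
#' @param rt_meanlog,rt_subject_sd,rt_sdlog log-normal response-time model:
#'   population location (log seconds), between-subject SD and residual SD
#'   on the log scale.
#' @param rt_rep_delta length-2 numeric: repetition effect on log RT per phase.
#' @param judgment_intercept logistic intercept of P("true").
#' @param judgment_rep_logodds length-2 numeric: repetition log-odds ratio on
#'   "true" judgments per phase.
#' @param judgment_latent_weight weight of the (centered) latent corrugator
#'   activation in the judgment logit; negative = relaxation favors "true".
#' @param judgment_subject_sd SD of the subject random intercept on the logit.
#' @param burst_base,burst_subject_sd named per-muscle mean burst amplitude
#'   (microvolts) and its between-subject SD.
#' @param burst_rep_delta 2 x 3 matrix (phase x muscle) of additive
#'   repetition effects on burst amplitude (microvolts).
#' @param burst_latent_gain microvolts of corrugator burst amplitude per unit
#'   of (centered) latent activation.
#' @param noise_floor_sd standard deviation of the band-limited baseline
#'   noise (microvolts).
#' @param burst_onset_ms length-2 range: uniform burst-onset delay after
#'   stimulus onset (ms).
#' @param burst_frac length-2 range: burst duration as a fraction of the
#'   trial's response time.
#' @param burst_min_ms minimum burst duration (ms); must be detectable, so
#'   at least the 50 ms activity rule.
#' @param burst_shape `"hanning"` (tapered, default) or `"rect"` (flat
#'   plateau; with a sine carrier this yields closed-form features).
#' @param carrier `"noise"` (band-limited 20--250 Hz white noise, default)
#'   or `"sine"` (pure tone at `carrier_freq`, for analytic fixtures).
#' @param carrier_freq carrier tone frequency (Hz) when `carrier = "sine"`.
#' @return an `effect_config` list, validated.
#' @export
effect_config <- function(latent_mean = 2.8,
                          latent_subject_sd = 0.7,
                          latent_noise_sd = 0.9,
                          latent_rep_delta = c(-0.233, 0.006),
                          rt_meanlog = log(2.2),
                          rt_subject_sd = 0.15,
                          rt_sdlog = 0.35,
                          rt_rep_delta = c(-0.10, -0.005),
                          judgment_intercept = 0.20,
                          judgment_rep_logodds = c(0.924, 0.320),
                          judgment_latent_weight = -0.135,
                          judgment_subject_sd = 0.5,
                          burst_base = c(corrugator = 8, zygomaticus = 5,
                                         frontalis = 6),
                          burst_subject_sd = c(corrugator = 2,
                                               zygomaticus = 1.5,
                                               frontalis = 1.5),
                          burst_rep_delta = rbind(phase1 = c(-1.5, -0.4, -0.8),
                                                  phase2 = c(0, -0.2, -0.3)),
                          burst_latent_gain = 1.5,
                          noise_floor_sd = 1.5,
                          burst_onset_ms = c(150, 400),
                          burst_frac = c(0.55, 0.85),
                          burst_min_ms = 120,
                          burst_shape = c("hanning", "rect"),
                          carrier = c("noise", "sine"),
                          carrier_freq = 100) {
  burst_shape <- match.arg(burst_shape)
  carrier <- match.arg(carrier)
  for (nm in c("latent_mean", "latent_subject_sd", "latent_noise_sd",
               "rt_meanlog", "rt_subject_sd", "rt_sdlog",
               "judgment_intercept", "judgment_latent_weight",
               "judgment_subject_sd", "burst_latent_gain", "noise_floor_sd",
               "burst_min_ms", "carrier_freq")) {
    check_number(get(nm), nm)
  }
  for (nm in c("latent_subject_sd", "latent_noise_sd", "rt_subject_sd",
               "rt_sdlog", "judgment_subject_sd", "noise_floor_sd")) {
    if (get(nm) < 0) stop2("`%s` must be non-negative", nm)
  }
  if (length(latent_rep_delta) != 2L || length(rt_rep_delta) != 2L ||
      length(judgment_rep_logodds) != 2L) {
    stop2("per-phase parameters must have length 2 (phase 1, phase 2)")
  }
  check_finite_vector(c(latent_rep_delta, rt_rep_delta, judgment_rep_logodds),
                      "per-phase effect parameters")
  if (any(burst_base < 0) || any(burst_subject_sd < 0)) {
    stop2("burst amplitudes and SDs must be non-negative")
  }
  burst_rep_delta <- matrix(as.numeric(burst_rep_delta), nrow = 2,
                            dimnames = list(c("phase1", "phase2"), MUSCLES))
  if (burst_min_ms < 50) {
    stop2("`burst_min_ms` must be >= 50 ms so bursts satisfy the minimum detectable duration")
  }
  if (length(burst_onset_ms) != 2L || length(burst_frac) != 2L ||
      burst_onset_ms[1] > burst_onset_ms[2] || burst_frac[1] > burst_frac[2]) {
    stop2("`burst_onset_ms` and `burst_frac` must be increasing length-2 ranges")
  }
  structure(list(
    latent_mean = latent_mean, latent_subject_sd = latent_subject_sd,
    latent_noise_sd = latent_noise_sd,
    latent_rep_delta = as.numeric(latent_rep_delta),
    rt_meanlog = rt_meanlog, rt_subject_sd = rt_subject_sd,
    rt_sdlog = rt_sdlog, rt_rep_delta = as.numeric(rt_rep_delta),
    judgment_intercept = judgment_intercept,
    judgment_rep_logodds = as.numeric(judgment_rep_logodds),
    judgment_latent_weight = judgment_latent_weight,
    judgment_subject_sd = judgment_subject_sd,
    burst_base = setNames(as.numeric(burst_base), MUSCLES),
    burst_subject_sd = setNames(as.numeric(burst_subject_sd), MUSCLES),
    burst_rep_delta = burst_rep_delta,
    burst_latent_gain = burst_latent_gain,
    noise_floor_sd = noise_floor_sd,
    burst_onset_ms = as.numeric(burst_onset_ms),
    burst_frac = as.numeric(burst_frac),
    burst_min_ms = burst_min_ms,
    burst_shape = burst_shape, carrier = carrier, carrier_freq = carrier_freq
  ), class = "effect_config")
}

#' Generate the trial-level experimental design
#'
#' Builds the per-subject event table skeleton: statement assignment,
#' repetition status, veridicality and randomized trial order for both
#' judgment phases. Behavioral fields (`stimulus_onset`, `response_onset`,
#' `rt_ms`, `judgment`, `confidence`) are left `NA` and filled by
#' [simulate_behavior()].
#'
#' Statement bookkeeping mirrors the two-session design: each subject sees
#' `n_exposure` statements in the exposure phase, of which the first and
#' last `n_buffer` are primacy/recency buffers that are never repeated.
#' Phase-1 repeated items are drawn from the non-buffer exposure items;
#' phase-2 repeated items are the exposure items *not* used in phase 1, so
#' the two phases never share a repeated statement. New items are fresh ids
#' in every phase.
#'
#' @param config a [design_config()].
#' @param seed integer seed; the same `(config, seed)` pair always yields an
#'   identical table.
#' @return a data.frame (one row per judgment trial) with columns
#'   `subject_id`, `phase` (1 = 10-minute interval, 2 = 1-week interval),
#'   `trial_index`, `statement_id`, `repetition_status`
#'   (`"new"`/`"repeated"`), `veridicality` (`"false_fact"`/`"true_fact"`)
#'   and `NA` behavioral columns. The exposure lists are attached as
#'   attribute `"exposure"` (a data.frame with `subject_id`, `statement_id`,
#'   `is_buffer`).
#' @export
generate_design <- function(config = design_config(), seed = 1L) {
  stopifnot(inherits(config, "design_config"))
  with_seed(seed, {
    per_subj <- lapply(seq_len(config$n_subjects), function(s) {
      generate_subject_design(config, s)
    })
  })
  events <- do.call(rbind, lapply(per_subj, `[[`, "events"))
  exposure <- do.call(rbind, lapply(per_subj, `[[`, "exposure"))
  rownames(events) <- NULL
  structure(events, exposure = exposure,
            config = config, seed = as.integer(seed))
}

generate_subject_design <- function(config, subject_id) {
  nb <- config$n_buffer
  nrep <- config$n_repeated_per_phase
  nnew <- config$n_new_per_phase
  # statement id space, per subject: exposure items then fresh new items
  exp_ids <- sprintf("s%02d_exp%03d", subject_id, seq_len(config$n_exposure))
  is_buffer <- seq_len(config$n_exposure) <= nb |
    seq_len(config$n_exposure) > config$n_exposure - nb
  repeatable <- exp_ids[!is_buffer]
  # random split of repeatable items between the two phases
  p1_rep <- sample(repeatable, nrep)
  p2_rep <- sample(setdiff(repeatable, p1_rep), nrep)
  phase_tab <- function(phase, rep_ids) {
    new_ids <- sprintf("s%02d_p%d_new%03d", subject_id, phase, seq_len(nnew))
    ids <- c(new_ids, rep_ids)
    status <- rep(c("new", "repeated"), c(nnew, nrep))
    n <- length(ids)
    n_true <- round(config$veridicality_split * n)
    verid <- sample(rep(c("true_fact", "false_fact"),
                        c(n_true, n - n_true)))
    ord <- sample.int(n)
    data.frame(
      subject_id = subject_id, phase = phase,
      trial_index = seq_len(n),
      statement_id = ids[ord],
      repetition_status = status[ord],
      veridicality = verid[ord],
      stimulus_onset = NA_integer_, response_onset = NA_integer_,
      rt_ms = NA_real_, judgment = NA_integer_, confidence = NA_integer_,
      latent_corrugator = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  list(events = rbind(phase_tab(1L, p1_rep), phase_tab(2L, p2_rep)),
       exposure = data.frame(subject_id = subject_id, statement_id = exp_ids,
                             is_buffer = is_buffer,
                             stringsAsFactors = FALSE))
}

phase_index <- function(phase) ifelse(phase == 1L, 1L, 2L)

#' Simulate behavior and the latent mediator
#'
#' Completes a design table from [generate_design()] with response times,
#' truth judgments, confidence ratings, the latent corrugator activation and
#' a non-overlapping within-session timeline of stimulus/response onsets.
#'
#' The generative model, per trial \eqn{i} of subject \eqn{j} in phase
#' \eqn{p} (rep = 1 for repeated statements):
#' \itemize{
#'   \item latent activation
#'     \eqn{L_{ij} = \mu_L + u_j + \delta_{L,p}\,rep + \epsilon_{ij}},
#'   \item log RT (seconds)
#'     \eqn{\log T_{ij} = \mu_T + v_j + \delta_{T,p}\,rep + e_{ij}},
#'   \item judgment
#'     \eqn{Y_{ij} \sim Bernoulli(logit^{-1}(\beta_0 + w_j +
#'       \beta_{rep,p}\,rep + \beta_M (L_{ij} - \mu_L)))}.
#' }
#' The latent value is stored so that [simulate_emg()] can key the
#' corrugator burst amplitude to it, making mediation recoverable.
#'
#' @param design event table from [generate_design()].
#' @param effects an [effect_config()].
#' @param seed integer seed.
#' @return the completed event table; sampling-rate/fixation settings are
#'   carried over from the design attributes.
#' @export
simulate_behavior <- function(design, effects = effect_config(), seed = 1L) {
  stopifnot(inherits(effects, "effect_config"))
  config <- attr(design, "config")
  if (is.null(config)) stop2("`design` must come from generate_design()")
  fs <- config$sampling_rate
  fix_n <- round(config$fixation_ms * fs / 1000)
  iti_n <- round(config$intertrial_ms * fs / 1000)
  ev <- as.data.frame(design)
  subjects <- unique(ev$subject_id)
  with_seed(derive_seed(seed, 2L), {
    u_lat <- rnorm(length(subjects), 0, effects$latent_subject_sd)
    u_rt <- rnorm(length(subjects), 0, effects$rt_subject_sd)
    u_jdg <- rnorm(length(subjects), 0, effects$judgment_subject_sd)
    names(u_lat) <- names(u_rt) <- names(u_jdg) <- subjects
    rep01 <- as.integer(ev$repetition_status == "repeated")
    ph <- phase_index(ev$phase)
    n <- nrow(ev)
    lat <- effects$latent_mean + u_lat[as.character(ev$subject_id)] +
      effects$latent_rep_delta[ph] * rep01 +
      rnorm(n, 0, effects$latent_noise_sd)
    log_rt <- effects$rt_meanlog + u_rt[as.character(ev$subject_id)] +
      effects$rt_rep_delta[ph] * rep01 + rnorm(n, 0, effects$rt_sdlog)
    rt_s <- exp(log_rt)
    eta <- effects$judgment_intercept + u_jdg[as.character(ev$subject_id)] +
      effects$judgment_rep_logodds[ph] * rep01 +
      effects$judgment_latent_weight * (lat - effects$latent_mean)
    if (any(!is.finite(eta)) || any(!is.finite(rt_s))) {
      stop2("non-finite values in generative model; check effect_config")
    }
    judgment <- rbinom(n, 1L, plogis(eta))
    # confidence loosely tied to |eta|: more extreme logits -> more certain
    conf_p <- plogis(abs(eta) - 1)
    confidence <- pmin(6L, pmax(1L, 1L + rbinom(n, 5L, conf_p)))
  })
  ev$latent_corrugator <- as.numeric(lat)
  rt_samp <- pmax(round(rt_s * fs), round(0.3 * fs)) # floor RT at 300 ms
  ev$judgment <- as.integer(judgment)
  ev$confidence <- as.integer(confidence)
  # lay out a non-overlapping timeline per subject-phase session
  for (s in subjects) {
    for (p in unique(ev$phase)) {
      idx <- which(ev$subject_id == s & ev$phase == p)
      idx <- idx[order(ev$trial_index[idx])]
      t <- fix_n # head-room so the first baseline fits
      for (i in idx) {
        onset <- t + fix_n
        resp <- onset + rt_samp[i]
        ev$stimulus_onset[i] <- onset
        ev$response_onset[i] <- resp
        t <- resp + iti_n
      }
    }
  }
  ev$rt_ms <- (ev$response_onset - ev$stimulus_onset) / fs * 1000
  structure(ev, config = config, effects = effects,
            seed = as.integer(seed))
}

# Hanning (raised-cosine) window of length n.
hanning_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# Band-limited (20-250 Hz) unit-variance noise used both as noise floor and
# as burst carrier; spectrum sits inside the 10-400 Hz analysis passband.
bandlimited_noise <- function(n, fs) {
  if (n < 16L) return(rnorm(n))
  x <- emg_bandpass(rnorm(n), fs, low = 20, high = min(250, fs / 2.5),
                    order = 2, padlen = min(n - 1L, 200L))
  s <- sd(x)
  if (s > 0) x / s else x
}

#' Simulate raw multi-channel EMG recordings
#'
#' Renders one continuous three-channel recording (microvolts) per
#' subject-phase session from a completed event table. Each channel is
#' band-limited Gaussian noise (the baseline floor) plus one burst per
#' trial: an amplitude envelope (Hanning-tapered by default) modulating a
#' carrier, starting `burst_onset_ms` after stimulus onset and lasting a
#' fraction of the response time. Inter-trial segments contain noise only,
#' so the pre-stimulus fixation windows are valid baselines.
#'
#' Burst amplitude for muscle \eqn{m} is
#' \eqn{A = \max(0, base_m + u_{jm} + \Delta_{pm}\,rep + g\,(L - \mu_L))}
#' where the latent term \eqn{g (L - \mu_L)} applies to the corrugator
#' channel only.
#'
#' @param events completed event table from [simulate_behavior()].
#' @param effects an [effect_config()]; must match the one used for behavior
#'   (the latent values are read from the table).
#' @param seed integer seed.
#' @return a list of `emg_recording` objects (fields `subject_id`, `phase`,
#'   `channels`, `signal` — an n x 3 matrix in microvolts — and
#'   `sampling_rate`), one per subject-phase, named `"sub<j>_phase<p>"`.
#' @export
simulate_emg <- function(events, effects = effect_config(), seed = 1L) {
  stopifnot(inherits(effects, "effect_config"))
  config <- attr(events, "config")
  if (is.null(config) || anyNA(events$response_onset)) {
    stop2("`events` must be a completed table from simulate_behavior()")
  }
  fs <- config$sampling_rate
  ev <- as.data.frame(events)
  sessions <- unique(ev[, c("subject_id", "phase")])
  recs <- vector("list", nrow(sessions))
  names(recs) <- sprintf("sub%d_phase%d", sessions$subject_id, sessions$phase)
  subjects <- unique(ev$subject_id)
  with_seed(derive_seed(seed, 3L), {
    u_amp <- vapply(MUSCLES, function(m) {
      rnorm(length(subjects), 0, effects$burst_subject_sd[[m]])
    }, numeric(length(subjects)))
    u_amp <- matrix(u_amp, nrow = length(subjects),
                    dimnames = list(subjects, MUSCLES))
    for (k in seq_len(nrow(sessions))) {
      s <- sessions$subject_id[k]
      p <- sessions$phase[k]
      tr <- ev[ev$subject_id == s & ev$phase == p, ]
      tr <- tr[order(tr$trial_index), ]
      if (any(diff(tr$stimulus_onset) <= 0) ||
          any(tr$stimulus_onset[-1] < tr$response_onset[-nrow(tr)])) {
        stop2("overlapping trial windows for subject %s phase %s", s, p)
      }
      n <- max(tr$response_onset) + round(fs) # 1 s tail
      sig <- matrix(0, nrow = n, ncol = length(MUSCLES),
                    dimnames = list(NULL, MUSCLES))
      ph <- phase_index(p)
      for (m in seq_along(MUSCLES)) {
        mus <- MUSCLES[m]
        ch <- if (effects$noise_floor_sd > 0) {
          effects$noise_floor_sd * bandlimited_noise(n, fs)
        } else {
          numeric(n)
        }
        for (i in seq_len(nrow(tr))) {
          rep01 <- as.integer(tr$repetition_status[i] == "repeated")
          amp <- effects$burst_base[[mus]] + u_amp[as.character(s), mus] +
            effects$burst_rep_delta[ph, mus] * rep01
          if (mus == "corrugator") {
            amp <- amp + effects$burst_latent_gain *
              (tr$latent_corrugator[i] - effects$latent_mean)
          }
          amp <- max(0, amp)
          if (amp == 0) next
          onset_ms <- runif(1, effects$burst_onset_ms[1],
                            effects$burst_onset_ms[2])
          frac <- runif(1, effects$burst_frac[1], effects$burst_frac[2])
          dur_ms <- max(effects$burst_min_ms, frac * tr$rt_ms[i])
          b0 <- tr$stimulus_onset[i] + round(onset_ms * fs / 1000)
          b1 <- min(b0 + round(dur_ms * fs / 1000) - 1L,
                    tr$response_onset[i] - 1L, n)
          if (b1 <= b0) next
          len <- b1 - b0 + 1L
          shape <- switch(effects$burst_shape,
                          hanning = hanning_window(len),
                          rect = rep(1, len))
          car <- switch(effects$carrier,
                        noise = bandlimited_noise(len, fs),
                        sine = sin(2 * pi * effects$carrier_freq *
                                     seq_len(len) / fs))
          ch[b0:b1] <- ch[b0:b1] + amp * shape * car
        }
        sig[, m] <- ch
      }
      recs[[k]] <- structure(list(subject_id = s, phase = p,
                                  channels = MUSCLES, signal = sig,
                                  sampling_rate = fs),
                             class = "emg_recording")
    }
  })
  recs
}

#' Simulate a complete experiment
#'
#' Convenience wrapper chaining [generate_design()], [simulate_behavior()]
#' and (optionally) [simulate_emg()].
#'
#' @param config a [design_config()].
#' @param effects an [effect_config()].
#' @param seed integer seed controlling every stage.
#' @param signals if `FALSE`, skip raw-signal rendering and return only the
#'   completed event table (feature-level studies).
#' @return list with `events` and (if requested) `recordings`.
#' @export
simulate_experiment <- function(config = design_config(),
                                effects = effect_config(),
                                seed = 1L, signals = TRUE) {
  design <- generate_design(config, seed = seed)
  events <- simulate_behavior(design, effects, seed = seed)
  out <- list(events = events)
  if (signals) out$recordings <- simulate_emg(events, effects, seed = seed)
  out
}

#' Simulate an analysis-ready feature table without raw signals
#'
#' Emits the long-format feature table the extraction chain would produce,
#' directly from the generative model: the latent corrugator activation *is*
#' the corrugator `log_rel_auc`, and the other two muscles get independent
#' activations with their own repetition effects (scaled from the burst
#' amplitude deltas). This feature-level shortcut is what makes large
#' calibration studies (hundreds of replicate fits) affordable; the raw
#' signal route is validated separately against it.
#'
#' @inheritParams simulate_experiment
#' @return a feature table as produced by [assemble_features()] (already
#'   coded, `outlier = FALSE` everywhere).
#' @export
simulate_features <- function(config = design_config(),
                              effects = effect_config(),
                              seed = 1L) {
  design <- generate_design(config, seed = seed)
  events <- simulate_behavior(design, effects, seed = seed)
  ev <- as.data.frame(events)
  n <- nrow(ev)
  ph <- phase_index(ev$phase)
  rep01 <- as.integer(ev$repetition_status == "repeated")
  # side-muscle activations: same variance structure as the corrugator
  # latent, repetition deltas scaled from the burst-amplitude ratios
  with_seed(derive_seed(seed, 4L), {
    subjects <- unique(ev$subject_id)
    vals <- matrix(NA_real_, n, 3, dimnames = list(NULL, MUSCLES))
    vals[, "corrugator"] <- ev$latent_corrugator
    for (mus in c("zygomaticus", "frontalis")) {
      u <- setNames(rnorm(length(subjects), 0, effects$latent_subject_sd),
                    subjects)
      scale_m <- effects$burst_rep_delta[, mus] /
        ifelse(effects$burst_rep_delta[, "corrugator"] == 0, 1,
               effects$burst_rep_delta[, "corrugator"])
      delta_m <- effects$latent_rep_delta * scale_m
      vals[, mus] <- effects$latent_mean * 0.7 +
        u[as.character(ev$subject_id)] + delta_m[ph] * rep01 +
        rnorm(n, 0, effects$latent_noise_sd)
    }
  })
  long <- do.call(rbind, lapply(MUSCLES, function(mus) {
    data.frame(ev[, c("subject_id", "phase", "trial_index",
                      "repetition_status", "veridicality", "rt_ms",
                      "judgment", "confidence")],
               muscle = mus, log_rel_auc = pmax(0, vals[, mus]),
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  finish_feature_table(long)
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> subject %s, phase %s: %d samples x %d channels @ %g Hz\n",
              x$subject_id, x$phase, nrow(x$signal), ncol(x$signal),
              x$sampling_rate))
  invisible(x)
}
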