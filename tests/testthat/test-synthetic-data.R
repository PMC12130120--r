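# Design generation, behavior simulation, raw-signal rendering.

test_that("default design has the full trial structure", {
  # the default (full-profile) configuration is the 75-subject design
  expect_equal(design_config()$n_subjects, 75L)
  expect_equal(run_config(tempdir(), profile = "full")$design$n_subjects, 75L)
  des <- generate_design(design_config(n_subjects = 3), seed = 5)
  one <- des[des$subject_id == 1 & des$phase == 1, ]
  expect_equal(sum(one$repetition_status == "repeated"), 30L)
  expect_equal(sum(one$repetition_status == "new"), 30L)
  expect_equal(nrow(one), 60L)
  # both phases for every subject
  expect_equal(nrow(des), 3 * 2 * 60)
  # veridicality split is half/half
  expect_equal(sum(one$veridicality == "true_fact"), 30L)
  # exposure list: 72 statements, 6 + 6 buffers
  expo <- attr(des, "exposure")
  e1 <- expo[expo$subject_id == 1, ]
  expect_equal(nrow(e1), 72L)
  expect_equal(sum(e1$is_buffer), 12L)
})

test_that("design generation is deterministic and phases share no repeated statement", {
  cfg <- design_config(n_subjects = 4, n_new_per_phase = 2,
                       n_repeated_per_phase = 2, n_exposure = 16,
                       n_buffer = 6)
  d1 <- generate_design(cfg, seed = 42)
  d2 <- generate_design(cfg, seed = 42)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_false(identical(as.data.frame(d1),
                         as.data.frame(generate_design(cfg, seed = 43))))
  # brute-force id bookkeeping per subject
  expo <- attr(d1, "exposure")
  for (s in unique(d1$subject_id)) {
    ds <- d1[d1$subject_id == s, ]
    expect_equal(sum(ds$phase == 1), 4L)
    rep1 <- ds$statement_id[ds$phase == 1 & ds$repetition_status == "repeated"]
    rep2 <- ds$statement_id[ds$phase == 2 & ds$repetition_status == "repeated"]
    expect_length(intersect(rep1, rep2), 0)
    allowed <- expo$statement_id[expo$subject_id == s & !expo$is_buffer]
    expect_true(all(c(rep1, rep2) %in% allowed))
    # new statements never come from the exposure list
    new_ids <- ds$statement_id[ds$repetition_status == "new"]
    expect_length(intersect(new_ids, expo$statement_id[expo$subject_id == s]), 0)
  }
})

test_that("impossible repetition demands are a configuration error", {
  expect_error(design_config(n_repeated_per_phase = 31),
               "repeatable exposure statements")
  expect_error(design_config(veridicality_split = 1.3), "must be in")
})

test_that("null behavior model hits the intercept probability", {
  cfg <- design_config(n_subjects = 90, n_new_per_phase = 30,
                       n_repeated_per_phase = 30)
  eff <- effect_config(judgment_rep_logodds = c(0, 0),
                       judgment_latent_weight = 0,
                       judgment_subject_sd = 0,
                       judgment_intercept = 0.2)
  ev <- simulate_behavior(generate_design(cfg, seed = 9), eff, seed = 9)
  n <- nrow(ev)
  expect_gte(n, 1e4)
  p_hat <- mean(ev$judgment)
  p_true <- plogis(0.2)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("repetition shifts log response times by the configured delta", {
  cfg <- design_config(n_subjects = 60)
  eff <- effect_config(rt_rep_delta = c(-0.1, -0.1), rt_subject_sd = 0)
  ev <- simulate_behavior(generate_design(cfg, seed = 3), eff, seed = 3)
  d_obs <- mean(log(ev$rt_ms[ev$repetition_status == "repeated"] / 1000)) -
    mean(log(ev$rt_ms[ev$repetition_status == "new"] / 1000))
  se <- eff$rt_sdlog * sqrt(4 / nrow(ev))
  expect_lt(abs(d_obs - (-0.1)), 3 * se)
})

test_that("behavioral tables satisfy the event-table invariants", {
  cfg <- design_config(n_subjects = 3)
  ev <- simulate_behavior(generate_design(cfg, seed = 21), effect_config(),
                          seed = 21)
  expect_true(all(ev$response_onset > ev$stimulus_onset))
  expect_equal(ev$rt_ms,
               (ev$response_onset - ev$stimulus_onset) / cfg$sampling_rate * 1000)
  expect_true(all(ev$judgment %in% 0:1))
  expect_true(all(ev$confidence %in% 1:6))
  # non-overlap with at least one fixation between trials, per session
  for (s in unique(ev$subject_id)) {
    for (p in 1:2) {
      tr <- ev[ev$subject_id == s & ev$phase == p, ]
      tr <- tr[order(tr$stimulus_onset), ]
      gaps <- tr$stimulus_onset[-1] - tr$response_onset[-nrow(tr)]
      expect_true(all(gaps >= cfg$fixation_ms * cfg$sampling_rate / 1000))
    }
  }
})

test_that("phase-wise judgment effects are recoverable from one large draw", {
  cfg <- design_config(n_subjects = 75)
  ev <- simulate_behavior(generate_design(cfg, seed = 31), effect_config(),
                          seed = 31)
  ev <- code_predictors(ev)
  for (p in 1:2) {
    dd <- ev[ev$phase == p, ]
    fit <- fit_glmm_logit(model_spec("judgment01", "repetition01",
                                     family = "binomial"), dd)
    co <- fit$coefficients[fit$coefficients$term == "repetition01", ]
    truth <- effect_config()$judgment_rep_logodds[p]
    expect_lt(abs(co$b - truth), 3 * co$se)
  }
})

test_that("zero-amplitude, zero-noise configuration yields silent channels", {
  cfg <- design_config(n_subjects = 1, n_new_per_phase = 2,
                       n_repeated_per_phase = 2, n_exposure = 16, n_buffer = 2)
  eff <- effect_config(burst_base = c(0, 0, 0), burst_subject_sd = c(0, 0, 0),
                       burst_rep_delta = matrix(0, 2, 3),
                       burst_latent_gain = 0, noise_floor_sd = 0)
  sim <- simulate_experiment(cfg, eff, seed = 2)
  for (rec in sim$recordings) expect_true(all(rec$signal == 0))
})

test_that("signal rendering is seed-deterministic and trials never overlap", {
  cfg <- design_config(n_subjects = 2, n_new_per_phase = 3,
                       n_repeated_per_phase = 3, n_exposure = 16, n_buffer = 2)
  ev <- simulate_behavior(generate_design(cfg, seed = 8), effect_config(),
                          seed = 8)
  r1 <- simulate_emg(ev, effect_config(), seed = 8)
  r2 <- simulate_emg(ev, effect_config(), seed = 8)
  expect_identical(lapply(r1, `[[`, "signal"), lapply(r2, `[[`, "signal"))
  # tampered timeline -> overlap error
  bad <- ev
  i2 <- which(bad$subject_id == 1 & bad$phase == 1)[2]
  i1 <- which(bad$subject_id == 1 & bad$phase == 1)[1]
  bad$stimulus_onset[i2] <- bad$stimulus_onset[i1] + 10
  bad$response_onset[i2] <- bad$response_onset[i1] + 10
  attr(bad, "config") <- attr(ev, "config")
  expect_error(simulate_emg(bad, effect_config(), seed = 8), "overlap")
})

test_that("extracted corrugator features track the latent activation", {
  # low noise, strong latent gain: the signal route must reproduce the
  # latent ordering that simulate_features() uses directly
  cfg <- design_config(n_subjects = 2, n_new_per_phase = 8,
                       n_repeated_per_phase = 8, n_exposure = 36, n_buffer = 2)
  eff <- effect_config(noise_floor_sd = 0.3, burst_latent_gain = 3,
                       burst_subject_sd = c(0, 0, 0))
  sim <- simulate_experiment(cfg, eff, seed = 99)
  tf <- extract_trial_features(sim$recordings, sim$events)
  feats <- assemble_features(tf, sim$events)
  corr <- feats[feats$muscle == "corrugator", ]
  expect_gt(stats::cor(corr$log_rel_auc, corr$latent_corrugator), 0.5)
})

test_that("burst amplitudes carry repetition and latent structure into the signal", {
  # strong effect, no noise: repeated-trial corrugator bursts must be weaker
  cfg <- design_config(n_subjects = 4, n_new_per_phase = 6,
                       n_repeated_per_phase = 6, n_exposure = 24, n_buffer = 2)
  eff <- effect_config(noise_floor_sd = 0, burst_subject_sd = c(0, 0, 0),
                       burst_latent_gain = 0,
                       burst_rep_delta = rbind(c(-4, 0, 0), c(0, 0, 0)))
  sim <- simulate_experiment(cfg, eff, seed = 13)
  ev <- sim$events
  peak <- function(rec, tr) {
    max(abs(rec$signal[tr$stimulus_onset:(tr$response_onset - 1), "corrugator"]))
  }
  p_new <- p_rep <- c()
  for (rec in sim$recordings) {
    if (rec$phase != 1) next
    tr <- ev[ev$subject_id == rec$subject_id & ev$phase == 1, ]
    for (i in seq_len(nrow(tr))) {
      v <- peak(rec, tr[i, ])
      if (tr$repetition_status[i] == "new") p_new <- c(p_new, v)
      else p_rep <- c(p_rep, v)
    }
  }
  expect_gt(mean(p_new), mean(p_rep))
})
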