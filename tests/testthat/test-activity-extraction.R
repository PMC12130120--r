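# Trial segmentation, baseline thresholding, run detection, AUC features.

fs <- 1000

test_that("segmentation produces half-open baseline and activity spans", {
  ev <- data.frame(trial_index = 1:2,
                   stimulus_onset = c(5000, 9000),
                   response_onset = c(5800, 10200))
  w <- segment_trials(ev, n_samples = 12000, fs = fs)
  expect_equal(w$baseline_start, c(4000, 8000))
  expect_equal(w$baseline_end, c(5000, 9000))
  expect_equal(w$activity_end - w$activity_start, c(800, 1200))
  expect_equal(w$rt_ms, c(800, 1200))
  # baseline immediately precedes onset and spans exactly 1000 ms
  expect_equal(w$baseline_end - w$baseline_start, c(1000, 1000))
})

test_that("segmentation errors name the offending trial", {
  ev <- data.frame(trial_index = 1:2, stimulus_onset = c(500, 9000),
                   response_onset = c(1500, 9500))
  expect_error(segment_trials(ev, 12000, fs), "trial 1.*before the recording")
  ev2 <- data.frame(trial_index = 1:2, stimulus_onset = c(5000, 5600),
                    response_onset = c(5800, 6200))
  expect_error(segment_trials(ev2, 12000, fs), "trial 2 overlaps")
  ev3 <- data.frame(trial_index = 1, stimulus_onset = 5000,
                    response_onset = 5000)
  expect_error(segment_trials(ev3, 12000, fs), "non-positive activity")
})

test_that("baseline threshold is median plus sample SD", {
  # hand computation: median 1, sample SD with n-1 denominator
  x <- c(1, 1, 1, 1, 5)
  expect_equal(baseline_threshold(x),
               1 + sqrt(sum((x - mean(x))^2) / 4))
  expect_equal(baseline_threshold(x), 2.78885438, tolerance = 1e-8)
  # constant baseline: threshold equals the constant
  expect_equal(baseline_threshold(rep(3.2, 100)), 3.2)
  # translation equivariance
  set.seed(2)
  b <- runif(50)
  expect_equal(baseline_threshold(b + 7), baseline_threshold(b) + 7)
  expect_error(baseline_threshold(numeric(0)), "empty")
})

test_that("activity detection honours strict threshold and the 50 ms rule", {
  # constant at threshold: nothing active (strictly greater)
  expect_equal(sum(detect_active(rep(2, 200), 2, fs)), 0L)
  # a 49-sample run is rejected, a 50-sample run accepted
  e49 <- c(numeric(30), rep(5, 49), numeric(30))
  e50 <- c(numeric(30), rep(5, 50), numeric(30))
  expect_equal(sum(detect_active(e49, 1, fs, min_ms = 50)), 0L)
  expect_equal(sum(detect_active(e50, 1, fs, min_ms = 50)), 50L)
  # two long runs separated by a subthreshold gap: both active, gap inactive
  env <- c(rep(5, 60), rep(0.5, 20), rep(5, 60))
  mask <- detect_active(env, 1, fs)
  expect_true(all(mask[1:60]), all(mask[81:140]))
  expect_false(any(mask[61:80]))
})

test_that("run-based detection equals the brute-force per-sample oracle", {
  set.seed(303)
  for (i in 1:1000) {
    n <- sample(60:200, 1)
    env <- abs(rnorm(n, sd = 2)) + sample(c(0, 2), n, replace = TRUE,
                                          prob = c(0.7, 0.3))
    thr <- runif(1, 0.5, 3)
    min_n <- sample(c(1, 5, 50), 1)
    expect_identical(detect_active(env, thr, fs, min_ms = min_n),
                     brute_force_active(env, thr, min_n))
  }
})

test_that("AUC integrates the envelope over active samples only", {
  env <- rep(2, 100)
  mask <- c(rep(TRUE, 60), rep(FALSE, 40))
  expect_equal(compute_auc(env, mask, fs), 120) # 60 samples x 2 uV x 1 ms
  expect_equal(compute_auc(env, rep(FALSE, 100), fs), 0)
  # additivity over disjoint runs
  m1 <- m2 <- rep(FALSE, 100)
  m1[1:20] <- TRUE; m2[51:70] <- TRUE
  expect_equal(compute_auc(env, m1 | m2, fs),
               compute_auc(env, m1, fs) + compute_auc(env, m2, fs))
  expect_error(compute_auc(env, m1[1:50], fs), "length")
})

test_that("raising the threshold never increases activity or AUC", {
  set.seed(77)
  env <- emg_envelope(abs(rnorm(2000, sd = 3)), fs)
  thrs <- seq(0, 4, by = 0.25)
  stats_by_thr <- t(vapply(thrs, function(th) {
    m <- detect_active(env, th, fs)
    c(sum(m), compute_auc(env, m, fs))
  }, c(0, 0)))
  expect_true(all(diff(stats_by_thr[, 1]) <= 0))
  expect_true(all(diff(stats_by_thr[, 2]) <= 1e-9))
})

test_that("relativized AUC has the right units and invariances", {
  expect_equal(relativize(120, 1000), 0.12)
  expect_equal(relativize(0, 777), 0)
  expect_equal(relativize(240, 2000), relativize(120, 1000))
  expect_error(relativize(120, 0), "positive")
})

test_that("a noiseless constant burst reproduces its analytic AUC/RT through the full chain", {
  # one trial: constant 10 uV burst (100 Hz sine carrier), 200 ms plateau
  # with 30 ms cosine on/off ramps (a strictly rectangular edge has
  # out-of-band splatter that the band-pass legitimately reshapes, ~2.5%),
  # starting 300 ms after stimulus onset; rt = 1000 ms; no noise anywhere
  amp <- 10; dur <- 200; f0 <- 100; ramp <- 30
  onset <- 3000; resp <- 4000
  n <- 6000
  sig <- numeric(n)
  b0 <- onset + 300
  shape <- rep(1, dur)
  shape[1:ramp] <- 0.5 - 0.5 * cos(pi * (0:(ramp - 1)) / ramp)
  shape[(dur - ramp + 1):dur] <- rev(shape[1:ramp])
  sig[b0:(b0 + dur - 1)] <- amp * shape * sin(2 * pi * f0 * seq_len(dur) / fs)
  rec <- structure(list(subject_id = 1, phase = 1,
                        channels = c("corrugator", "zygomaticus", "frontalis"),
                        signal = cbind(corrugator = sig, zygomaticus = sig,
                                       frontalis = sig),
                        sampling_rate = fs),
                   class = "emg_recording")
  ev <- data.frame(subject_id = 1, phase = 1, trial_index = 1,
                   stimulus_onset = onset, response_onset = resp)
  tf <- extract_trial_features(list(rec), ev)
  # closed form from the input definition alone: integral of the rectified
  # burst (the moving average preserves integrals; band-pass gain at 100 Hz
  # is 1 to < 1e-4), never routed through the filter chain
  expected_auc <- sum(abs(sig)) * (1000 / fs)
  got <- tf[tf$muscle == "corrugator", ]
  expect_equal(got$auc, expected_auc, tolerance = 0.01)
  expect_equal(got$rel_auc, expected_auc / 1000, tolerance = 0.01)
  expect_equal(got$rt_ms, 1000)
})
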