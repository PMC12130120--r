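# ln(x + 1) transform, IQR screening, predictor coding, table assembly.

test_that("log transform is ln(x + 1) and monotone", {
  expect_equal(log_relauc(0), 0)
  expect_equal(log_relauc(exp(1) - 1), 1)
  x <- sort(runif(100, 0, 50))
  expect_true(all(diff(log_relauc(x)) >= 0))
  expect_error(log_relauc(-0.1), "non-negative")
})

test_that("IQR screen matches a hand quartile oracle and is translation invariant", {
  # identical values: IQR 0, strict inequality keeps everything
  expect_true(all(iqr_keep_mask(rep(3, 10))))
  # 99 zeros and one 100: type-7 quartiles of the sorted set are both 0,
  # so only the 100 is outside [Q1 - 3 IQR, Q3 + 3 IQR]
  v <- c(rep(0, 99), 100)
  expect_equal(sum(!iqr_keep_mask(v)), 1L)
  expect_false(iqr_keep_mask(v)[100])
  # oracle on a random draw: manual linear-interpolation quartiles
  set.seed(5)
  w <- rnorm(473)
  srt <- sort(w)
  hand_q <- function(p) {
    h <- (length(srt) - 1) * p + 1
    lo <- floor(h)
    srt[lo] + (h - lo) * (srt[min(lo + 1, length(srt))] - srt[lo])
  }
  q1 <- hand_q(0.25); q3 <- hand_q(0.75); iqr <- q3 - q1
  expect_identical(iqr_keep_mask(w),
                   w >= q1 - 3 * iqr & w <= q3 + 3 * iqr)
  # translation invariance of the removal count
  wx <- c(w, 40)
  expect_equal(sum(!iqr_keep_mask(wx)), sum(!iqr_keep_mask(wx + 123.4)))
  expect_error(iqr_keep_mask(c(1, 2, 3)), "at least 4")
})

test_that("predictor coding follows the documented contrasts and round-trips", {
  ev <- data.frame(
    repetition_status = c("new", "repeated"),
    phase = c(1L, 2L),
    veridicality = c("false_fact", "true_fact"),
    judgment = c(0L, 1L),
    rt_ms = c(1500, 2000)
  )
  co <- code_predictors(ev)
  expect_equal(co$repetition01, c(0L, 1L))
  expect_equal(co$phase_c, c(-0.5, 0.5))
  expect_equal(co$veridicality_c, c(-0.5, 0.5))
  expect_equal(co$judgment01, c(0L, 1L))
  expect_equal(co$rt_s, c(1.5, 2))
  # decode(code(x)) = x
  expect_equal(ifelse(co$repetition01 == 1, "repeated", "new"),
               ev$repetition_status)
  expect_equal(ifelse(co$phase_c > 0, 2L, 1L), ev$phase)
  expect_equal(ifelse(co$veridicality_c > 0, "true_fact", "false_fact"),
               ev$veridicality)
  expect_error(code_predictors(transform(ev, repetition_status = "maybe")),
               "unknown repetition_status")
  expect_error(code_predictors(transform(ev, veridicality = "unsure")),
               "unknown veridicality")
})

test_that("assembly joins, transforms, flags outliers and keeps keys unique", {
  cfg <- design_config(n_subjects = 3, n_new_per_phase = 6,
                       n_repeated_per_phase = 6, n_exposure = 24,
                       n_buffer = 2)
  sim <- simulate_experiment(cfg, effect_config(), seed = 17)
  tf <- extract_trial_features(sim$recordings, sim$events)
  feats <- assemble_features(tf, sim$events)
  # row count: subjects x phases x trials x 3 muscles
  expect_equal(nrow(feats), 3 * 2 * 12 * 3)
  expect_equal(feats$log_rel_auc, log(feats$rel_auc + 1))
  key <- with(feats, paste(subject_id, phase, trial_index, muscle))
  expect_false(anyDuplicated(key) > 0)
  osum <- attr(feats, "outlier_summary")
  expect_setequal(osum$muscle, c("corrugator", "zygomaticus", "frontalis"))
  expect_equal(sum(osum$n), nrow(feats))
  # outlier flags reproduce the per-muscle screen
  for (m in unique(feats$muscle)) {
    idx <- feats$muscle == m
    expect_equal(feats$outlier[idx], !iqr_keep_mask(feats$log_rel_auc[idx]))
  }
  # wide pivot: one row per trial, outliers become NA
  wide <- features_wide(feats)
  expect_equal(nrow(wide), 3 * 2 * 12)
  expect_equal(sum(is.na(wide[, c("log_corrugator", "log_zygomaticus",
                                  "log_frontalis")])),
               sum(feats$outlier))
})

test_that("an injected extreme trial is flagged and removed from wide EMG columns", {
  feats <- simulate_features(design_config(n_subjects = 6), seed = 23)
  i <- which(feats$muscle == "corrugator")[5]
  feats$log_rel_auc[i] <- 60 # far beyond 3 IQRs
  refreshed <- truthemg:::finish_feature_table(
    as.data.frame(feats)[, setdiff(names(feats), "outlier")])
  expect_true(refreshed$outlier[i])
  wide <- features_wide(refreshed)
  row <- wide[wide$subject_id == refreshed$subject_id[i] &
                wide$phase == refreshed$phase[i] &
                wide$trial_index == refreshed$trial_index[i], ]
  expect_true(is.na(row$log_corrugator))
})
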