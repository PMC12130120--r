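# From trial features to the analysis table: ln(x + 1) transform, 3-IQR
# outlier screening, predictor coding, behavior join.

#' Log-transform a relativized AUC
#'
#' `ln(rel_auc + 1)`: the constant keeps zero-activity trials defined and
#' the natural log compresses the right tail of the amplitude distribution.
#'
#' @param rel_auc non-negative relativized AUC (microvolts).
#' @return unitless log feature, `>= 0`.
#' @export
log_relauc <- function(rel_auc) {
  if (any(rel_auc < 0)) stop2("rel_auc must be non-negative")
  log(rel_auc + 1.0)
}

#' Interquartile-range outlier screen
#'
#' Flags values lying strictly more than `k` interquartile ranges below the
#' first or above the third quartile (quartiles by linear interpolation,
#' type 7). With identical values the IQR is zero and nothing is removed.
#'
#' @param values numeric vector (at least 4 values).
#' @param k IQR multiplier; default 3.0 flags only extreme values.
#' @return logical keep-mask (`TRUE` = retained).
#' @export
iqr_keep_mask <- function(values, k = 3.0) {
  if (length(values) < 4L) stop2("need at least 4 values to screen outliers")
  check_finite_vector(values, "values")
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values >= q[1] - k * iqr & values <= q[2] + k * iqr
}

#' Code design predictors for the multilevel models
#'
#' Deterministic coding used throughout the inference layer:
#' * `repetition01`: dummy coded, 0 = new (reference), 1 = repeated;
#' * `phase_c`: -0.5 = first (10-minute) and +0.5 = second (1-week)
#'   judgment phase;
#' * `veridicality_c`: -0.5 = factually incorrect, +0.5 = factually correct;
#' * `judgment01`: 0 = "false", 1 = "true";
#' * `rt_s`: response time in seconds.
#'
#' @param events data.frame with `repetition_status`, `phase`,
#'   `veridicality` and optionally `judgment`, `rt_ms`.
#' @return the input with coded columns appended.
#' @export
code_predictors <- function(events) {
  ev <- as.data.frame(events)
  rep_map <- c(new = 0L, repeated = 1L)
  ver_map <- c(false_fact = -0.5, true_fact = 0.5)
  if (!all(ev$repetition_status %in% names(rep_map))) {
    stop2("unknown repetition_status label(s): %s",
          paste(setdiff(unique(ev$repetition_status), names(rep_map)),
                collapse = ", "))
  }
  if (!all(ev$veridicality %in% names(ver_map))) {
    stop2("unknown veridicality label(s): %s",
          paste(setdiff(unique(ev$veridicality), names(ver_map)),
                collapse = ", "))
  }
  if (!all(ev$phase %in% c(1L, 2L))) {
    stop2("phase must be 1 or 2")
  }
  ev$repetition01 <- unname(rep_map[ev$repetition_status])
  ev$phase_c <- ifelse(ev$phase == 1L, -0.5, 0.5)
  ev$veridicality_c <- unname(ver_map[ev$veridicality])
  if ("judgment" %in% names(ev)) ev$judgment01 <- as.integer(ev$judgment)
  if ("rt_ms" %in% names(ev)) ev$rt_s <- ev$rt_ms / 1000
  ev
}

# Shared tail of assemble_features() / simulate_features(): coding, outlier
# flags, key checks.
finish_feature_table <- function(long, outlier_k = 3.0,
                                 outlier_grouping = c("muscle",
                                                      "muscle_phase")) {
  outlier_grouping <- match.arg(outlier_grouping)
  long <- code_predictors(long)
  key <- paste(long$subject_id, long$phase, long$trial_index, long$muscle)
  if (anyDuplicated(key)) {
    stop2("duplicate (subject, phase, trial, muscle) rows in feature table")
  }
  grp <- switch(outlier_grouping,
                muscle = long$muscle,
                muscle_phase = paste(long$muscle, long$phase))
  long$outlier <- FALSE
  for (g in unique(grp)) {
    idx <- which(grp == g)
    long$outlier[idx] <- !iqr_keep_mask(long$log_rel_auc[idx], k = outlier_k)
  }
  attr(long, "outlier_summary") <- do.call(rbind, lapply(
    split(long, long$muscle), function(d) {
      data.frame(muscle = d$muscle[1], n = nrow(d),
                 n_removed = sum(d$outlier),
                 frac_removed = mean(d$outlier))
    }))
  class(long) <- c("feature_table", "data.frame")
  long
}

#' Assemble the long-format analysis table
#'
#' Joins trial features with the behavioral event table, applies the
#' ln(x + 1) transform, screens outliers per muscle on the full logarithmized
#' distribution (strictly beyond `outlier_k` = 3 IQRs from the quartiles)
#' and codes all model predictors.
#'
#' Outlier rows are *flagged*, not dropped: models over EMG outcomes or
#' predictors exclude them (see [features_wide()]), behavior-only models use
#' all trials.
#'
#' @param trial_features output of [extract_trial_features()].
#' @param events completed event table.
#' @param outlier_k IQR multiplier for the outlier screen.
#' @param outlier_grouping `"muscle"` (default: pooled across subjects and
#'   phases, per muscle) or `"muscle_phase"`.
#' @return a `feature_table` data.frame, one row per trial x muscle, with
#'   columns `subject_id`, `phase`, `trial_index`, `muscle`, `log_rel_auc`,
#'   `rt_s`, `judgment01`, `repetition01`, `phase_c`, `veridicality_c`,
#'   `confidence`, `outlier`; per-muscle removal fractions in attribute
#'   `"outlier_summary"`.
#' @export
assemble_features <- function(trial_features, events, outlier_k = 3.0,
                              outlier_grouping = "muscle") {
  tf <- as.data.frame(trial_features)
  ev <- as.data.frame(events)
  need_ev <- c("subject_id", "phase", "trial_index", "repetition_status",
               "veridicality", "judgment", "confidence")
  miss <- setdiff(need_ev, names(ev))
  if (length(miss)) stop2("events lack column(s): %s", paste(miss, collapse = ", "))
  long <- merge(tf,
                ev[, c(need_ev, intersect("latent_corrugator", names(ev)))],
                by = c("subject_id", "phase", "trial_index"), sort = FALSE)
  if (nrow(long) != nrow(tf)) {
    stop2("feature/event join changed row count (%d -> %d); check keys",
          nrow(tf), nrow(long))
  }
  long$log_rel_auc <- log_relauc(long$rel_auc)
  long <- long[order(long$subject_id, long$phase, long$trial_index,
                     long$muscle), ]
  rownames(long) <- NULL
  finish_feature_table(long, outlier_k = outlier_k,
                       outlier_grouping = outlier_grouping)
}

#' Pivot the feature table to one row per trial
#'
#' Spreads the three muscles into `log_corrugator`, `log_zygomaticus` and
#' `log_frontalis` columns. Values flagged as outliers become `NA`, so any
#' model formula touching an EMG column automatically drops those trials
#' while behavior-only models keep them.
#'
#' @param features a `feature_table` from [assemble_features()] or
#'   [simulate_features()].
#' @return data.frame, one row per (subject, phase, trial).
#' @export
features_wide <- function(features) {
  f <- as.data.frame(features)
  f$value <- ifelse(f$outlier, NA_real_, f$log_rel_auc)
  base_cols <- intersect(
    c("subject_id", "phase", "trial_index", "repetition01", "phase_c",
      "veridicality_c", "judgment01", "confidence", "rt_s"),
    names(f))
  wide <- unique(f[, base_cols])
  for (mus in unique(f$muscle)) {
    sub <- f[f$muscle == mus, c("subject_id", "phase", "trial_index", "value")]
    names(sub)[4] <- paste0("log_", mus)
    wide <- merge(wide, sub, by = c("subject_id", "phase", "trial_index"),
                  sort = FALSE)
  }
  wide <- wide[order(wide$subject_id, wide$phase, wide$trial_index), ]
  rownames(wide) <- NULL
  wide
}
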