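# Trial-wise muscle-activity extraction on amplitude envelopes:
# segmentation, baseline thresholding, minimum-duration active runs,
# AUC and AUC/RT.

#' Segment a recording into per-trial baseline and activity windows
#'
#' For every trial, the baseline is the `baseline_ms` window ending at
#' stimulus onset (half-open `[onset - baseline_ms, onset)` in samples) and
#' the activity window runs from stimulus onset to the response keypress
#' (half-open `[onset, response_onset)`).
#'
#' @param events event table rows for a single subject-phase session with
#'   `stimulus_onset` / `response_onset` sample indices (1-based, as
#'   produced by [simulate_behavior()]).
#' @param n_samples recording length in samples.
#' @param fs sampling rate (Hz).
#' @param baseline_ms baseline duration (ms) before stimulus onset.
#' @return data.frame with one row per trial: `trial_index`,
#'   `baseline_start`, `baseline_end`, `activity_start`, `activity_end`
#'   (half-open, 1-based starts / exclusive ends) and `rt_ms`.
#' @export
segment_trials <- function(events, n_samples, fs, baseline_ms = 1000) {
  ev <- as.data.frame(events)
  need <- c("trial_index", "stimulus_onset", "response_onset")
  if (!all(need %in% names(ev))) {
    stop2("events must contain columns %s", paste(need, collapse = ", "))
  }
  if (anyNA(ev$stimulus_onset) || anyNA(ev$response_onset)) {
    stop2("events contain NA onsets; run simulate_behavior() first")
  }
  nb <- round(baseline_ms * fs / 1000)
  ev <- ev[order(ev$stimulus_onset), , drop = FALSE]
  w <- data.frame(
    trial_index = ev$trial_index,
    baseline_start = ev$stimulus_onset - nb,
    baseline_end = ev$stimulus_onset,      # exclusive
    activity_start = ev$stimulus_onset,
    activity_end = ev$response_onset,      # exclusive
    rt_ms = (ev$response_onset - ev$stimulus_onset) / fs * 1000
  )
  bad <- which(w$baseline_start < 1L)
  if (length(bad)) {
    stop2("baseline of trial %s starts before the recording",
          paste(w$trial_index[bad], collapse = ", "))
  }
  if (any(w$activity_end > n_samples + 1L)) {
    bad <- w$trial_index[w$activity_end > n_samples + 1L]
    stop2("trial %s extends beyond the recording", paste(bad, collapse = ", "))
  }
  if (any(w$activity_end <= w$activity_start)) {
    bad <- w$trial_index[w$activity_end <= w$activity_start]
    stop2("trial %s has a non-positive activity span", paste(bad, collapse = ", "))
  }
  if (nrow(w) > 1L) {
    overlap <- which(w$baseline_start[-1] < w$activity_end[-nrow(w)])
    if (length(overlap)) {
      stop2("trial %s overlaps the preceding trial",
            paste(w$trial_index[overlap + 1L], collapse = ", "))
    }
  }
  w
}

#' Baseline activity-detection threshold
#'
#' Median plus one sample standard deviation (denominator n - 1) of the
#' baseline envelope. Computed trial-wise so slow drifts in pre-stimulus
#' tone do not leak across trials.
#'
#' @param baseline_env numeric vector, envelope over the baseline window.
#' @return scalar threshold in microvolts.
#' @examples
#' baseline_threshold(c(1, 1, 1, 1, 5)) # 1 + sd = 2.7889
#' @export
baseline_threshold <- function(baseline_env) {
  if (length(baseline_env) == 0L) stop2("empty baseline window")
  check_finite_vector(baseline_env, "baseline_env")
  thr <- median(baseline_env) + if (length(baseline_env) > 1L) {
    sd(baseline_env)
  } else {
    0
  }
  unname(thr)
}

#' Detect active samples above a baseline threshold
#'
#' Marks samples whose envelope lies strictly above `threshold`, groups them
#' into maximal runs, and discards runs shorter than the minimum duration
#' (default 50 ms). Gaps between runs are never merged.
#'
#' @param env_window numeric vector, envelope over the activity window.
#' @param threshold microvolt threshold from [baseline_threshold()].
#' @param fs sampling rate (Hz).
#' @param min_ms minimum run duration in ms; runs of fewer than
#'   `round(min_ms * fs / 1000)` samples are rejected.
#' @return logical vector the same length as `env_window`.
#' @export
detect_active <- function(env_window, threshold, fs, min_ms = 50) {
  check_finite_vector(env_window, "env_window")
  check_number(threshold, "threshold")
  min_n <- round(min_ms * fs / 1000)
  if (min_n < 1) stop2("`min_ms` of %g spans no sample at %g Hz", min_ms, fs)
  above <- env_window > threshold
  if (!any(above)) return(above)
  r <- rle(above)
  r$values <- r$values & r$lengths >= min_n
  inverse.rle(r)
}

#' Area under the envelope over active samples
#'
#' Integrates the envelope over active samples only, by the rectangle rule:
#' `sum(env[mask]) * (1000 / fs)` microvolt-milliseconds.
#'
#' @param env_window numeric envelope over the activity window.
#' @param mask logical mask from [detect_active()]; same length.
#' @param fs sampling rate (Hz).
#' @return AUC in microvolt-milliseconds (`>= 0` for non-negative envelopes).
#' @export
compute_auc <- function(env_window, mask, fs) {
  if (length(env_window) != length(mask)) {
    stop2("mask length (%d) differs from window length (%d)",
          length(mask), length(env_window))
  }
  sum(env_window[mask]) * (1000 / fs)
}

#' Relativize an AUC to the trial's response time
#'
#' `auc / rt_ms`: normalizes for trial-duration differences, giving the mean
#' active-sample amplitude contribution per millisecond (microvolts).
#'
#' @param auc AUC in microvolt-milliseconds.
#' @param rt_ms response time in milliseconds; must be positive.
#' @return relativized AUC in microvolts.
#' @export
relativize <- function(auc, rt_ms) {
  if (any(rt_ms <= 0)) stop2("response time must be positive")
  auc / rt_ms
}

#' Extract per-trial muscle-activity features from recordings
#'
#' Runs the full conditioning chain ([emg_preprocess()]) on every channel of
#' every recording, segments trials, estimates trial-wise baseline
#' thresholds, applies the minimum-duration activity rule and emits one
#' feature row per trial and muscle.
#'
#' @param recordings list of `emg_recording` objects from [simulate_emg()]
#'   (or read back with [read_signal_csv()]).
#' @param events the completed event table covering those recordings.
#' @param baseline_ms baseline window (ms).
#' @param min_ms minimum active-run duration (ms).
#' @param ... filter settings forwarded to [emg_preprocess()].
#' @return data.frame with columns `subject_id`, `phase`, `trial_index`,
#'   `muscle`, `threshold`, `n_active`, `auc`, `rt_ms`, `rel_auc`.
#' @export
extract_trial_features <- function(recordings, events, baseline_ms = 1000,
                                   min_ms = 50, ...) {
  ev <- as.data.frame(events)
  out <- vector("list", length(recordings))
  for (k in seq_along(recordings)) {
    rec <- recordings[[k]]
    stopifnot(inherits(rec, "emg_recording"))
    fs <- rec$sampling_rate
    tr <- ev[ev$subject_id == rec$subject_id & ev$phase == rec$phase, ]
    if (nrow(tr) == 0L) {
      stop2("no events for subject %s phase %s", rec$subject_id, rec$phase)
    }
    wins <- segment_trials(tr, nrow(rec$signal), fs, baseline_ms = baseline_ms)
    rows <- vector("list", length(rec$channels))
    for (m in seq_along(rec$channels)) {
      env <- emg_preprocess(rec$signal[, m], fs, ...)
      thr <- numeric(nrow(wins)); nact <- integer(nrow(wins))
      auc <- numeric(nrow(wins))
      for (i in seq_len(nrow(wins))) {
        bl <- env[wins$baseline_start[i]:(wins$baseline_end[i] - 1L)]
        aw <- env[wins$activity_start[i]:(wins$activity_end[i] - 1L)]
        thr[i] <- baseline_threshold(bl)
        mask <- detect_active(aw, thr[i], fs, min_ms = min_ms)
        nact[i] <- sum(mask)
        auc[i] <- compute_auc(aw, mask, fs)
      }
      rows[[m]] <- data.frame(
        subject_id = rec$subject_id, phase = rec$phase,
        trial_index = wins$trial_index, muscle = rec$channels[m],
        threshold = thr, n_active = nact, auc = auc, rt_ms = wins$rt_ms,
        rel_auc = relativize(auc, wins$rt_ms),
        stringsAsFactors = FALSE
      )
    }
    out[[k]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
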