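# End-to-end orchestration: simulate -> extract -> analyze, with a YAML
# config, per-stage logging and reproducibility manifests.

#' Build a run configuration
#'
#' A run configuration bundles everything one end-to-end run needs: output
#' directory, design and effect configurations, signal-processing and
#' feature settings, inference settings and the global seed. Two profiles
#' are provided: `"full"` (the complete 75-subject design; signal rendering
#' takes a while) and `"tiny"` (4 subjects, 8 trials per phase — a smoke
#' profile that exercises every stage in seconds).
#'
#' @param out_dir output directory for all stages.
#' @param profile `"tiny"` or `"full"`; sets design defaults which
#'   `design`/`effects` entries may override.
#' @param design,effects optional [design_config()] / [effect_config()]
#'   overrides (lists of arguments are accepted).
#' @param signal list of filter settings (`low`, `high`, `order`,
#'   `notch_freq`, `q`, `window_ms`).
#' @param features list of feature settings (`baseline_ms`, `min_ms`,
#'   `outlier_k`, `outlier_grouping`).
#' @param inference list of inference settings (`n_boot`, `nagq`, `alpha`,
#'   `log_rt`).
#' @param seed global integer seed recorded in every manifest.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, profile = c("tiny", "full"),
                       design = NULL, effects = NULL,
                       signal = list(), features = list(),
                       inference = list(), seed = 1L) {
  profile <- match.arg(profile)
  base_design <- if (profile == "tiny") {
    list(n_subjects = 4L, n_new_per_phase = 4L, n_repeated_per_phase = 4L,
         n_exposure = 20L, n_buffer = 2L)
  } else {
    list()
  }
  if (inherits(design, "design_config")) design <- unclass(design)
  if (inherits(effects, "effect_config")) {
    effects_obj <- effects
  } else {
    effects_obj <- do.call(effect_config, effects %||% list())
  }
  design_args <- modifyList(base_design, design %||% list())
  cfg <- list(
    out_dir = out_dir,
    profile = profile,
    design = do.call(design_config, design_args),
    effects = effects_obj,
    signal = modifyList(list(low = 10, high = 400, order = 4,
                             notch_freq = 50, q = 30, window_ms = 30),
                        signal),
    features = modifyList(list(baseline_ms = 1000, min_ms = 50,
                               outlier_k = 3.0, outlier_grouping = "muscle"),
                          features),
    inference = modifyList(list(n_boot = 200L, nagq = 1L, alpha = 0.05,
                                log_rt = FALSE),
                           inference),
    seed = as.integer(seed)
  )
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' The file mirrors [run_config()] arguments: top-level keys `out_dir`,
#' `profile`, `seed` and sections `design`, `effects`, `signal`, `features`,
#' `inference` with flat key-value entries.
#'
#' @param path YAML file.
#' @param out_dir,seed optional overrides of the file's values.
#' @return a `run_config`.
#' @export
load_run_config <- function(path, out_dir = NULL, seed = NULL) {
  if (!file.exists(path)) stop2("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  run_config(
    out_dir = out_dir %||% y$out_dir %||% stop2("config lacks out_dir"),
    profile = y$profile %||% "tiny",
    design = y$design, effects = y$effects,
    signal = y$signal %||% list(), features = y$features %||% list(),
    inference = y$inference %||% list(),
    seed = seed %||% y$seed %||% 1L
  )
}

config_manifest <- function(cfg, stage, extra = list()) {
  ser <- list(
    design = unclass(cfg$design),
    effects = lapply(unclass(cfg$effects), function(x) {
      if (is.matrix(x)) as.vector(x) else x
    }),
    signal = cfg$signal, features = cfg$features, inference = cfg$inference
  )
  cfg_json <- jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA)
  c(list(stage = stage, seed = cfg$seed, profile = cfg$profile,
         config = ser,
         config_hash = content_hash(paste0(cfg_json, "|seed=", cfg$seed)),
         package_version = as.character(packageVersion("truthemg")),
         r_version = paste(R.version$major, R.version$minor, sep = ".")),
    extra)
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
}

#' Pipeline stage: simulate a dataset to disk
#'
#' Generates the design, behavior and raw EMG for the configured experiment
#' and writes `events.tsv`, one `signals/sub<j>_phase<p>.csv` (+ JSON
#' sidecar) per session, and `manifest.json` (config, config hash, seed,
#' versions, row/file counts).
#'
#' @param cfg a [run_config()].
#' @param verbose log per-stage progress messages.
#' @return the dataset directory, invisibly.
#' @export
cmd_simulate <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(file.path(cfg$out_dir, "signals"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(cfg$out_dir)) stop2("cannot create output dir %s", cfg$out_dir)
  t0 <- Sys.time()
  sim <- simulate_experiment(cfg$design, cfg$effects, seed = cfg$seed,
                             signals = TRUE)
  write_events_tsv(sim$events, file.path(cfg$out_dir, "events.tsv"))
  for (nm in names(sim$recordings)) {
    write_signal_csv(sim$recordings[[nm]],
                     file.path(cfg$out_dir, "signals", paste0(nm, ".csv")))
  }
  manifest <- config_manifest(cfg, "simulate", list(
    n_events = nrow(sim$events),
    n_recordings = length(sim$recordings),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage(verbose, "simulate: %d subjects, %d trials, %d recordings (%.1fs)",
            cfg$design$n_subjects, nrow(sim$events), length(sim$recordings),
            manifest$elapsed_s)
  invisible(cfg$out_dir)
}

#' Pipeline stage: extract the feature table from a dataset on disk
#'
#' Reads `events.tsv` and every signal CSV under `signals/`, runs the
#' conditioning chain, trial-wise activity extraction and feature assembly,
#' and writes `features.tsv` plus an extraction manifest with per-stage
#' counts (trials processed, outliers flagged per muscle).
#'
#' @inheritParams cmd_simulate
#' @return path to `features.tsv`, invisibly.
#' @export
cmd_extract <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  ev_path <- file.path(cfg$out_dir, "events.tsv")
  if (!file.exists(ev_path)) stop2("no dataset at %s; run cmd_simulate first",
                                   cfg$out_dir)
  t0 <- Sys.time()
  events <- read_events_tsv(ev_path)
  sig_files <- list.files(file.path(cfg$out_dir, "signals"),
                          pattern = "\\.csv$", full.names = TRUE)
  if (!length(sig_files)) stop2("no signal files under %s/signals", cfg$out_dir)
  recordings <- lapply(sig_files, read_signal_csv)
  tf <- extract_trial_features(
    recordings, events,
    baseline_ms = cfg$features$baseline_ms, min_ms = cfg$features$min_ms,
    low = cfg$signal$low, high = cfg$signal$high, order = cfg$signal$order,
    notch_freq = cfg$signal$notch_freq, q = cfg$signal$q,
    window_ms = cfg$signal$window_ms)
  feats <- assemble_features(tf, events, outlier_k = cfg$features$outlier_k,
                             outlier_grouping = cfg$features$outlier_grouping)
  out_path <- file.path(cfg$out_dir, "features.tsv")
  write_tsv(as.data.frame(feats), out_path)
  osum <- attr(feats, "outlier_summary")
  manifest <- config_manifest(cfg, "extract", list(
    n_recordings = length(recordings),
    n_feature_rows = nrow(feats),
    outliers = osum,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ))
  jsonlite::write_json(manifest, file.path(cfg$out_dir,
                                           "manifest_extract.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage(verbose,
            "extract: %d recordings -> %d feature rows, %d outliers (%.1fs)",
            length(recordings), nrow(feats), sum(osum$n_removed),
            manifest$elapsed_s)
  invisible(out_path)
}

#' Pipeline stage: run the model battery on extracted features
#'
#' Reads `features.tsv`, reruns predictor coding and outlier flags, fits the
#' full model battery (including mediation when `n_boot > 0`) and writes the
#' report directory `report/` (TSVs, JSON, summary text).
#'
#' @inheritParams cmd_simulate
#' @return the `truth_report`, invisibly.
#' @export
cmd_analyze <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  f_path <- file.path(cfg$out_dir, "features.tsv")
  if (!file.exists(f_path)) stop2("no features at %s; run cmd_extract first",
                                  cfg$out_dir)
  t0 <- Sys.time()
  long <- read_tsv(f_path)
  feats <- finish_feature_table(
    long[, setdiff(names(long),
                   c("outlier", "repetition01", "phase_c", "veridicality_c",
                     "judgment01", "rt_s"))],
    outlier_k = cfg$features$outlier_k,
    outlier_grouping = cfg$features$outlier_grouping)
  report <- run_model_battery(feats, n_boot = cfg$inference$n_boot,
                              nagq = cfg$inference$nagq,
                              alpha = cfg$inference$alpha,
                              log_rt = cfg$inference$log_rt,
                              seed = cfg$seed)
  rep_dir <- file.path(cfg$out_dir, "report")
  write_report(report, rep_dir)
  manifest <- config_manifest(cfg, "analyze", list(
    n_models = length(report$fits),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ))
  jsonlite::write_json(manifest, file.path(rep_dir, "manifest_analyze.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage(verbose, "analyze: %d models -> %s (%.1fs)",
            length(report$fits), rep_dir, manifest$elapsed_s)
  invisible(report)
}

#' Pipeline stage: run everything
#'
#' @inheritParams cmd_simulate
#' @return the `truth_report`, invisibly.
#' @export
cmd_all <- function(cfg, verbose = TRUE) {
  cmd_simulate(cfg, verbose = verbose)
  cmd_extract(cfg, verbose = verbose)
  cmd_analyze(cfg, verbose = verbose)
}

#' Command-line entry point
#'
#' Dispatches `simulate`, `extract`, `analyze` or `all` with flags
#' `--config <yaml>`, `--out <dir>`, `--seed <int>`,
#' `--profile {tiny,full}`, `--quiet`. Returns (and, under `Rscript`, exits
#' with) 0 on success, 2 on configuration errors, 3 on data errors.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return integer exit status, invisibly.
#' @export
truthemg_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: truthemg <simulate|extract|analyze|all>",
    "[--config FILE] [--out DIR] [--seed INT] [--profile tiny|full]",
    "[--quiet]")
  get_flag <- function(flag) {
    i <- which(args == flag)
    if (length(i) != 1L || i == length(args)) return(NULL)
    args[i + 1L]
  }
  if (length(args) < 1L || !args[1] %in% c("simulate", "extract",
                                           "analyze", "all")) {
    message(usage)
    return(invisible(2L))
  }
  verbose <- !("--quiet" %in% args)
  cfg <- tryCatch({
    cfg_file <- get_flag("--config")
    seed <- get_flag("--seed")
    if (!is.null(seed)) seed <- as.integer(seed)
    out <- get_flag("--out")
    if (!is.null(cfg_file)) {
      load_run_config(cfg_file, out_dir = out, seed = seed)
    } else {
      if (is.null(out)) stop2("either --config or --out is required")
      run_config(out, profile = get_flag("--profile") %||% "tiny",
                 seed = seed %||% 1L)
    }
  }, error = function(e) e)
  if (inherits(cfg, "error")) {
    message("configuration error: ", conditionMessage(cfg))
    return(invisible(2L))
  }
  res <- tryCatch({
    switch(args[1],
           simulate = cmd_simulate(cfg, verbose),
           extract = cmd_extract(cfg, verbose),
           analyze = cmd_analyze(cfg, verbose),
           all = cmd_all(cfg, verbose))
    0L
  }, error = function(e) {
    message("data error: ", conditionMessage(e))
    3L
  })
  invisible(res)
}
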