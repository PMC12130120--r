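# The full analysis battery over an assembled feature table: manipulation
# check, fluency-link model, moderation models, phase-wise EMG and judgment
# models, AIC/BIC comparison and the corrugator mediation analysis.

battery_model_list <- function() {
  c("rt_manipulation_check", "fluency_link",
    "moderation_corrugator", "moderation_zygomaticus", "moderation_frontalis",
    "emg_phase1_corrugator", "emg_phase1_frontalis", "emg_phase1_zygomaticus",
    "emg_phase2_corrugator", "emg_phase2_frontalis", "emg_phase2_zygomaticus",
    "corrugator_judgment", "zygomaticus_corrugator",
    "judgment_moderation",
    "judgment_phase1_model1", "judgment_phase1_model2",
    "judgment_phase2_model1", "judgment_phase2_model2")
}

#' Run the full multilevel model battery
#'
#' Fits, on one assembled feature table, the complete set of analyses this
#' package implements:
#' \itemize{
#'   \item `rt_manipulation_check`: RT (s) on repetition, judgment phase,
#'     veridicality and the repetition-by-phase / repetition-by-veridicality
#'     interactions (all trials; LMM).
#'   \item `fluency_link`: RT (s) on the three log muscle activities (LMM).
#'   \item `moderation_<muscle>`: each log activity on repetition, phase,
#'     veridicality and the repetition interactions (LMM).
#'   \item `emg_phase<p>_<muscle>`: per judgment phase, each log activity on
#'     repetition status alone (LMM, Table-style phase split).
#'   \item `corrugator_judgment`: phase-1 log corrugator on repetition,
#'     judgment and their interaction.
#'   \item `zygomaticus_corrugator`: phase-1 log zygomaticus on repetition
#'     plus log corrugator.
#'   \item `judgment_moderation`: judgments on repetition, phase,
#'     veridicality, all three log activities and the phase/veridicality
#'     interaction sets (GLMM, logit).
#'   \item `judgment_phase<p>_model1/2`: per phase, judgments on repetition
#'     alone (model 1) and with the three log activities (model 2), plus the
#'     AIC/BIC comparison of the two.
#'   \item `mediation`: phase-1 repetition -> log corrugator -> judgment
#'     cluster-bootstrap mediation.
#' }
#'
#' Models with EMG outcomes or predictors exclude outlier-flagged trials
#' (their wide-format values are `NA`); behavior-only models use all trials.
#' Response times enter in raw seconds by default (`log_rt = TRUE` switches
#' to log seconds).
#'
#' @param features a `feature_table` from [assemble_features()] or
#'   [simulate_features()].
#' @param n_boot bootstrap replicates for the mediation block (set to 0 to
#'   skip mediation).
#' @param nagq quadrature nodes for logistic models (1 = Laplace).
#' @param alpha significance level used when flagging effects in the text
#'   report.
#' @param log_rt analyze `log(rt_s)` instead of raw seconds.
#' @param seed seed for the mediation bootstrap.
#' @return a `truth_report` list: `fits` (named `model_fit`s), `comparisons`
#'   (per-phase judgment model AIC/BIC tables), `mediation`
#'   (a `mediation_result` or `NULL`), `outlier_summary`, `settings`.
#' @export
run_model_battery <- function(features, n_boot = 1000L, nagq = 1L,
                              alpha = 0.05, log_rt = FALSE, seed = 1L) {
  wide <- features_wide(features)
  need <- c("rt_s", "judgment01", "repetition01", "phase_c", "veridicality_c",
            "log_corrugator", "log_zygomaticus", "log_frontalis")
  miss <- setdiff(need, names(wide))
  if (length(miss)) stop2("feature table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (log_rt) wide$rt_s <- log(wide$rt_s)
  p1 <- wide[wide$phase == 1L, ]
  p2 <- wide[wide$phase == 2L, ]
  fits <- list()
  mod_terms <- c("repetition01", "phase_c", "veridicality_c",
                 "repetition01:veridicality_c", "repetition01:phase_c")
  fits$rt_manipulation_check <- fit_lmm(
    model_spec("rt_s", mod_terms), wide, label = "rt_manipulation_check")
  fits$fluency_link <- fit_lmm(
    model_spec("rt_s", c("log_corrugator", "log_frontalis",
                         "log_zygomaticus")),
    wide, label = "fluency_link")
  for (mus in c("corrugator", "zygomaticus", "frontalis")) {
    fits[[paste0("moderation_", mus)]] <- fit_lmm(
      model_spec(paste0("log_", mus), mod_terms), wide,
      label = paste0("moderation_", mus))
  }
  for (p in 1:2) {
    dat <- if (p == 1L) p1 else p2
    for (mus in c("corrugator", "frontalis", "zygomaticus")) {
      lab <- sprintf("emg_phase%d_%s", p, mus)
      fits[[lab]] <- fit_lmm(
        model_spec(paste0("log_", mus), "repetition01"), dat, label = lab)
    }
  }
  fits$corrugator_judgment <- fit_lmm(
    model_spec("log_corrugator",
               c("repetition01", "judgment01", "repetition01:judgment01")),
    p1, label = "corrugator_judgment")
  fits$zygomaticus_corrugator <- fit_lmm(
    model_spec("log_zygomaticus", c("repetition01", "log_corrugator")),
    p1, label = "zygomaticus_corrugator")
  emg_preds <- c("log_corrugator", "log_frontalis", "log_zygomaticus")
  fits$judgment_moderation <- fit_glmm_logit(
    model_spec("judgment01",
               c("repetition01", "phase_c", "veridicality_c", emg_preds,
                 paste0("phase_c:", c("repetition01", emg_preds)),
                 paste0("veridicality_c:", c("repetition01", emg_preds))),
               family = "binomial"),
    wide, nagq = nagq, label = "judgment_moderation")
  comparisons <- list()
  for (p in 1:2) {
    dat <- if (p == 1L) p1 else p2
    # models 1 and 2 are compared by AIC/BIC, so both are fit on the
    # EMG-complete trials only
    dat_cc <- dat[stats::complete.cases(dat[, emg_preds]), ]
    m1 <- fit_glmm_logit(model_spec("judgment01", "repetition01",
                                    family = "binomial"),
                         dat_cc, nagq = nagq,
                         label = sprintf("judgment_phase%d_model1", p))
    m2 <- fit_glmm_logit(model_spec("judgment01",
                                    c("repetition01", emg_preds),
                                    family = "binomial"),
                         dat_cc, nagq = nagq,
                         label = sprintf("judgment_phase%d_model2", p))
    fits[[m1$label]] <- m1
    fits[[m2$label]] <- m2
    comparisons[[sprintf("judgment_phase%d", p)]] <- compare_models(list(m1, m2))
  }
  mediation <- NULL
  if (n_boot > 0L) {
    mediation <- mediate_effect(p1, treatment = "repetition01",
                                mediator = "log_corrugator",
                                outcome = "judgment01",
                                n_boot = n_boot, nagq = nagq, seed = seed)
  }
  structure(list(
    fits = fits,
    comparisons = comparisons,
    mediation = mediation,
    outlier_summary = attr(features, "outlier_summary"),
    settings = list(n_boot = n_boot, nagq = nagq, alpha = alpha,
                    log_rt = log_rt, seed = seed)
  ), class = "truth_report")
}

#' @export
print.truth_report <- function(x, ...) {
  cat(sprintf("<truth_report> %d models, %s mediation\n",
              length(x$fits), if (is.null(x$mediation)) "no" else "with"))
  for (f in x$fits) {
    sig <- x$fits[[f$label]]$coefficients
    stars <- sum(sig$p[sig$term != "(Intercept)"] < x$settings$alpha)
    cat(sprintf("  %-28s n=%6d  AIC=%10.1f  sig. terms: %d\n",
                f$label, f$n_obs, f$AIC, stars))
  }
  if (!is.null(x$mediation)) {
    cat(sprintf("  mediation ACME %.4f [%.4f, %.4f], p %.4g\n",
                x$mediation$acme, x$mediation$ci["acme", 1],
                x$mediation$ci["acme", 2], x$mediation$p_acme))
  }
  invisible(x)
}

report_coef_table <- function(report) {
  do.call(rbind, lapply(report$fits, function(f) {
    co <- f$coefficients
    co$model <- f$label
    co$family <- f$spec$family
    if (is.null(co$or)) co$or <- NA_real_
    co[, c("model", "family", "term", "b", "se", "stat", "p", "or")]
  }))
}

#' Write a model battery report to disk
#'
#' Emits one coefficients TSV per model (`<label>_coefficients.tsv`), a
#' combined `coefficients.tsv`, a machine-readable `coefficients.json`
#' (coefficients, information criteria, mediation block) and a
#' human-readable `summary.txt`.
#'
#' @param report a `truth_report` from [run_model_battery()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "truth_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  all_co <- report_coef_table(report)
  write_tsv(all_co, file.path(dir, "coefficients.tsv"))
  for (f in report$fits) {
    write_tsv(f$coefficients,
              file.path(dir, paste0(f$label, "_coefficients.tsv")))
  }
  js <- list(
    models = lapply(report$fits, function(f) {
      list(label = f$label, family = f$spec$family,
           formula = deparse(f$formula),
           coefficients = f$coefficients,
           ranef_var = f$ranef_var, logLik = f$logLik,
           AIC = f$AIC, BIC = f$BIC, n_obs = f$n_obs,
           n_groups = f$n_groups, converged = f$converged)
    }),
    comparisons = report$comparisons,
    outlier_summary = report$outlier_summary,
    settings = report$settings
  )
  if (!is.null(report$mediation)) {
    m <- report$mediation
    js$mediation <- list(acme = m$acme, ade = m$ade, total = m$total,
                         prop_mediated = m$prop_mediated,
                         ci = as.data.frame(m$ci), p_acme = m$p_acme,
                         n_boot_ok = m$n_boot_ok,
                         n_boot_failed = m$n_boot_failed)
  }
  jsonlite::write_json(js, file.path(dir, "coefficients.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c(sprintf("model battery report (%d models)", length(report$fits)),
           "")
  for (f in report$fits) {
    txt <- c(txt, utils::capture.output(print(f)), "")
  }
  for (nm in names(report$comparisons)) {
    txt <- c(txt, sprintf("comparison %s:", nm),
             utils::capture.output(print(report$comparisons[[nm]])), "")
  }
  if (!is.null(report$mediation)) {
    txt <- c(txt, utils::capture.output(print(report$mediation)))
  }
  writeLines(txt, file.path(dir, "summary.txt"))
  invisible(dir)
}
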