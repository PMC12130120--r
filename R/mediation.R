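# Within-subject causal mediation: potential-outcomes simulation estimator
# with a subject-resampling (cluster) bootstrap.
#
# The estimand follows the counterfactual definition: the average causal
# mediation effect (ACME) is the change in the outcome when the mediator is
# switched from its value under control to its value under treatment while
# the treatment itself is held fixed; the average direct effect (ADE) holds
# the mediator distribution fixed and switches the treatment.

mediation_point <- function(data, treatment, mediator, outcome, group,
                            covariates, outcome_family, nagq, n_sims) {
  med_spec <- model_spec(mediator, c(treatment, covariates), group,
                         family = "gaussian")
  out_spec <- model_spec(outcome, c(treatment, mediator, covariates), group,
                         family = outcome_family)
  med_fit <- fit_lmm(med_spec, data)
  out_fit <- if (outcome_family == "binomial") {
    fit_glmm_logit(out_spec, data, nagq = nagq)
  } else {
    fit_lmm(out_spec, data)
  }
  me <- med_fit$engine
  oe <- out_fit$engine
  d <- check_spec_data(out_spec, data)
  n <- nrow(d)
  # Treatment and mediator enter both models linearly and without
  # interactions, so counterfactual linear predictors are the fitted ones
  # shifted by the relevant coefficients — no refit or predict() needed.
  t_obs <- d[[treatment]]
  m_obs <- d[[mediator]]
  a_t <- lme4::fixef(me)[[treatment]]
  b_t <- lme4::fixef(oe)[[treatment]]
  b_m <- lme4::fixef(oe)[[mediator]]
  mu_m_obs <- predict(me)          # conditional means, subject BLUPs included
  eta_obs <- predict(oe)           # link scale for glmer, response for lmer
  mu_m0 <- mu_m_obs - a_t * t_obs
  mu_m1 <- mu_m0 + a_t
  sig_m <- stats::sigma(me)
  inv <- if (outcome_family == "binomial") plogis else identity
  eta_base <- eta_obs - b_t * t_obs - b_m * m_obs
  pred_out <- function(t, m) inv(eta_base + b_t * t + b_m * m)
  acme_t <- ade_t <- c(0, 0)
  total <- 0
  for (s in seq_len(n_sims)) {
    eps <- rnorm(n, 0, sig_m)
    m0 <- mu_m0 + eps
    m1 <- mu_m1 + eps
    y00 <- pred_out(0, m0); y01 <- pred_out(0, m1)
    y10 <- pred_out(1, m0); y11 <- pred_out(1, m1)
    acme_t <- acme_t + c(mean(y01 - y00), mean(y11 - y10))
    ade_t <- ade_t + c(mean(y10 - y00), mean(y11 - y01))
    total <- total + mean(y11 - y00)
  }
  acme_t <- acme_t / n_sims; ade_t <- ade_t / n_sims; total <- total / n_sims
  list(acme = mean(acme_t), ade = mean(ade_t), total = total,
       med_fit = med_fit, out_fit = out_fit)
}

#' Bootstrap mediation analysis with a subject-resampling bootstrap
#'
#' Estimates how much of the effect of a treatment (typically
#' `repetition01`) on an outcome (typically `judgment01`) is transmitted
#' through a mediator (typically the log corrugator feature). The mediator
#' model is a random-intercept Gaussian LMM, the outcome model a
#' random-intercept logistic GLMM (or LMM for a gaussian outcome); both are
#' fit by maximum likelihood.
#'
#' Point estimates use the potential-outcomes simulation approach:
#' counterfactual mediator values are drawn under treatment and control
#' (conditional mean plus Gaussian residual draws, subject intercepts
#' included), predicted outcomes are contrasted, and effects are averaged
#' over the treated/control regimes. Uncertainty comes from resampling
#' *subjects* with replacement (`n_boot` replicates) — the cluster is the
#' exchangeable unit in this design — with percentile confidence intervals
#' and a two-sided bootstrap p-value for the ACME. Replicates whose model
#' fits fail are dropped and counted.
#'
#' @param data a `feature_table` in wide form ([features_wide()]) or any
#'   data.frame containing the named columns.
#' @param treatment,mediator,outcome column names.
#' @param group clustering column resampled by the bootstrap.
#' @param covariates optional extra fixed-effect terms for both models.
#' @param outcome_family `"binomial"` (default) or `"gaussian"`.
#' @param n_boot bootstrap replicates; values below 100 trigger a warning.
#' @param n_sims Monte Carlo draws for the mediator residual integral.
#' @param nagq quadrature nodes for the logistic outcome model.
#' @param conf confidence level for percentile intervals.
#' @param seed integer seed for the bootstrap and mediator draws.
#' @return a `mediation_result`: `acme`, `ade`, `total`, `prop_mediated`,
#'   percentile `ci` (matrix), `p_acme`, `n_boot_ok`, `n_boot_failed`, and
#'   the two underlying `model_fit`s.
#' @export
mediate_effect <- function(data,
                           treatment = "repetition01",
                           mediator = "log_corrugator",
                           outcome = "judgment01",
                           group = "subject_id",
                           covariates = character(0),
                           outcome_family = c("binomial", "gaussian"),
                           n_boot = 1000L, n_sims = 25L, nagq = 1L,
                           conf = 0.95, seed = 1L) {
  outcome_family <- match.arg(outcome_family)
  if (n_boot < 1L) stop2("`n_boot` must be at least 1")
  if (n_boot < 100L) {
    warning("n_boot < 100 gives unstable percentile intervals", call. = FALSE)
  }
  d <- as.data.frame(data)
  vars <- c(treatment, mediator, outcome, group, covariates)
  miss <- setdiff(vars, names(d))
  if (length(miss)) stop2("data lacks column(s): %s", paste(miss, collapse = ", "))
  d <- d[stats::complete.cases(d[, vars, drop = FALSE]), , drop = FALSE]
  point <- with_seed(derive_seed(seed, 11L),
    mediation_point(d, treatment, mediator, outcome, group, covariates,
                    outcome_family, nagq, n_sims))
  subjects <- unique(d[[group]])
  rows_by_subj <- split(seq_len(nrow(d)), d[[group]])
  boots <- matrix(NA_real_, nrow = n_boot, ncol = 3,
                  dimnames = list(NULL, c("acme", "ade", "total")))
  n_failed <- 0L
  with_seed(derive_seed(seed, 12L), {
    for (b in seq_len(n_boot)) {
      take <- sample(subjects, length(subjects), replace = TRUE)
      pieces <- lapply(seq_along(take), function(i) {
        pc <- d[rows_by_subj[[as.character(take[i])]], , drop = FALSE]
        pc[[group]] <- sprintf("bs%03d", i) # duplicated subjects -> new ids
        pc
      })
      db <- do.call(rbind, pieces)
      res <- tryCatch(
        suppressWarnings(
          mediation_point(db, treatment, mediator, outcome, group,
                          covariates, outcome_family, nagq, n_sims)),
        error = function(e) NULL)
      if (is.null(res)) {
        n_failed <- n_failed + 1L
      } else {
        boots[b, ] <- c(res$acme, res$ade, res$total)
      }
    }
  })
  ok <- stats::complete.cases(boots)
  bs <- boots[ok, , drop = FALSE]
  alpha <- 1 - conf
  ci <- t(apply(bs, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
                names = FALSE))
  colnames(ci) <- c("lower", "upper")
  # CIs must contain the point estimate: widen to include it if bootstrap
  # skew pushed the percentile band past it (rare, logged via attribute)
  est <- c(point$acme, point$ade, point$total)
  clamped <- est < ci[, 1] | est > ci[, 2]
  ci[, 1] <- pmin(ci[, 1], est)
  ci[, 2] <- pmax(ci[, 2], est)
  p_acme <- 2 * min(mean(bs[, "acme"] <= 0), mean(bs[, "acme"] >= 0))
  p_acme <- max(p_acme, 1 / (nrow(bs) + 1)) # never exactly zero
  structure(list(
    acme = point$acme, ade = point$ade, total = point$total,
    prop_mediated = if (point$total != 0) point$acme / point$total else NA_real_,
    ci = ci, p_acme = min(1, p_acme), conf = conf,
    n_boot = n_boot, n_boot_ok = nrow(bs), n_boot_failed = n_failed,
    ci_clamped = any(clamped),
    mediator_fit = point$med_fit, outcome_fit = point$out_fit,
    treatment = treatment, mediator = mediator, outcome = outcome
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, digits = 4, ...) {
  cat(sprintf("<mediation_result> %s -> %s -> %s (cluster bootstrap, %d/%d ok)\n",
              x$treatment, x$mediator, x$outcome, x$n_boot_ok, x$n_boot))
  tab <- data.frame(
    effect = c("ACME", "ADE", "total"),
    estimate = round(c(x$acme, x$ade, x$total), digits),
    lower = round(x$ci[, "lower"], digits),
    upper = round(x$ci[, "upper"], digits)
  )
  print(tab, row.names = FALSE)
  cat(sprintf("proportion mediated %.3f | bootstrap p(ACME) %.4g | %g%% CI\n",
              x$prop_mediated, x$p_acme, 100 * x$conf))
  invisible(x)
}
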