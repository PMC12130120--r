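# Statistical layer: random-intercept linear and logistic mixed models by
# maximum likelihood, odds ratios, AIC/BIC comparison.
#
# Fitting is delegated to lme4 (the standard multilevel engine in this
# field); this module owns the model contracts: ML (never REML), Laplace /
# adaptive Gauss-Hermite integration for the logistic family, documented
# p-value approximations, convergence surfaced rather than swallowed.

#' Specify a random-intercept model
#'
#' @param outcome outcome column name.
#' @param terms character vector of fixed-effect terms (interactions as
#'   `"a:b"`); use `character(0)` for an intercept-only model.
#' @param group grouping-factor column (random intercept), default subject.
#' @param family `"gaussian"` or `"binomial"` (logit link).
#' @return a `model_spec` object.
#' @export
model_spec <- function(outcome, terms = character(0), group = "subject_id",
                       family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  stopifnot(is.character(outcome), length(outcome) == 1L,
            is.character(terms), is.character(group), length(group) == 1L)
  structure(list(outcome = outcome, terms = terms, group = group,
                 family = family),
            class = "model_spec")
}

spec_formula <- function(spec) {
  rhs <- if (length(spec$terms)) paste(spec$terms, collapse = " + ") else "1"
  as.formula(sprintf("%s ~ %s + (1 | %s)", spec$outcome, rhs, spec$group))
}

check_spec_data <- function(spec, data) {
  vars <- unique(c(spec$outcome, spec$group,
                   unlist(strsplit(spec$terms, ":", fixed = TRUE))))
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    stop2("data lacks column(s): %s", paste(miss, collapse = ", "))
  }
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  if (length(unique(d[[spec$group]])) < 2L) {
    stop2("need at least 2 groups in `%s`", spec$group)
  }
  d
}

new_model_fit <- function(fit, spec, label = NULL) {
  co <- summary(fit)$coefficients
  stat_name <- if (spec$family == "gaussian") "t" else "z"
  stat <- co[, 3]
  p <- if (spec$family == "gaussian") 2 * pnorm(-abs(stat)) else co[, 4]
  vc <- lme4::VarCorr(fit)
  ranef_var <- as.numeric(vc[[spec$group]][1, 1])
  ll <- logLik(fit)
  # a singular (variance = 0) fit is a legitimate boundary ML solution, not
  # a convergence failure; it is flagged separately
  msgs <- fit@optinfo$conv$lme4$messages %||% character(0)
  msgs <- msgs[!grepl("singular", msgs, ignore.case = TRUE)]
  conv <- length(msgs) == 0L && (fit@optinfo$conv$opt %||% 0L) == 0L
  singular <- lme4::isSingular(fit)
  coefs <- data.frame(term = rownames(co), b = unname(co[, 1]),
                      se = unname(co[, 2]), stat = unname(stat),
                      p = unname(p), stringsAsFactors = FALSE)
  if (spec$family == "binomial") coefs$or <- exp(coefs$b)
  separation <- spec$family == "binomial" && any(abs(coefs$b) > 15)
  structure(list(
    label = label %||% spec$outcome,
    spec = spec,
    formula = spec_formula(spec),
    coefficients = coefs,
    ranef_var = ranef_var,
    sigma = if (spec$family == "gaussian") stats::sigma(fit) else NA_real_,
    logLik = as.numeric(ll),
    df = attr(ll, "df"),
    AIC = AIC(fit), BIC = BIC(fit),
    n_obs = stats::nobs(fit),
    n_groups = lme4::ngrps(fit)[[spec$group]],
    converged = conv,
    singular = singular,
    separation = separation,
    stat_name = stat_name,
    engine = fit
  ), class = "model_fit")
}

# Degenerate branch of both fitters: with the random-intercept variance
# pinned at zero the marginal likelihood is that of an ordinary fixed-effects
# model, so the fit is delegated to lm()/glm() and repackaged. Used for
# boundary checks against closed-form OLS / IRLS.
new_pinned_fit <- function(spec, d, label) {
  rhs <- if (length(spec$terms)) paste(spec$terms, collapse = " + ") else "1"
  fml <- as.formula(sprintf("%s ~ %s", spec$outcome, rhs))
  if (spec$family == "gaussian") {
    fit <- stats::lm(fml, data = d)
    co <- summary(fit)$coefficients
    stat <- co[, 3]
    p <- 2 * pnorm(-abs(stat))
    sig <- sqrt(mean(stats::residuals(fit)^2)) # ML, not n - p
  } else {
    fit <- stats::glm(fml, data = d, family = binomial())
    co <- summary(fit)$coefficients
    stat <- co[, 3]
    p <- co[, 4]
    sig <- NA_real_
  }
  ll <- logLik(fit)
  coefs <- data.frame(term = rownames(co), b = unname(co[, 1]),
                      se = unname(co[, 2]), stat = unname(stat),
                      p = unname(p), stringsAsFactors = FALSE)
  if (spec$family == "binomial") coefs$or <- exp(coefs$b)
  structure(list(
    label = paste0(label %||% spec$outcome, " (variance pinned to 0)"),
    spec = spec, formula = fml, coefficients = coefs,
    ranef_var = 0, sigma = sig,
    logLik = as.numeric(ll), df = attr(ll, "df"),
    AIC = AIC(fit), BIC = BIC(fit),
    n_obs = stats::nobs(fit), n_groups = length(unique(d[[spec$group]])),
    converged = fit$converged %||% TRUE, singular = TRUE,
    separation = spec$family == "binomial" && any(abs(coefs$b) > 15),
    stat_name = if (spec$family == "gaussian") "t" else "z",
    engine = fit
  ), class = "model_fit")
}

#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' Gaussian outcome, subject random intercept, estimated by full ML (not
#' REML) so that nested models are comparable by AIC/BIC and likelihood.
#' Fixed-effect p-values use the large-sample normal approximation of the
#' t statistic (`2 * pnorm(-|t|)`); with the cluster counts this package
#' targets (tens of subjects, thousands of trials) the difference from
#' finite-df corrections is negligible, and the method is recorded in the
#' fit object.
#'
#' @param spec a gaussian [model_spec()].
#' @param data data.frame (typically from [features_wide()] or a
#'   `feature_table`).
#' @param label optional label used in reports.
#' @param pin_variance_zero fit with the random-intercept variance fixed at
#'   zero (the model then reduces to an ordinary fixed-effects fit); used
#'   for boundary diagnostics.
#' @return a `model_fit` object: coefficient table (`term`, `b`, `se`,
#'   `stat`, `p`), random-intercept variance, residual `sigma`, `logLik`,
#'   `AIC`, `BIC`, `n_obs`, `n_groups`, `converged`.
#' @export
fit_lmm <- function(spec, data, label = NULL, pin_variance_zero = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "gaussian") stop2("fit_lmm() requires a gaussian spec")
  d <- check_spec_data(spec, data)
  if (!is.numeric(d[[spec$outcome]])) stop2("outcome must be numeric")
  if (pin_variance_zero) return(new_pinned_fit(spec, d, label))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- lme4::lmer(spec_formula(spec), data = d, REML = FALSE,
                    control = ctrl)
  out <- new_model_fit(fit, spec, label)
  if (!out$converged) {
    warning(sprintf("model '%s' did not converge cleanly", out$label),
            call. = FALSE)
  }
  out
}

#' Fit a random-intercept logistic mixed model
#'
#' Binomial outcome with logit link; the subject random intercept is
#' integrated out by adaptive Gauss-Hermite quadrature with `nagq` nodes.
#' The default `nagq = 1` is the Laplace approximation. Estimates with
#' `|b| > 15` are flagged as likely separation.
#'
#' @param spec a binomial [model_spec()].
#' @param data data.frame; outcome must be 0/1.
#' @param nagq number of quadrature nodes (1 = Laplace).
#' @param label optional label used in reports.
#' @param pin_variance_zero fit with the random-intercept variance fixed at
#'   zero (plain logistic regression); used for boundary diagnostics.
#' @return a `model_fit` (see [fit_lmm()]); coefficient table gains an `or`
#'   column with `exp(b)`.
#' @export
fit_glmm_logit <- function(spec, data, nagq = 1L, label = NULL,
                           pin_variance_zero = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "binomial") stop2("fit_glmm_logit() requires a binomial spec")
  d <- check_spec_data(spec, data)
  y <- d[[spec$outcome]]
  if (!all(y %in% c(0, 1))) stop2("outcome must be coded 0/1")
  if (pin_variance_zero) return(new_pinned_fit(spec, d, label))
  ctrl <- lme4::glmerControl(check.conv.singular = "ignore")
  fit <- lme4::glmer(spec_formula(spec), data = d, family = binomial(),
                     nAGQ = as.integer(nagq), control = ctrl)
  out <- new_model_fit(fit, spec, label)
  if (out$separation) {
    warning(sprintf("model '%s': |b| > 15 suggests separation", out$label),
            call. = FALSE)
  }
  if (!out$converged) {
    warning(sprintf("model '%s' did not converge cleanly", out$label),
            call. = FALSE)
  }
  out
}

#' Odds ratio from a log-odds coefficient
#'
#' @param b log-odds estimate (finite numeric).
#' @return `exp(b)`.
#' @examples
#' odds_ratio(0.924) # 2.52
#' @export
odds_ratio <- function(b) {
  check_finite_vector(b, "b")
  exp(b)
}

#' Compare model fits by information criteria
#'
#' Reports AIC and BIC per fit with deltas relative to the best (smallest)
#' value of each criterion; a decrease indicates improved fit. Errors if the
#' fits were not estimated on the same number of observations, and flags
#' rankings on which the two criteria disagree.
#'
#' @param fits list of `model_fit` objects.
#' @return data.frame (`label`, `logLik`, `df`, `AIC`, `dAIC`, `BIC`,
#'   `dBIC`) with attribute `"criteria_agree"`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "model_fit")))
  n_obs <- vapply(fits, `[[`, 0, "n_obs")
  if (length(unique(n_obs)) != 1L) {
    stop2("fits use differing numbers of observations (%s); not comparable",
          paste(unique(n_obs), collapse = ", "))
  }
  tab <- data.frame(
    label = vapply(fits, `[[`, "", "label"),
    logLik = vapply(fits, `[[`, 0, "logLik"),
    df = vapply(fits, `[[`, 0, "df"),
    AIC = vapply(fits, `[[`, 0, "AIC"),
    BIC = vapply(fits, `[[`, 0, "BIC"),
    stringsAsFactors = FALSE
  )
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab$dBIC <- tab$BIC - min(tab$BIC)
  attr(tab, "criteria_agree") <- identical(order(tab$AIC), order(tab$BIC))
  tab
}

#' @export
print.model_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<model_fit: %s> %s | %s family, ML, random intercept (%s)\n",
              x$label, deparse(x$formula), x$spec$family, x$spec$group))
  co <- x$coefficients
  co$b <- round(co$b, digits); co$se <- round(co$se, digits)
  co$stat <- round(co$stat, digits)
  co$p <- signif(co$p, 3)
  if (!is.null(co$or)) co$or <- round(co$or, 2)
  names(co)[names(co) == "stat"] <- x$stat_name
  print(co, row.names = FALSE)
  cat(sprintf("ranef var %.4f | logLik %.1f | AIC %.1f | BIC %.1f | n %d, groups %d%s\n",
              x$ranef_var, x$logLik, x$AIC, x$BIC, x$n_obs, x$n_groups,
              if (x$converged) "" else " | NOT CONVERGED"))
  invisible(x)
}
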