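# Mixed-model layer: boundary oracles, likelihood sanity, quadrature,
# information criteria, odds ratios.

test_that("LMM with a pinned-zero variance equals closed-form OLS", {
  d <- make_toy_features(tau = 0) # no true between-subject variance
  fit <- fit_lmm(model_spec("y", "repetition01"), d,
                 pin_variance_zero = TRUE)
  X <- cbind(1, d$repetition01)
  expect_equal(fit$coefficients$b, ols_oracle(X, d$y), tolerance = 1e-9)
  # freely estimated fit lands on the same boundary solution here
  free <- fit_lmm(model_spec("y", "repetition01"), d)
  expect_true(free$singular)
  expect_equal(free$coefficients$b, ols_oracle(X, d$y), tolerance = 1e-6)
})

test_that("logistic GLMM with a pinned-zero variance equals hand-rolled IRLS", {
  d <- make_toy_features()
  fit <- fit_glmm_logit(model_spec("z", "repetition01", family = "binomial"),
                        d, pin_variance_zero = TRUE)
  X <- cbind(1, d$repetition01)
  expect_equal(fit$coefficients$b, irls_logit_oracle(X, d$z),
               tolerance = 1e-6)
})

test_that("balanced coin-flip data gives a near-zero intercept", {
  set.seed(61)
  d <- data.frame(subject_id = rep(1:20, each = 50))
  d$z <- rbinom(1000, 1, 0.5)
  fit <- fit_glmm_logit(model_spec("z", character(0), family = "binomial"), d)
  co <- fit$coefficients
  expect_lt(abs(co$b[1]), 3 * co$se[1])
})

test_that("fitted LMM is a local maximum of the exact marginal likelihood", {
  d <- make_toy_features(n_subjects = 10, n_trials = 30, seed = 202)
  fit <- fit_lmm(model_spec("y", "repetition01"), d)
  X <- cbind(1, d$repetition01)
  beta <- fit$coefficients$b
  tau2 <- fit$ranef_var
  sigma2 <- fit$sigma^2
  ll_hat <- lmm_loglik_oracle(beta, tau2, sigma2, X, d$y, d$subject_id)
  # the oracle reproduces lme4's logLik at the fitted parameters
  expect_equal(ll_hat, fit$logLik, tolerance = 1e-6)
  # ... and no perturbed parameter vector does better
  set.seed(7)
  for (i in 1:100) {
    pb <- beta + rnorm(2, 0, 0.05)
    pt2 <- max(1e-8, tau2 * exp(rnorm(1, 0, 0.2)))
    ps2 <- sigma2 * exp(rnorm(1, 0, 0.2))
    expect_lte(lmm_loglik_oracle(pb, pt2, ps2, X, d$y, d$subject_id), ll_hat)
  }
})

test_that("high-order quadrature GLMM maximizes the quadrature oracle likelihood", {
  d <- make_toy_features(n_subjects = 12, n_trials = 30, seed = 404)
  fit <- fit_glmm_logit(model_spec("z", "repetition01", family = "binomial"),
                        d, nagq = 25)
  X <- cbind(1, d$repetition01)
  beta <- fit$coefficients$b
  tau <- sqrt(fit$ranef_var)
  ll_hat <- glmm_loglik_oracle(beta, tau, X, d$z, d$subject_id)
  expect_equal(ll_hat, fit$logLik, tolerance = 1e-4)
  set.seed(8)
  for (i in 1:100) {
    pb <- beta + rnorm(2, 0, 0.1)
    pt <- max(1e-6, tau * exp(rnorm(1, 0, 0.2)))
    expect_lte(glmm_loglik_oracle(pb, pt, X, d$z, d$subject_id),
               ll_hat + 1e-8)
  }
})

test_that("Laplace and 21-node quadrature agree at analysis scale", {
  feats <- simulate_features(design_config(n_subjects = 40), seed = 55)
  wide <- features_wide(feats)
  p1 <- wide[wide$phase == 1, ]
  spec <- model_spec("judgment01", "repetition01", family = "binomial")
  f1 <- fit_glmm_logit(spec, p1, nagq = 1)
  f21 <- fit_glmm_logit(spec, p1, nagq = 21)
  expect_lt(max(abs(f1$coefficients$b - f21$coefficients$b)), 0.02)
})

test_that("adding a pure-noise predictor never decreases the log-likelihood", {
  d <- make_toy_features(seed = 99)
  set.seed(100)
  d$noise <- rnorm(nrow(d))
  f0 <- fit_lmm(model_spec("y", "repetition01"), d)
  f1 <- fit_lmm(model_spec("y", c("repetition01", "noise")), d)
  expect_gte(f1$logLik, f0$logLik - 1e-8)
})

test_that("information criteria satisfy their definitions and comparisons line up", {
  fake_fit <- function(label, ll, k, n) {
    structure(list(label = label, logLik = ll, df = k,
                   AIC = -2 * ll + 2 * k, BIC = -2 * ll + k * log(n),
                   n_obs = n),
              class = "model_fit")
  }
  # logLik -10, k = 3 -> AIC 26; with n = 100 -> BIC 20 + 3 ln(100)
  f <- fake_fit("a", -10, 3, 100)
  expect_equal(f$AIC, 26)
  expect_equal(f$BIC, 20 + 3 * log(100), tolerance = 1e-10)
  expect_equal(f$BIC, 33.81551, tolerance = 1e-5)
  tab <- compare_models(list(f, fake_fit("b", -10, 3, 100)))
  expect_equal(tab$dAIC, c(0, 0))
  expect_error(compare_models(list(f, fake_fit("c", -9, 3, 99))),
               "differing numbers")
  # real fits: k counts fixed effects + variance parameters (+ residual)
  d <- make_toy_features(seed = 31)
  fit <- fit_lmm(model_spec("y", "repetition01"), d)
  k <- nrow(fit$coefficients) + 1 + 1
  expect_equal(fit$df, k)
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * k, tolerance = 1e-10)
  expect_equal(fit$BIC, -2 * fit$logLik + k * log(fit$n_obs),
               tolerance = 1e-10)
  gfit <- fit_glmm_logit(model_spec("z", "repetition01", family = "binomial"), d)
  expect_equal(gfit$df, nrow(gfit$coefficients) + 1)
  expect_equal(gfit$AIC, -2 * gfit$logLik + 2 * gfit$df, tolerance = 1e-10)
})

test_that("odds ratios are exp(b)", {
  expect_equal(odds_ratio(0), 1)
  expect_equal(round(odds_ratio(0.924), 2), 2.52)
  expect_equal(round(odds_ratio(-0.135), 2), 0.87)
  b <- rnorm(20)
  expect_equal(odds_ratio(b), exp(b))
})

test_that("missing columns and bad outcomes are rejected with useful messages", {
  d <- make_toy_features()
  expect_error(fit_lmm(model_spec("nope", "repetition01"), d), "nope")
  expect_error(fit_glmm_logit(model_spec("y", "repetition01",
                                         family = "binomial"), d), "0/1")
  expect_error(fit_lmm(model_spec("y", "repetition01", group = "absent"), d),
               "absent")
  expect_error(fit_glmm_logit(model_spec("z", family = "gaussian"), d),
               "binomial")
})
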