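# Independent oracles used across the suite. Each one is a deliberately
# naive route to the same quantity as the implementation under test: closed
# forms, per-sample scans, normal-equation algebra. None of them call the
# package's own code paths.

# ordinary least squares by normal equations
ols_oracle <- function(X, y) {
  as.numeric(solve(crossprod(X), crossprod(X, y)))
}

# logistic regression by hand-rolled iteratively reweighted least squares
irls_logit_oracle <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- as.numeric(solve(crossprod(X, w * X), crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < tol) return(beta_new)
    beta <- beta_new
  }
  beta
}

# active-run detection by an explicit per-sample scan with run counting
brute_force_active <- function(env, threshold, min_n) {
  n <- length(env)
  out <- logical(n)
  i <- 1L
  while (i <= n) {
    if (env[i] > threshold) {
      j <- i
      while (j < n && env[j + 1L] > threshold) j <- j + 1L
      if (j - i + 1L >= min_n) out[i:j] <- TRUE
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# marginal log-likelihood of a gaussian random-intercept model, evaluated
# directly through the per-group covariance sigma2*I + tau2*J
# (Sherman-Morrison for the quadratic form, closed-form determinant)
lmm_loglik_oracle <- function(beta, tau2, sigma2, X, y, groups) {
  r <- y - as.numeric(X %*% beta)
  ll <- 0
  for (g in unique(groups)) {
    rg <- r[groups == g]
    ng <- length(rg)
    logdet <- (ng - 1) * log(sigma2) + log(sigma2 + ng * tau2)
    quad <- sum(rg^2) / sigma2 -
      (tau2 / (sigma2 * (sigma2 + ng * tau2))) * sum(rg)^2
    ll <- ll - 0.5 * (ng * log(2 * pi) + logdet + quad)
  }
  ll
}

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen decomposition of the
# Jacobi matrix for the physicists' Hermite polynomials)
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# marginal log-likelihood of a logistic random-intercept model by plain
# (non-adaptive) Gauss-Hermite quadrature
glmm_loglik_oracle <- function(beta, tau, X, y, groups, n_nodes = 80) {
  gh <- gauss_hermite(n_nodes)
  u <- sqrt(2) * tau * gh$nodes
  w <- gh$weights / sqrt(pi)
  eta_fix <- as.numeric(X %*% beta)
  ll <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    contrib <- vapply(seq_along(u), function(k) {
      p <- plogis(eta_fix[idx] + u[k])
      exp(sum(stats::dbinom(y[idx], 1, p, log = TRUE)))
    }, 0)
    ll <- ll + log(sum(w * contrib))
  }
  ll
}

# a small deterministic multilevel dataset with known structure, used by
# the inference tests
make_toy_features <- function(n_subjects = 12, n_trials = 40, seed = 101,
                              beta_rep = -0.2, tau = 0.4, sigma = 0.8,
                              beta0 = 2.5) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    d <- expand.grid(subject_id = seq_len(n_subjects),
                     trial = seq_len(n_trials))
    d$repetition01 <- rbinom(nrow(d), 1, 0.5)
    u <- rnorm(n_subjects, 0, tau)
    d$y <- beta0 + u[d$subject_id] + beta_rep * d$repetition01 +
      rnorm(nrow(d), 0, sigma)
    d$z <- rbinom(nrow(d), 1, plogis(0.2 + u[d$subject_id] +
                                       0.9 * d$repetition01))
    d
  })
}

# analytic trial fixture: one noiseless rectangular burst with a sine
# carrier; returns the event table, recording and the closed-form expected
# feature (AUC of the rectified burst over the response window)
constant_burst_expectation <- function(amp, dur_samples, freq, fs) {
  carrier <- abs(amp * sin(2 * pi * freq * seq_len(dur_samples) / fs))
  sum(carrier) * (1000 / fs)
}

# all-gaussian synthetic mediation world with known paths:
# M = a*T + u_subj + e;  Y = c*T + b*M + v_subj + f
make_mediation_data <- function(n_subjects = 30, n_trials = 30, a = 0.5,
                                b = 0.4, cpr = 0.3, seed = 1,
                                binary_outcome = FALSE) {
  set.seed(seed)
  d <- expand.grid(subject_id = seq_len(n_subjects),
                   trial = seq_len(n_trials))
  d$repetition01 <- rbinom(nrow(d), 1, 0.5)
  u <- rnorm(n_subjects, 0, 0.3)
  v <- rnorm(n_subjects, 0, 0.3)
  d$log_corrugator <- a * d$repetition01 + u[d$subject_id] +
    rnorm(nrow(d), 0, 0.7)
  eta <- cpr * d$repetition01 + b * d$log_corrugator + v[d$subject_id]
  if (binary_outcome) {
    d$judgment01 <- rbinom(nrow(d), 1, plogis(eta))
  } else {
    d$judgment01 <- eta + rnorm(nrow(d), 0, 0.8)
  }
  d
}

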