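sim_sfa <- function(n, beta, sigma_v, sigma_u, seed) {
  set.seed(seed)
  Z <- cbind(rnorm(n), rnorm(n))
  S <- drop(cbind(1, Z) %*% beta) + rnorm(n, 0, sigma_v) +
    abs(rnorm(n, 0, sigma_u))
  list(S = S, Z = Z)
}

test_that("no-inefficiency data drive gamma to zero and beta to OLS", {
  set.seed(4)
  n <- 500
  Z <- cbind(rnorm(n), rnorm(n))
  S <- drop(cbind(1, Z) %*% c(1, 2, -1)) + rnorm(n, 0, 0.5)
  m <- fit_slack_frontier(S, Z)
  ols <- unname(stats::lm.fit(cbind(1, Z), S)$coefficients)
  # slopes revert to OLS; the inefficiency share is not distinguishable
  # from zero (gamma and the intercept trade off along a likelihood
  # ridge near the boundary, so gamma itself is weakly identified)
  expect_equal(unname(m$beta)[-1], ols[-1], tolerance = 1e-3)
  expect_false(lr_mixed_chisq_test(m$lr_stat, 1)$significant)
  expect_gte(m$loglik, m$loglik_ols - 1e-6)
})

test_that("the half-normal MLE recovers known parameters at n = 2000", {
  d <- sim_sfa(2000, c(2, -1, 0.5), sigma_v = 0.5, sigma_u = 1, seed = 11)
  m <- fit_slack_frontier(d$S, d$Z)
  expect_true(m$converged)
  expect_true(all(abs(m$beta - c(2, -1, 0.5)) < 0.1))
  expect_lt(abs(m$gamma - 0.8), 0.07)      # gamma = 1 / (1 + 0.25) = 0.8
  # the optimum dominates the OLS-beta / gamma = 0.5 start
  Zi <- cbind(1, d$Z)
  ols <- stats::lm.fit(Zi, d$S)
  s2 <- sum(ols$residuals^2) / length(d$S)
  par0 <- c(ols$coefficients, log(s2 / (1 - 2 * 0.5 / pi)),
            stats::qlogis(0.5))
  expect_gte(m$loglik, ebmgml:::sfa_loglik(par0, d$S, Zi))
})

test_that("estimation error shrinks with the sample size", {
  err <- vapply(c(200, 2000), function(n) {
    d <- sim_sfa(n, c(2, -1, 0.5), 0.5, 1, seed = 99)
    m <- fit_slack_frontier(d$S, d$Z)
    max(abs(m$beta - c(2, -1, 0.5)))
  }, numeric(1))
  expect_lt(err[2], err[1] + 0.02)
})

test_that("JLMS decomposition reconstructs slacks exactly and keeps u nonnegative", {
  d <- sim_sfa(400, c(1, 0.5, -0.5), 0.4, 0.8, seed = 21)
  m <- fit_slack_frontier(d$S, d$Z)
  dec <- jlms_decompose(d$S, d$Z, m)
  expect_lt(max(abs(dec$f_hat + dec$u_hat + dec$v_hat - d$S)), 1e-10)
  expect_true(all(dec$u_hat >= 0))
})

test_that("mean conditional inefficiency matches the half-normal moment", {
  sigma_u <- 1
  d <- sim_sfa(200, c(2, -1, 0.5), 0.5, sigma_u, seed = 31)
  m <- fit_slack_frontier(d$S, d$Z)
  dec <- jlms_decompose(d$S, d$Z, m)
  target <- sigma_u * sqrt(2 / pi)
  expect_lt(abs(mean(dec$u_hat) - target) / target, 0.15)
})

test_that("in the noise-dominant limit u collapses and v absorbs the residual", {
  set.seed(41)
  n <- 300
  Z <- cbind(rnorm(n))
  S <- drop(cbind(1, Z) %*% c(1, 1)) + rnorm(n, 0, 1)  # sigma_u = 0
  m <- fit_slack_frontier(S, Z)
  dec <- jlms_decompose(S, Z, m)
  # u_hat is nearly flat relative to the composed residual, so v carries
  # essentially all the variation
  eps <- S - dec$f_hat
  expect_lt(sd(dec$u_hat), 0.3 * sd(eps))
  expect_gt(cor(dec$v_hat, eps), 0.99)
})

test_that("input adjustment harmonizes to the worst environment and luck", {
  expect_equal(adjust_inputs(c(10, 10), f_hat = c(3, 5),
                             v_hat = c(0.2, -0.1)),
               c(12.0, 10.3))
  # homogeneous environment and luck: no adjustment at all
  x <- c(4, 7, 1)
  expect_equal(adjust_inputs(x, rep(2, 3), rep(-1, 3)), x)
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    x <- runif(n, 5, 10); f <- rnorm(n); v <- rnorm(n, 0, 0.3)
    xs <- adjust_inputs(x, f, v)
    expect_true(all(xs >= x - 1e-12))
    if (which.max(f) == which.max(v)) {
      expect_equal(min(xs - x), 0)
      expect_equal(which.min(xs - x), which.max(f))
    }
  }
  expect_error(adjust_inputs(1:3, 1:2, 1:3), "equal length")
})

test_that("mixed chi-square boundary test has the textbook critical value", {
  expect_false(lr_mixed_chisq_test(0, 1)$significant)
  expect_equal(lr_mixed_chisq_test(0, 1)$p_value, 1)
  kp <- lr_mixed_chisq_test(3, 1, level = 0.05)
  expect_equal(kp$critical, 2.706, tolerance = 1e-3)
  expect_true(kp$significant)
  # df = 2 mixture: 1/4 chi0 + 1/2 chi1 + 1/4 chi2
  kp2 <- lr_mixed_chisq_test(1, 2, level = 0.05)
  x <- kp2$critical
  expect_equal(0.5 * pchisq(x, 1, lower.tail = FALSE) +
                 0.25 * pchisq(x, 2, lower.tail = FALSE), 0.05,
               tolerance = 1e-8)
  expect_error(lr_mixed_chisq_test(1, 0), "df")
})

test_that("the boundary test holds its size under the null", {
  set.seed(61)
  n <- 100; reps <- 400
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    Z <- cbind(rnorm(n))
    S <- 1 + Z[, 1] + rnorm(n, 0, 1)       # gamma = 0 truth
    m <- fit_slack_frontier(S, Z, gamma_starts = c(0.2, 0.7))
    rej[r] <- lr_mixed_chisq_test(m$lr_stat, 1)$significant
  }
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("a covariate that inflates slack gets a positive coefficient", {
  set.seed(71)
  n <- 300
  Z <- cbind(rnorm(n), rnorm(n))
  S <- 2 + 1.5 * Z[, 1] - 0.8 * Z[, 2] + rnorm(n, 0, 0.3) +
    abs(rnorm(n, 0, 0.8))
  m <- fit_slack_frontier(S, Z)
  expect_gt(m$beta[2], 0)
  expect_lt(m$beta[3], 0)
})
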