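# Stage 2: stochastic frontier regression of stage-one input slacks on
# environmental covariates.
#
# Model (per input variable, pooled over all unit-period observations):
#
#   S_i = z_i' beta + v_i + u_i,   v ~ N(0, sigma_v^2),  u ~ |N(0, sigma_u^2)|
#
# Slack sitting above the environmental frontier is management
# inefficiency (u); the symmetric part is statistical noise (v).  The
# likelihood is the half-normal composed-error ("cost frontier" sign
# convention: u enters with +) and parameters are reported in the
# FRONTIER 4.1 parameterization sigma^2 = sigma_u^2 + sigma_v^2,
# gamma = sigma_u^2 / sigma^2.

sfa_loglik <- function(par, S, Zi) {
  p <- ncol(Zi)
  beta <- par[seq_len(p)]
  sigma_sq <- exp(par[p + 1L])
  gamma <- stats::plogis(par[p + 2L])
  sigma <- sqrt(sigma_sq)
  lambda <- sqrt(gamma / (1 - gamma))
  eps <- S - drop(Zi %*% beta)
  sum(log(2) - log(sigma) +
        stats::dnorm(eps / sigma, log = TRUE) +
        stats::pnorm(eps * lambda / sigma, log.p = TRUE))
}

#' Fit a half-normal stochastic frontier to input slacks
#'
#' Maximum-likelihood estimation of the slack frontier
#' `S = Z beta + v + u` with `u >= 0` half-normal.  Starting values are
#' corrected OLS (COLS) with a multi-start over gamma; optimization is
#' quasi-Newton (BFGS) on the unconstrained parameterization
#' `(beta, log sigma^2, logit gamma)`.
#'
#' @param S numeric vector of slacks (one input variable, all
#'   observations).
#' @param Z covariate matrix or data frame (no intercept column; one is
#'   added).
#' @param gamma_starts gamma values for the multi-start (default
#'   0.1/0.5/0.9).
#' @param reltol convergence tolerance passed to [stats::optim()].
#' @return an object of class `sfa_model`: coefficients `beta` (with
#'   intercept), `sigma_sq`, `gamma`, `sigma_u_sq`, `sigma_v_sq`,
#'   `loglik`, `loglik_ols`, `lr_stat` (one-sided LR against OLS),
#'   `beta_se` and `beta_t` (from the observed information), `converged`,
#'   `gamma_at_boundary`, `n_obs`.
#' @export
fit_slack_frontier <- function(S, Z, gamma_starts = c(0.1, 0.5, 0.9),
                               reltol = 1e-12) {
  Z <- as.matrix(Z)
  n <- length(S)
  if (nrow(Z) != n) stop("length(S) must equal nrow(Z)")
  p_env <- ncol(Z)
  if (n < p_env + 3L) stop("too few observations for the covariate count")
  Zi <- cbind(`(Intercept)` = 1, Z)
  if (qr(Zi)$rank < ncol(Zi)) {
    stop("covariate matrix is rank-deficient after adding an intercept")
  }
  cn <- colnames(Zi)

  ols <- stats::lm.fit(Zi, S)
  e <- ols$residuals
  s2_ols <- sum(e^2) / n
  loglik_ols <- sum(stats::dnorm(e, 0, sqrt(s2_ols), log = TRUE))

  # COLS sigma_u start from the third central moment (positive skew under
  # the cost-frontier sign convention), floored at a small positive value
  m3 <- mean(e^3)
  su_cols <- if (m3 > 0) (m3 / (sqrt(2 / pi) * (4 / pi - 1)))^(1 / 3) else
    0.1 * sqrt(s2_ols)

  best <- NULL
  for (g0 in gamma_starts) {
    sig2_0 <- s2_ols / (1 - (2 / pi) * g0)
    b0 <- ols$coefficients
    b0[1] <- b0[1] - sqrt(g0 * sig2_0) * sqrt(2 / pi)  # shift intercept by E[u]
    par0 <- c(b0, log(sig2_0), stats::qlogis(g0))
    fit <- tryCatch(
      stats::optim(par0, sfa_loglik, S = S, Zi = Zi, method = "BFGS",
                   control = list(fnscale = -1, reltol = reltol,
                                  maxit = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value > best$value) best <- fit
  }
  # one extra start from the COLS skewness estimate of gamma
  g_cols <- min(0.95, max(0.05, su_cols^2 / (su_cols^2 + s2_ols)))
  sig2_0 <- s2_ols / (1 - (2 / pi) * g_cols)
  b0 <- ols$coefficients
  b0[1] <- b0[1] - sqrt(g_cols * sig2_0) * sqrt(2 / pi)
  fit <- tryCatch(
    stats::optim(c(b0, log(sig2_0), stats::qlogis(g_cols)), sfa_loglik,
                 S = S, Zi = Zi, method = "BFGS",
                 control = list(fnscale = -1, reltol = reltol, maxit = 1000)),
    error = function(e) NULL)
  if (!is.null(fit) && (is.null(best) || fit$value > best$value)) best <- fit
  if (is.null(best)) stop("stochastic frontier optimization failed to start")

  # the gamma -> 0 boundary of the likelihood IS the OLS model; if no
  # interior candidate beats it, return the boundary solution rather than
  # an optimizer iterate stranded marginally below it
  if (best$value < loglik_ols) {
    best <- list(par = c(ols$coefficients, log(s2_ols),
                         stats::qlogis(1e-8)),
                 value = loglik_ols, convergence = 0L)
  }
  par <- best$par
  beta <- stats::setNames(par[seq_len(ncol(Zi))], cn)
  sigma_sq <- exp(par[ncol(Zi) + 1L])
  gamma <- stats::plogis(par[ncol(Zi) + 2L])
  loglik <- best$value
  converged <- best$convergence == 0 && loglik >= loglik_ols - 1e-6

  # observed information for the beta block (numerical Hessian)
  H <- tryCatch(
    stats::optimHess(par, sfa_loglik, S = S, Zi = Zi),
    error = function(e) NULL)
  beta_se <- rep(NA_real_, length(beta))
  if (!is.null(H)) {
    V <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(V)) {
      d <- diag(V)[seq_along(beta)]
      d[!is.finite(d) | d <= 0] <- NA_real_
      beta_se <- sqrt(d)
    }
  }

  structure(list(
    beta = beta,
    sigma_sq = sigma_sq,
    gamma = gamma,
    sigma_u_sq = gamma * sigma_sq,
    sigma_v_sq = (1 - gamma) * sigma_sq,
    loglik = loglik,
    loglik_ols = loglik_ols,
    lr_stat = max(0, 2 * (loglik - loglik_ols)),
    beta_se = stats::setNames(beta_se, cn),
    beta_t = stats::setNames(beta / beta_se, cn),
    converged = converged,
    gamma_at_boundary = gamma < 1e-4 || gamma > 1 - 1e-4,
    n_obs = n
  ), class = "sfa_model")
}

#' @export
print.sfa_model <- function(x, ...) {
  cat("Half-normal stochastic slack frontier (MLE)\n")
  tab <- cbind(Estimate = x$beta, `Std. Error` = x$beta_se,
               `t value` = x$beta_t)
  print(round(tab, 4))
  cat(sprintf("sigma-squared = %.4g, gamma = %.4f\n", x$sigma_sq, x$gamma))
  cat(sprintf("log likelihood = %.3f (OLS %.3f), LR = %.3f, n = %d\n",
              x$loglik, x$loglik_ols, x$lr_stat, x$n_obs))
  invisible(x)
}

#' JLMS decomposition of slacks
#'
#' Separates each observed slack into its environmental component
#' `f = Z beta`, the management-inefficiency estimate
#' `u = E[u | eps]` (Jondrow-Lovell-Materov-Schmidt conditional mean) and
#' the noise remainder `v = eps - u`, so that `f + u + v` reconstructs the
#' slack exactly.
#'
#' @param S slack vector used in the fit.
#' @param Z covariate matrix used in the fit (no intercept column).
#' @param model an [fit_slack_frontier()] result.
#' @return list with vectors `f_hat`, `u_hat` (nonnegative), `v_hat`.
#' @export
jlms_decompose <- function(S, Z, model) {
  Zi <- cbind(1, as.matrix(Z))
  if (ncol(Zi) != length(model$beta)) {
    stop("covariate count does not match the fitted model")
  }
  f_hat <- drop(Zi %*% model$beta)
  eps <- S - f_hat
  su2 <- model$sigma_u_sq; sv2 <- model$sigma_v_sq
  s2 <- model$sigma_sq
  mu_star <- eps * su2 / s2
  sig_star <- sqrt(su2 * sv2 / s2)
  if (sig_star < .Machine$double.eps) {
    # degenerate limits: all inefficiency (gamma ~ 1) or none (gamma ~ 0)
    u_hat <- if (su2 <= sv2) rep(0, length(eps)) else pmax(eps, 0)
  } else {
    zq <- mu_star / sig_star
    # inverse Mills ratio in the log domain; never divides by a zero CDF
    imr <- exp(stats::dnorm(zq, log = TRUE) -
                 stats::pnorm(zq, log.p = TRUE))
    u_hat <- mu_star + sig_star * imr
  }
  u_hat <- pmax(u_hat, 0)
  list(f_hat = f_hat, u_hat = u_hat, v_hat = eps - u_hat)
}

#' Environmentally harmonized input adjustment
#'
#' Places every observation on the least favorable environment and
#' worst-luck footing seen in the sample:
#' `X* = X + (max f - f) + (max v - v)`.  Both added terms are
#' nonnegative, so adjusted inputs never fall below the originals; the
#' observation attaining both maxima is unchanged.
#'
#' @param X original input values.
#' @param f_hat fitted environmental component per observation.
#' @param v_hat estimated noise per observation.
#' @return adjusted input vector.
#' @export
adjust_inputs <- function(X, f_hat, v_hat) {
  if (length(X) != length(f_hat) || length(X) != length(v_hat)) {
    stop("X, f_hat and v_hat must have equal length")
  }
  X + (max(f_hat) - f_hat) + (max(v_hat) - v_hat)
}

#' One-sided mixed chi-square LR test for the inefficiency share
#'
#' Because `gamma = 0` lies on the boundary of the parameter space, the
#' LR statistic against OLS is compared with a mixed chi-square
#' distribution: with `df` one-sided restrictions the tail probability is
#' `sum_i C(df, i) 2^-df P(chisq_i >= x)` (the i = 0 term is a point mass
#' at zero).  For `df = 1`, the 5% critical value is 2.706.
#'
#' @param lr_stat observed LR statistic (tiny negatives are clipped).
#' @param df number of restricted parameters (>= 1).
#' @param level significance level (default 0.05).
#' @return list with `lr_stat`, `df`, `p_value`, `critical`, `level`,
#'   `significant`.
#' @export
lr_mixed_chisq_test <- function(lr_stat, df, level = 0.05) {
  if (df < 1) stop("df must be at least 1")
  lr_stat <- max(0, lr_stat)
  tail_p <- function(x) {
    if (x <= 0) return(1)
    w <- stats::dbinom(0:df, df, 0.5)
    # chi^2_0 is a point mass at 0: contributes 0 to P(X >= x) for x > 0
    sum(w[-1] * stats::pchisq(x, df = 1:df, lower.tail = FALSE))
  }
  p_value <- tail_p(lr_stat)
  critical <- stats::uniroot(function(x) tail_p(x) - level,
                             c(1e-12, 200), tol = 1e-10)$root
  list(lr_stat = lr_stat, df = df, p_value = p_value,
       critical = critical, level = level,
       significant = lr_stat > critical)
}
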