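# Synthetic panels with the statistical structure the three-stage method
# assumes: a known production frontier, environment-driven input slack,
# half-normal management inefficiency and Gaussian noise — plus the full
# ground truth needed for recovery experiments.
#
# The default configuration mirrors the panel shape of a provincial
# grain-production study: 13 units x 20 years, 4 inputs, 1 desirable
# output, 1 undesirable (carbon) output, 5 environmental covariates.

#' Simulation configuration
#'
#' @param J number of units (>= 3).
#' @param T number of periods (>= 2).
#' @param m number of inputs.
#' @param p number of environmental covariates.
#' @param seed integer RNG seed (recorded in the output).
#' @param beta_env true slack-frontier coefficients, an `m x p` matrix
#'   (row i = the covariate effects on input i's slack).  The default is
#'   a common covariate pattern `(1.2, -0.8, 0.6, 0, 0.4, ...)` scaled by
#'   an input-specific positive factor: each covariate pushes every
#'   input's slack in the same direction (as e.g. a disaster year does),
#'   with input-dependent strength.
#' @param sigma_u half-normal management-inefficiency scale.
#' @param mgmt_spread log-scale standard deviation of persistent
#'   unit-level differences in the inefficiency scale: unit j draws its
#'   slacks from `|N(0, (sigma_u * exp(nu_j))^2)|` with
#'   `nu_j ~ N(0, mgmt_spread^2)`.  This is what makes some units
#'   persistently better managed than others, as provinces are.
#' @param sigma_v Gaussian noise scale.
#' @param env_mgmt_cor correlation between a unit's persistent
#'   environmental favorability and its management inefficiency scale.
#'   Positive values put poorly managed units in favorable environments,
#'   so the raw stage-1 ranking is systematically confounded — the
#'   situation the three-stage adjustment exists to correct.  Set to 0
#'   for an environment orthogonal to management.
#' @param tfp_trend per-period Hicks-neutral frontier shift factor
#'   (1.02 = 2% less input needed per year, a typical agricultural TFP
#'   drift).
#' @param rts_exponent scale elasticity of the frontier input requirement
#'   (`< 1` = decreasing returns, so VRS and CRS scores differ; the mild
#'   default keeps scale efficiency near the 0.95+ typical of provincial
#'   panels so scale effects do not swamp the management signal).
#' @param carbon_rate undesirable output per unit of aggregate input.
#' @param weight_profile log-scale standard deviation of the unit size
#'   distribution (output heterogeneity across units).
#' @param input_req base input requirement per unit output, length `m`.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(J = 13, T = 20, m = 4, p = 5, seed = 1,
                              beta_env = NULL,
                              sigma_u = 1.4, mgmt_spread = 0.9,
                              sigma_v = 0.2, env_mgmt_cor = 0.45,
                              tfp_trend = 1.02, rts_exponent = 0.97,
                              carbon_rate = 0.3, weight_profile = 0.12,
                              input_req = NULL) {
  if (J < 3 || T < 2) stop("need J >= 3 and T >= 2")
  if (sigma_u < 0 || sigma_v < 0) stop("scales must be nonnegative")
  if (abs(env_mgmt_cor) > 1) stop("env_mgmt_cor must lie in [-1, 1]")
  if (is.null(input_req)) {
    input_req <- rep_len(c(1.0, 0.8, 1.2, 0.9), m)
  }
  if (is.null(beta_env)) {
    pattern <- rep_len(c(1.4, -0.95, 0.7, 0, 0.5), p)
    scale_i <- rep_len(c(1, 0.7, 1.2, 0.9), m)
    beta_env <- outer(scale_i, pattern)
  }
  beta_env <- matrix(as.numeric(beta_env), m, p)
  structure(list(J = J, T = T, m = m, p = p, seed = as.integer(seed),
                 beta_env = beta_env, sigma_u = sigma_u,
                 mgmt_spread = mgmt_spread, sigma_v = sigma_v,
                 env_mgmt_cor = env_mgmt_cor,
                 tfp_trend = tfp_trend, rts_exponent = rts_exponent,
                 carbon_rate = carbon_rate, weight_profile = weight_profile,
                 input_req = input_req),
            class = "simulation_config")
}

#' Generate a synthetic panel with ground truth
#'
#' Draws unit sizes, sets the frontier-minimal input requirement
#' `x*_i = a_i * y^rts_exponent / tfp_trend^(t-1)`, draws correlated
#' environmental covariates (one shared factor with a persistent
#' unit-level component, so the SFA faces the mild collinearity yearbook
#' covariates would show and units differ durably in their environment),
#' and inflates inputs by the slack `Z beta + u + v` with `u` half-normal
#' (unit-specific scale, see `mgmt_spread`) and `v` Gaussian.
#' The additive slack is floored so that `X >= 0.05 x*`; flooring events
#' are counted in the truth object (rare under the default calibration).
#' The undesirable output is proportional to aggregate input use; the
#' weighting basis `W` is the desirable output.
#'
#' The reported `true_efficiency` is the management-only efficiency
#' `mean_i(x*_i / (x*_i + u_i))`: the quantity stage 3 is meant to
#' recover, deliberately excluding the environment and noise components
#' that stage 2 strips out.
#'
#' @param cfg a [simulation_config()].
#' @return list with `panel` (a `panel_dataset`) and `truth` (list:
#'   `efficient_inputs` J x T x m, `f`, `u`, `v` slack components
#'   (J x T x m each), `true_efficiency` J x T (management-only),
#'   `env_advantage` J x T (total input reduction granted by the
#'   environment; positive = flattered by a favorable environment),
#'   `true_beta`, `n_floored`).
#' @export
generate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  J <- cfg$J; Tn <- cfg$T; m <- cfg$m; p <- cfg$p

  units <- sprintf("U%02d", seq_len(J))
  years <- 2000L + seq_len(Tn) - 1L

  # unit sizes and output panel (mild idiosyncratic wobble around the
  # unit's scale)
  size <- exp(stats::rnorm(J, log(10), cfg$weight_profile))
  Y <- array(size * exp(stats::rnorm(J * Tn, 0, 0.05)), c(J, Tn, 1))

  # persistent management heterogeneity, drawn first so the environment
  # factor can be tied to it (env_mgmt_cor): with a positive correlation,
  # badly managed units sit in flattering environments
  nu <- stats::rnorm(J)
  sigma_u_j <- cfg$sigma_u * exp(cfg$mgmt_spread * nu)

  # covariates: one shared factor (persistent unit component plus yearly
  # innovation) plus an idiosyncratic part per covariate; a high factor
  # value raises slacks (inputs), i.e. an unfavorable environment
  rho <- cfg$env_mgmt_cor
  fj <- -rho * nu + sqrt(1 - rho^2) * stats::rnorm(J)
  Fjt <- sqrt(0.8) * matrix(fj, J, Tn) +
    sqrt(0.2) * matrix(stats::rnorm(J * Tn), J, Tn)
  Z <- array(0, c(J, Tn, p))
  for (q in seq_len(p)) {
    Z[, , q] <- 0.7 * Fjt +
      sqrt(1 - 0.49) * matrix(stats::rnorm(J * Tn), J, Tn)
  }

  trend <- cfg$tfp_trend^(seq_len(Tn) - 1L)
  Xstar <- array(0, c(J, Tn, m))
  for (i in seq_len(m)) {
    Xstar[, , i] <- cfg$input_req[i] *
      sweep(Y[, , 1, drop = FALSE][, , 1]^cfg$rts_exponent, 2, trend, "/")
  }

  Zmat <- matrix(Z, J * Tn, p)
  X <- Xstar
  f_arr <- u_arr <- v_arr <- array(0, c(J, Tn, m))
  n_floored <- 0L
  for (i in seq_len(m)) {
    f <- matrix(Zmat %*% cfg$beta_env[i, ], J, Tn)
    u <- matrix(abs(stats::rnorm(J * Tn, 0, 1)), J, Tn) * sigma_u_j
    v <- matrix(stats::rnorm(J * Tn, 0, cfg$sigma_v), J, Tn)
    slack <- f + u + v
    floorv <- -0.95 * Xstar[, , i]
    n_floored <- n_floored + sum(slack < floorv)
    slack <- pmax(slack, floorv)
    X[, , i] <- Xstar[, , i] + slack
    f_arr[, , i] <- f; u_arr[, , i] <- u; v_arr[, , i] <- v
  }
  if (any(X <= 0)) {
    stop("configuration produced nonpositive inputs even at the floor; rescale sigma_u/sigma_v or beta_env")
  }

  total_X <- apply(X, c(1, 2), sum)
  B <- array(cfg$carbon_rate * total_X *
               exp(stats::rnorm(J * Tn, 0, 0.05)), c(J, Tn, 1))

  input_names <- paste0("input", seq_len(m))
  dimnames(X) <- dimnames(Xstar) <- list(units, years, input_names)
  dimnames(Y) <- list(units, years, "output")
  dimnames(B) <- list(units, years, "carbon")
  dimnames(Z) <- list(units, years, paste0("env", seq_len(p)))

  panel <- panel_dataset(X, Y, B, Z, W = Y[, , 1],
                         dmu_ids = units, periods = years)

  true_eff <- apply(Xstar / (Xstar + u_arr), c(1, 2), mean)
  env_adv <- -apply(f_arr, c(1, 2), sum)   # positive = inputs reduced
  dimnames(true_eff) <- dimnames(env_adv) <- list(units, years)

  list(panel = panel,
       truth = list(efficient_inputs = Xstar,
                    f = f_arr, u = u_arr, v = v_arr,
                    true_efficiency = true_eff,
                    env_advantage = env_adv,
                    true_beta = cfg$beta_env,
                    n_floored = n_floored,
                    seed = cfg$seed))
}

#' A fixed hand-solvable toy panel
#'
#' Four units, two identical periods, one input, one output, with integer
#' values chosen so the radial CRS efficiencies are obvious from the
#' output/input ratios (2, 1, 1, 0.5 against the best ratio 2):
#' scores 1, 0.5, 0.5, 0.25 in every period under a global frontier.
#'
#' @return a `panel_dataset`.
#' @export
toy_fixture <- function() {
  x <- c(2, 4, 5, 10)
  y <- c(4, 4, 5, 5)
  X <- array(rep(x, 2), c(4, 2, 1))
  Y <- array(rep(y, 2), c(4, 2, 1))
  dimnames(X) <- list(LETTERS[1:4], c(2000L, 2001L), "x")
  dimnames(Y) <- list(LETTERS[1:4], c(2000L, 2001L), "y")
  panel_dataset(X, Y, dmu_ids = LETTERS[1:4], periods = c(2000L, 2001L))
}
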