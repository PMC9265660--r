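# Input-oriented (super-efficiency) epsilon-based-measure DEA.
#
# The EBM score blends the radial contraction factor theta with a weighted
# sum of input slacks:
#
#   gamma* = min  theta - eps * sum_i w_i s_i / x_ik
#   s.t.    sum_{j in R} lambda_j x_ij + s_i = theta * x_ik   (each input i)
#           sum_{j in R} lambda_j y_rj >= y_rk                (each output r)
#           sum_j lambda_j = 1  (VRS only),  lambda, s >= 0
#
# eps = 0 recovers the radial CCR/BCC model, eps = 1 approaches SBM.
# Undesirable outputs are by default folded into the input side (they are
# things to be contracted), each with its own slack and affinity weight;
# a weak-disposability mode replaces that with equality constraints.
# Super-efficiency removes the evaluated observation from the reference
# set, letting frontier units score above 1.

#' Technology specification for EBM scoring
#'
#' @param rts returns to scale, `"crs"` or `"vrs"`.
#' @param frontier `"global"` (pool every unit-period observation into one
#'   reference technology, giving transitive cross-period comparisons) or
#'   `"contemporaneous"` (same-period observations only).
#' @param epsilon_x EBM key parameter in \[0, 1\]; `NULL` (default) means
#'   determine it from the data by the affinity-index procedure
#'   ([affinity_epsilon_weights()]).
#' @param input_weights relative weights of the input slacks, nonnegative,
#'   summing to 1 over inputs plus undesirable outputs when those are
#'   modeled as inputs; `NULL` means affinity-derived.
#' @param super_efficiency logical; exclude the evaluated observation from
#'   its own reference set.
#' @param bad_output_mode `"as_input"` (default) or
#'   `"weak_disposability"` (equality constraints on undesirable outputs).
#' @return an object of class `technology_spec`.
#' @export
technology_spec <- function(rts = c("crs", "vrs"),
                            frontier = c("global", "contemporaneous"),
                            epsilon_x = NULL,
                            input_weights = NULL,
                            super_efficiency = FALSE,
                            bad_output_mode = c("as_input",
                                                "weak_disposability")) {
  rts <- match.arg(rts)
  frontier <- match.arg(frontier)
  bad_output_mode <- match.arg(bad_output_mode)
  if (!is.null(epsilon_x)) {
    if (epsilon_x < 0 || epsilon_x > 1) stop("epsilon_x must lie in [0, 1]")
  }
  if (!is.null(input_weights)) {
    if (any(input_weights < 0)) stop("input weights must be nonnegative")
    if (abs(sum(input_weights) - 1) > 1e-9) {
      stop("input weights must sum to 1 (tolerance 1e-9)")
    }
  }
  structure(list(orientation = "input", rts = rts, frontier = frontier,
                 epsilon_x = epsilon_x, input_weights = input_weights,
                 super_efficiency = super_efficiency,
                 bad_output_mode = bad_output_mode),
            class = "technology_spec")
}

#' Affinity-index determination of the EBM parameters
#'
#' Data-driven choice of the EBM key parameter and slack weights.  For
#' every pair of input columns the affinity index measures how close the
#' two input profiles are to proportionality (1 = exactly proportional,
#' 0 = maximally diverse), via the dispersion of the log ratio:
#' with `c = log(b/a)`, diversity `D = sum(|c - mean(c)|) / (n * (max(c)
#' - min(c)))` (0 if all ratios equal) and affinity `S = 1 - 2 D`.  The
#' principal eigenvalue `rho_max` of the affinity matrix then gives
#' `epsilon = (m - rho_max) / (m - 1)` and the normalized principal
#' eigenvector gives the weights.
#'
#' @param input_matrix observations x inputs, strictly positive.
#' @return list with `epsilon_x` and `input_weights` (summing to 1).
#' @export
affinity_epsilon_weights <- function(input_matrix) {
  input_matrix <- as.matrix(input_matrix)
  if (any(input_matrix <= 0)) stop("inputs must be strictly positive")
  n <- nrow(input_matrix); m <- ncol(input_matrix)
  if (n < 2L) stop("at least 2 observations are required")
  if (m == 1L) return(list(epsilon_x = 0, input_weights = 1))
  S <- diag(m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      cc <- log(input_matrix[, j] / input_matrix[, i])
      rng <- max(cc) - min(cc)
      D <- if (rng < 1e-12) 0 else sum(abs(cc - mean(cc))) / (n * rng)
      S[i, j] <- S[j, i] <- 1 - 2 * D
    }
  }
  eg <- eigen(S, symmetric = TRUE)
  rho_max <- eg$values[1]
  w <- abs(eg$vectors[, 1])      # Perron vector of a nonnegative matrix
  list(epsilon_x = max(0, min(1, (m - rho_max) / (m - 1))),
       input_weights = w / sum(w))
}

# Flatten a panel into pooled observations (one row per unit-period).
# Returns matrices X (n x m), Y (n x s), B (n x sb or NULL) plus the
# (unit, period) address of every row.
pool_panel <- function(panel) {
  J <- length(panel$dmu_ids); Tn <- length(panel$periods)
  flat <- function(A) {
    if (is.null(A)) return(NULL)
    matrix(A, J * Tn, dim(A)[3],
           dimnames = list(NULL, dimnames(A)[[3]]))
  }
  list(X = flat(panel$X), Y = flat(panel$Y), B = flat(panel$B),
       unit = rep(panel$dmu_ids, Tn),
       period = rep(panel$periods, each = J),
       unit_idx = rep(seq_len(J), Tn),
       period_idx = rep(seq_len(Tn), each = J))
}

# EBM parameters actually used for a given spec + pooled data: affinity
# defaults computed on the augmented input matrix (inputs plus undesirable
# outputs in as_input mode).
resolve_ebm_params <- function(pool, spec) {
  Xa <- pool$X
  if (!is.null(pool$B) && spec$bad_output_mode == "as_input") {
    Xa <- cbind(pool$X, pool$B)
  }
  m_a <- ncol(Xa)
  eps <- spec$epsilon_x
  w <- spec$input_weights
  if (is.null(eps) || is.null(w)) {
    aff <- if (nrow(Xa) >= 2L && all(Xa > 0)) {
      affinity_epsilon_weights(Xa)
    } else {
      list(epsilon_x = 0, input_weights = rep(1 / m_a, m_a))
    }
    if (is.null(eps)) eps <- aff$epsilon_x
    if (is.null(w)) w <- aff$input_weights
  }
  if (length(w) != m_a) {
    stop(sprintf("input_weights length %d does not match %d input-side variables",
                 length(w), m_a))
  }
  list(epsilon_x = eps, input_weights = w, m_a = m_a)
}

#' Solve one EBM program
#'
#' Scores observation `k` of a pooled observation set against the
#' reference set `ref` (default: all observations; the evaluated
#' observation itself is removed under super-efficiency).
#'
#' @param pool pooled observations as returned by internal flattening:
#'   a list with matrices `X` (n x m), `Y` (n x s), optionally `B`
#'   (n x sb).  A `panel_dataset` is accepted and flattened.
#' @param k row index of the evaluated observation.
#' @param spec a [technology_spec()].
#' @param ref integer indices of the reference observations (before any
#'   super-efficiency exclusion); defaults to all rows for a global
#'   frontier, same-period rows for a contemporaneous one.
#' @param params optional precomputed `(epsilon_x, input_weights)` — used
#'   by [score_panel()] so the affinity procedure runs once per panel.
#' @return an `efficiency_result`: list with `score`, `theta`, `slacks`,
#'   `lambdas` (named by reference row), and `status` (`"optimal"` or
#'   `"fallback-used"` when an infeasible super-efficiency program was
#'   re-solved without the exclusion).
#' @export
solve_ebm <- function(pool, k, spec, ref = NULL, params = NULL) {
  if (inherits(pool, "panel_dataset")) pool <- pool_panel(pool)
  n <- nrow(pool$X)
  if (is.null(ref)) {
    ref <- if (spec$frontier == "contemporaneous" && !is.null(pool$period)) {
      which(pool$period == pool$period[k])
    } else seq_len(n)
  }
  if (is.null(params)) {
    params <- resolve_ebm_params(
      list(X = pool$X[ref, , drop = FALSE], Y = NULL,
           B = if (!is.null(pool$B)) pool$B[ref, , drop = FALSE]), spec)
  }
  as_input <- !is.null(pool$B) && spec$bad_output_mode == "as_input"
  Xa <- if (as_input) cbind(pool$X, pool$B) else pool$X
  ebm_solve_one(Xa, pool$Y,
                Beq = if (!as_input) pool$B else NULL,
                k = k, ref = ref, spec = spec, params = params)
}

# core LP assembly/solution; Xa holds the input-side variables (inputs and,
# in as_input mode, undesirable outputs), Beq the equality-constrained bads
ebm_solve_one <- function(Xa, Y, Beq, k, ref, spec, params) {
  R <- if (spec$super_efficiency) setdiff(ref, k) else ref
  if (length(R) == 0L) {
    stop("reference set is empty after super-efficiency exclusion")
  }
  m_a <- ncol(Xa); s <- ncol(Y)
  xk <- Xa[k, ]; yk <- Y[k, ]
  build <- function(R) {
    nR <- length(R)
    nv <- 1L + nR + m_a   # theta, lambda, slacks
    eps <- params$epsilon_x; w <- params$input_weights
    obj <- c(1, rep(0, nR), ifelse(xk > 0, -eps * w / ifelse(xk > 0, xk, 1), 0))
    rows <- list(); dirs <- character(0); rhs <- numeric(0)
    for (i in seq_len(m_a)) {
      rows[[length(rows) + 1L]] <-
        c(-xk[i], Xa[R, i], as.numeric(seq_len(m_a) == i))
      dirs <- c(dirs, "="); rhs <- c(rhs, 0)
    }
    for (r in seq_len(s)) {
      rows[[length(rows) + 1L]] <- c(0, Y[R, r], rep(0, m_a))
      dirs <- c(dirs, ">="); rhs <- c(rhs, yk[r])
    }
    if (!is.null(Beq)) {
      for (r in seq_len(ncol(Beq))) {
        rows[[length(rows) + 1L]] <- c(0, Beq[R, r], rep(0, m_a))
        dirs <- c(dirs, "="); rhs <- c(rhs, Beq[k, r])
      }
    }
    if (spec$rts == "vrs") {
      rows[[length(rows) + 1L]] <- c(0, rep(1, nR), rep(0, m_a))
      dirs <- c(dirs, "="); rhs <- c(rhs, 1)
    }
    list(obj = obj, mat = do.call(rbind, rows), dir = dirs, rhs = rhs,
         nR = nR)
  }
  lp <- build(R)
  sol <- solve_lp(lp$obj, lp$mat, lp$dir, lp$rhs)
  status <- "optimal"
  if (sol$status != "optimal") {
    if (spec$super_efficiency && sol$status == "infeasible") {
      # VRS super-efficiency can be infeasible; fall back to the
      # non-super score for this observation and flag it
      R <- ref
      lp <- build(R)
      sol <- solve_lp(lp$obj, lp$mat, lp$dir, lp$rhs)
      status <- "fallback-used"
      if (sol$status != "optimal") {
        stop("EBM solver failure (", sol$status, ") for observation ", k)
      }
    } else {
      stop("EBM solver failure (", sol$status, ") for observation ", k)
    }
  }
  lambdas <- sol$x[1L + seq_len(lp$nR)]
  names(lambdas) <- as.character(R)
  structure(list(
    score = sol$value,
    theta = sol$x[1],
    slacks = stats::setNames(sol$x[1L + lp$nR + seq_len(m_a)],
                             colnames(Xa)),
    lambdas = lambdas,
    status = status,
    epsilon_x = params$epsilon_x,
    input_weights = params$input_weights
  ), class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("EBM efficiency: %.6f (theta = %.6f, status: %s)\n",
              x$score, x$theta, x$status))
  invisible(x)
}

#' Score every unit-period of a panel
#'
#' Applies [solve_ebm()] to every observation of the panel under the given
#' technology.  The affinity-based EBM parameters are determined once from
#' the full observation pool so that all programs share one aggregation.
#'
#' @param panel a `panel_dataset`.
#' @param spec a [technology_spec()].
#' @return an `efficiency_panel`: list with `scores` and `theta`
#'   (J x T matrices), `slacks` (J x T x input-side variables), `status`
#'   (J x T character), the `spec` and resolved `epsilon_x`,
#'   `input_weights`.
#' @export
score_panel <- function(panel, spec) {
  validate_panel(panel)
  pool <- pool_panel(panel)
  params <- resolve_ebm_params(pool, spec)
  J <- length(panel$dmu_ids); Tn <- length(panel$periods)
  n <- J * Tn
  scores <- theta <- matrix(NA_real_, J, Tn,
                            dimnames = list(panel$dmu_ids, panel$periods))
  status <- matrix(NA_character_, J, Tn,
                   dimnames = list(panel$dmu_ids, panel$periods))
  slacks <- array(NA_real_, c(J, Tn, params$m_a))
  for (k in seq_len(n)) {
    res <- tryCatch(
      solve_ebm(pool, k, spec, params = params),
      error = function(e) {
        stop(sprintf("EBM failure at unit '%s', year %d: %s",
                     pool$unit[k], pool$period[k], conditionMessage(e)),
             call. = FALSE)
      })
    j <- pool$unit_idx[k]; t <- pool$period_idx[k]
    scores[j, t] <- res$score
    theta[j, t] <- res$theta
    slacks[j, t, ] <- res$slacks
    status[j, t] <- res$status
  }
  dimnames(slacks) <- list(panel$dmu_ids, panel$periods,
                           names(pool_slack_names(panel, spec)))
  structure(list(scores = scores, theta = theta, slacks = slacks,
                 status = status, spec = spec,
                 epsilon_x = params$epsilon_x,
                 input_weights = params$input_weights),
            class = "efficiency_panel")
}

pool_slack_names <- function(panel, spec) {
  nm <- dimnames(panel$X)[[3]]
  if (!is.null(panel$B) && spec$bad_output_mode == "as_input") {
    nm <- c(nm, dimnames(panel$B)[[3]])
  }
  stats::setNames(seq_along(nm), nm)
}

#' @export
print.efficiency_panel <- function(x, ...) {
  cat(sprintf(
    "EBM scores: %d units x %d periods (%s, %s frontier%s), eps = %.4f\n",
    nrow(x$scores), ncol(x$scores), toupper(x$spec$rts), x$spec$frontier,
    if (x$spec$super_efficiency) ", super-efficiency" else "",
    x$epsilon_x))
  print(round(x$scores, 4))
  invisible(x)
}

#' Scale efficiency from CRS and VRS scores
#'
#' Decomposes comprehensive technical efficiency (CRS) into pure technical
#' efficiency (VRS) times scale efficiency: `SE = CTE / PTE`.
#'
#' @param cte CRS score(s).
#' @param pte VRS score(s), strictly positive.
#' @return scale efficiency, same shape as the inputs.
#' @export
decompose_efficiency <- function(cte, pte) {
  if (any(pte <= 0)) stop("pure technical efficiency must be positive")
  cte / pte
}
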