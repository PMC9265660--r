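# Dense two-phase primal simplex used by the EBM envelopment programs.
#
# DEA envelopment LPs are small (a handful of constraints, one column per
# reference observation) but are solved thousands of times per panel, and
# they are highly degenerate (zero right-hand sides on every input row).
# The solver below keeps a full tableau, uses Dantzig pricing with a switch
# to Bland's rule after a burn-in to guard against cycling, and applies the
# optimality tolerance stated in the technology spec (1e-9 by default).

#' Solve a linear program
#'
#' Minimizes `obj %*% x` subject to `mat %*% x (dir) rhs` and `x >= 0`,
#' where `dir` is a vector of `"<="`, `">="` or `"="` per row.
#'
#' @param obj numeric objective coefficients (length n).
#' @param mat constraint matrix (m x n).
#' @param dir character vector of constraint directions.
#' @param rhs numeric right-hand sides.
#' @param tol pivoting/optimality tolerance.
#' @param max_iter iteration cap; defaults to `50 * (m + n)`.
#' @return list with `status` ("optimal", "infeasible", "unbounded",
#'   "maxiter"), the primal solution `x` and the objective `value`.
#' @keywords internal
solve_lp <- function(obj, mat, dir, rhs, tol = 1e-9, max_iter = NULL) {
  mat <- as.matrix(mat)
  m <- nrow(mat)
  n <- ncol(mat)
  stopifnot(length(obj) == n, length(dir) == m, length(rhs) == m)
  if (!all(dir %in% c("<=", ">=", "="))) {
    stop("constraint directions must be one of '<=', '>=', '='")
  }

  # normalize rows so all right-hand sides are nonnegative
  flip <- rhs < 0
  if (any(flip)) {
    mat[flip, ] <- -mat[flip, , drop = FALSE]
    rhs[flip] <- -rhs[flip]
    dir[flip] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[flip]]
  }

  n_le <- sum(dir == "<=")
  n_ge <- sum(dir == ">=")
  # slack columns for "<=", surplus for ">="; artificials for ">=" and "="
  slack_cols <- integer(m)   # column index of the row's slack/surplus (0 = none)
  art_rows <- which(dir != "<=")
  n_art <- length(art_rows)

  ncols <- n + n_le + n_ge + n_art
  A <- matrix(0, m, ncols)
  A[, seq_len(n)] <- mat
  nxt <- n
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      nxt <- nxt + 1L
      A[i, nxt] <- 1
      slack_cols[i] <- nxt
    } else if (dir[i] == ">=") {
      nxt <- nxt + 1L
      A[i, nxt] <- -1
      slack_cols[i] <- nxt
    }
  }
  art_cols <- integer(0)
  basis <- integer(m)
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      basis[i] <- slack_cols[i]
    } else {
      nxt <- nxt + 1L
      A[i, nxt] <- 1
      art_cols <- c(art_cols, nxt)
      basis[i] <- nxt
    }
  }

  b <- rhs
  if (is.null(max_iter)) max_iter <- 50L * (m + ncols)

  run_simplex <- function(A, b, basis, red, obj_val, allowed, max_iter, tol) {
    # red: reduced-cost row; obj_val: current (negated bookkeeping not used,
    # we track the true objective of the phase)
    iter <- 0L
    bland_after <- 3L * (nrow(A) + ncol(A))
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) {
        return(list(status = "maxiter", A = A, b = b, basis = basis,
                    red = red, obj_val = obj_val))
      }
      cand <- which(allowed & red < -tol)
      if (length(cand) == 0L) {
        return(list(status = "optimal", A = A, b = b, basis = basis,
                    red = red, obj_val = obj_val))
      }
      if (iter > bland_after) {
        jin <- cand[1L]                      # Bland's rule
      } else {
        jin <- cand[which.min(red[cand])]    # Dantzig
      }
      col <- A[, jin]
      pos <- which(col > tol)
      if (length(pos) == 0L) {
        return(list(status = "unbounded", A = A, b = b, basis = basis,
                    red = red, obj_val = obj_val))
      }
      ratio <- b[pos] / col[pos]
      rmin <- min(ratio)
      tie <- pos[ratio <= rmin + tol * (1 + abs(rmin))]
      # leave the lowest basis index among ties (anti-cycling heuristic)
      rout <- tie[which.min(basis[tie])]
      # pivot on (rout, jin)
      pv <- A[rout, jin]
      prow <- A[rout, ] / pv
      pb <- b[rout] / pv
      colv <- A[, jin]
      A <- A - outer(colv, prow)
      b <- b - colv * pb
      A[rout, ] <- prow
      b[rout] <- pb
      obj_val <- obj_val - red[jin] * pb * 0  # objective tracked via red below
      rj <- red[jin]
      red <- red - rj * prow
      obj_val <- obj_val + rj * pb
      basis[rout] <- jin
      b[abs(b) < tol] <- pmax(b[abs(b) < tol], 0)  # clip tiny negatives
    }
  }

  # ---- phase 1 ----
  if (n_art > 0L) {
    cvec <- numeric(ncols)
    cvec[art_cols] <- 1
    cB <- cvec[basis]
    red <- cvec - as.numeric(crossprod(cB, A))
    obj_val <- -sum(cB * b)   # phase objective = sum of artificial values
    allowed <- rep(TRUE, ncols)
    res <- run_simplex(A, b, basis, red, obj_val, allowed, max_iter, tol)
    if (res$status == "unbounded") {
      stop("internal error: phase-1 LP unbounded")
    }
    phase1_obj <- sum(cvec[res$basis] * res$b)
    if (res$status == "maxiter") {
      return(list(status = "maxiter", x = NULL, value = NA_real_))
    }
    if (phase1_obj > 1e-7) {
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    }
    A <- res$A; b <- res$b; basis <- res$basis
    # drive any residual (zero-valued) artificials out of the basis
    for (i in which(basis %in% art_cols)) {
      piv_cand <- which(abs(A[i, seq_len(n + n_le + n_ge)]) > tol)
      piv_cand <- setdiff(piv_cand, basis)
      if (length(piv_cand) > 0L) {
        jin <- piv_cand[1L]
        pv <- A[i, jin]
        prow <- A[i, ] / pv
        pb <- b[i] / pv
        colv <- A[, jin]
        A <- A - outer(colv, prow)
        b <- b - colv * pb
        A[i, ] <- prow
        b[i] <- pb
        basis[i] <- jin
      }
    }
  }

  # ---- phase 2 ----
  cvec <- numeric(ncols)
  cvec[seq_len(n)] <- obj
  cB <- cvec[basis]
  red <- cvec - as.numeric(crossprod(cB, A))
  allowed <- rep(TRUE, ncols)
  if (n_art > 0L) allowed[art_cols] <- FALSE
  res <- run_simplex(A, b, basis, red, sum(cB * b), allowed, max_iter, tol)
  if (res$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  }
  if (res$status == "maxiter") {
    return(list(status = "maxiter", x = NULL, value = NA_real_))
  }
  x <- numeric(ncols)
  x[res$basis] <- res$b
  xs <- x[seq_len(n)]
  list(status = "optimal", x = xs, value = sum(obj * xs))
}
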