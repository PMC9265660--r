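# Independent oracles used across the suite.
#
# The radial DEA oracle solves the MULTIPLIER form of the CCR/BCC model
# with pracma::linprog — a different formulation (LP dual) and a different
# solver than the package's envelopment-form simplex, so agreement is a
# genuine cross-check.

# input-oriented radial score of unit k (columns of X, Y are units)
#   max u'y_k (+ w under VRS)  s.t.  v'x_k = 1,
#   u'y_j (+ w) - v'x_j <= 0 for j in reference set, u, v >= 0, w free
oracle_radial_dea <- function(X, Y, k, rts = "crs", super = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  m <- nrow(X); s <- nrow(Y); J <- ncol(X)
  R <- if (super) setdiff(seq_len(J), k) else seq_len(J)
  vrs <- rts == "vrs"
  # variables: u (s), v (m), [w+ , w- under VRS]
  nv <- s + m + if (vrs) 2L else 0L
  cc <- c(Y[, k], rep(0, m), if (vrs) c(1, -1))
  # maximize -> minimize negative
  A_ub <- t(vapply(R, function(j) {
    c(Y[, j], -X[, j], if (vrs) c(1, -1))
  }, numeric(nv)))
  b_ub <- rep(0, length(R))
  Aeq <- matrix(c(rep(0, s), X[, k], if (vrs) c(0, 0)), 1)
  r <- tryCatch(
    pracma::linprog(cc = -cc, A = A_ub, b = b_ub, Aeq = Aeq, beq = 1,
                    maxiter = 5000),
    error = function(e) NULL)
  # pracma's simplex can hit a singular basis on degenerate duals; the
  # comparison for that unit is skipped (returns NA)
  if (is.null(r) || is.null(r$fval) || !is.finite(r$fval)) return(NA_real_)
  -r$fval
}

# brute-force affinity matrix exactly as documented, via an explicit
# double loop (used to cross-check affinity_epsilon_weights)
oracle_affinity_matrix <- function(M) {
  n <- nrow(M); m <- ncol(M)
  S <- diag(m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    cc <- log(M[, j] / M[, i])
    rng <- max(cc) - min(cc)
    D <- if (rng < 1e-12) 0 else sum(abs(cc - mean(cc))) / (n * rng)
    S[i, j] <- 1 - 2 * D
  }
  S
}

# small random positive panel for property tests
random_panel <- function(J, Tn, m, s = 1, seed) {
  set.seed(seed)
  X <- array(runif(J * Tn * m, 1, 10), c(J, Tn, m))
  Y <- array(runif(J * Tn * s, 1, 10), c(J, Tn, s))
  panel_dataset(X, Y)
}
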