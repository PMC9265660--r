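two_unit_pool <- function() {
  list(X = matrix(c(2, 4), 2, 1), Y = matrix(c(4, 4), 2, 1), B = NULL)
}

test_that("hand-solved radial programs are reproduced", {
  pool <- two_unit_pool()
  sp <- technology_spec("crs", epsilon_x = 0, input_weights = 1)
  expect_equal(solve_ebm(pool, 2, sp)$score, 0.5, tolerance = 1e-8)
  expect_equal(solve_ebm(pool, 1, sp)$score, 1.0, tolerance = 1e-8)
  sup <- technology_spec("crs", epsilon_x = 0, input_weights = 1,
                         super_efficiency = TRUE)
  expect_equal(solve_ebm(pool, 1, sup)$score, 2.0, tolerance = 1e-8)

  # a unit whose twin is in the reference set scores exactly 1
  pool2 <- list(X = matrix(c(3, 3, 5), 3, 1),
                Y = matrix(c(6, 6, 4), 3, 1), B = NULL)
  expect_equal(solve_ebm(pool2, 2, sp)$score, 1.0, tolerance = 1e-8)
})

test_that("a static panel scores identically in every period on the global frontier", {
  p <- toy_fixture()
  ep <- score_panel(p, technology_spec("crs", epsilon_x = 0,
                                       input_weights = 1))
  expect_equal(unname(ep$scores[, 1]), c(1, 0.5, 0.5, 0.25),
               tolerance = 1e-8)
  expect_equal(ep$scores[, 1], ep$scores[, 2], tolerance = 1e-10)
})

test_that("affinity procedure matches a hand-built eigen oracle", {
  # exactly proportional columns: radial limit, equal weights
  Xp <- cbind(1:5, 2 * (1:5), 0.5 * (1:5))
  aff <- affinity_epsilon_weights(Xp)
  expect_equal(aff$epsilon_x, 0, tolerance = 1e-12)
  expect_equal(aff$input_weights, rep(1 / 3, 3), tolerance = 1e-10)

  # single input degenerates to the radial model
  expect_equal(affinity_epsilon_weights(matrix(1:4, 4, 1)),
               list(epsilon_x = 0, input_weights = 1))

  set.seed(3)
  M <- matrix(runif(8, 1, 9), 4, 2)
  S <- oracle_affinity_matrix(M)
  eg <- eigen(S, symmetric = TRUE)
  aff <- affinity_epsilon_weights(M)
  expect_equal(aff$epsilon_x, (2 - eg$values[1]) / (2 - 1),
               tolerance = 1e-10)
  expect_equal(aff$input_weights,
               abs(eg$vectors[, 1]) / sum(abs(eg$vectors[, 1])),
               tolerance = 1e-10)

  expect_error(affinity_epsilon_weights(matrix(c(1, -1), 2, 1)),
               "strictly positive")
})

test_that("with epsilon 0 and no bads, scores equal the multiplier-form radial oracle", {
  skip_if_not_installed("pracma")
  for (case in 1:6) {
    set.seed(100 + case)
    J <- sample(3:8, 1); m <- sample(1:3, 1); s <- sample(1:2, 1)
    X <- matrix(runif(J * m, 1, 10), m, J)
    Y <- matrix(runif(J * s, 1, 10), s, J)
    pool <- list(X = t(X), Y = t(Y), B = NULL)
    for (rts in c("crs", "vrs")) {
      sp <- technology_spec(rts, epsilon_x = 0,
                            input_weights = rep(1 / m, m))
      for (k in seq_len(J)) {
        o <- oracle_radial_dea(X, Y, k, rts)
        if (is.finite(o)) {
          expect_equal(solve_ebm(pool, k, sp)$score, o, tolerance = 1e-6)
        }
      }
    }
    # super-efficiency under CRS (always feasible via scaling)
    spu <- technology_spec("crs", epsilon_x = 0,
                           input_weights = rep(1 / m, m),
                           super_efficiency = TRUE)
    for (k in seq_len(J)) {
      o <- oracle_radial_dea(X, Y, k, "crs", super = TRUE)
      if (is.finite(o)) {
        expect_equal(solve_ebm(pool, k, spu)$score, o, tolerance = 1e-6)
      }
    }
  }
})

test_that("EBM scores satisfy the core frontier properties", {
  p <- random_panel(6, 2, 3, seed = 11)
  for (rts in c("crs", "vrs")) {
    sp <- technology_spec(rts, "global")
    ep <- score_panel(p, sp)
    # non-super scores live in (0, 1]
    expect_true(all(ep$scores > 0 & ep$scores <= 1 + 1e-7))
    # score <= theta whenever slack is active
    expect_true(all(ep$scores <= ep$theta + 1e-9))
    # slacks nonnegative
    expect_true(all(ep$slacks >= -1e-9))
    # global frontier scores never exceed contemporaneous ones
    epc <- score_panel(p, technology_spec(rts, "contemporaneous"))
    expect_true(all(ep$scores <= epc$scores + 1e-7))
    # super-efficiency only relaxes frontier units upward
    eps <- score_panel(p, technology_spec(rts, "global",
                                          super_efficiency = TRUE))
    expect_true(all(eps$scores >= ep$scores - 1e-7))
    frontier <- abs(ep$scores - 1) < 1e-7
    expect_true(all(eps$scores[frontier] >= 1 - 1e-7))
  }
})

test_that("scores are invariant to rescaling an input column", {
  p <- random_panel(5, 2, 3, seed = 21)
  sp <- technology_spec("crs", "global")
  base <- score_panel(p, sp)$scores
  p2 <- p
  p2$X[, , 2] <- p2$X[, , 2] * 1000
  expect_equal(score_panel(p2, sp)$scores, base, tolerance = 1e-7)
})

test_that("inflating the evaluated unit's input weakly lowers its score", {
  p <- random_panel(6, 1, 2, seed = 31)
  sp <- technology_spec("crs", "global")
  s0 <- score_panel(p, sp)$scores[3, 1]
  p2 <- p
  p2$X[3, 1, ] <- p2$X[3, 1, ] * 1.25
  expect_lte(score_panel(p2, sp)$scores[3, 1], s0 + 1e-9)
})

test_that("undesirable outputs reduce the feasible score in both modes", {
  g <- generate_panel(simulation_config(J = 5, T = 2, seed = 77))
  for (mode in c("as_input", "weak_disposability")) {
    ep <- score_panel(g$panel, technology_spec(
      "crs", "global", bad_output_mode = mode))
    expect_true(all(ep$scores > 0 & ep$scores <= 1 + 1e-7))
    expect_true(all(ep$status == "optimal"))
  }
})

test_that("scale efficiency is the CRS/VRS ratio and never exceeds 1", {
  expect_equal(decompose_efficiency(0.5, 1.0), 0.5)
  expect_equal(decompose_efficiency(0.73, 0.73), 1.0)
  expect_error(decompose_efficiency(0.5, 0), "positive")
  p <- random_panel(7, 2, 2, seed = 41)
  cte <- score_panel(p, technology_spec("crs"))$scores
  pte <- score_panel(p, technology_spec("vrs"))$scores
  expect_true(all(decompose_efficiency(cte, pte) <= 1 + 1e-7))
})

test_that("technology_spec rejects invalid parameters", {
  expect_error(technology_spec(epsilon_x = 1.5), "\\[0, 1\\]")
  expect_error(technology_spec(input_weights = c(0.5, 0.4)), "sum to 1")
  expect_error(technology_spec(input_weights = c(-0.5, 1.5)),
               "nonnegative")
})
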