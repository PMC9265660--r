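test_that("panel construction validates dimensions and positivity", {
  p <- toy_fixture()
  expect_s3_class(p, "panel_dataset")
  expect_identical(length(p$dmu_ids), 4L)
  expect_identical(p$periods, c(2000L, 2001L))

  # minimal 1x1 panel is valid
  p1 <- panel_dataset(array(1, c(1, 1, 1)), array(1, c(1, 1, 1)))
  expect_s3_class(p1, "panel_dataset")

  # zero input cell is rejected with the cell address
  X <- array(1, c(2, 2, 1)); X[2, 1, 1] <- 0
  expect_error(panel_dataset(X, array(1, c(2, 2, 1))),
               "nonpositive input.*DMU2.*year 1", ignore.case = TRUE)

  # gap in the period sequence is rejected
  expect_error(
    panel_dataset(array(1, c(2, 3, 1)), array(1, c(2, 3, 1)),
                  periods = c(2000L, 2001L, 2005L)),
    "increasing with no gaps")
})

test_that("wide and long CSV dialects load to the same panel", {
  g <- generate_panel(simulation_config(J = 4, T = 3, seed = 5))
  wide <- tempfile(fileext = ".csv")
  schema <- write_panel(g$panel, wide)
  p2 <- load_panel(wide, schema)
  expect_equal(p2$X, g$panel$X)
  expect_equal(p2$Y, g$panel$Y)
  expect_equal(p2$B, g$panel$B)
  expect_equal(p2$Z, g$panel$Z)
  expect_equal(p2$W, g$panel$W, ignore_attr = TRUE)

  # long dialect round-trips through the same panel
  long <- tempfile(fileext = ".csv")
  df <- as.data.frame(g$panel)
  df2 <- df[df$role != "weight", c("unit", "year", "variable", "value")]
  utils::write.csv(df2, long, row.names = FALSE)
  schema_long <- schema
  schema_long$format <- "long"
  schema_long$weight <- NULL
  p3 <- load_panel(long, schema_long)
  expect_equal(p3$X, g$panel$X)
  expect_equal(p3$Z, g$panel$Z)
})

test_that("toy fixture CSV loads via its shipped YAML schema", {
  csv <- system.file("extdata", "toy_panel.csv", package = "ebmgml")
  schema <- system.file("extdata", "toy_schema.yaml", package = "ebmgml")
  p <- load_panel(csv, schema)
  expect_equal(p$X, toy_fixture()$X)
  expect_equal(p$Y, toy_fixture()$Y)
  # numeric cells round-trip bit-identically through write_panel
  out <- tempfile(fileext = ".csv")
  sc <- write_panel(p, out)
  p2 <- load_panel(out, sc)
  expect_identical(p2$X, p$X)
  expect_identical(p2$Y, p$Y)
})

test_that("load_panel fails loudly on bad files", {
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(unit = "A", year = 2000, x = 1),
                   csv, row.names = FALSE)
  expect_error(load_panel(csv, list(inputs = "x", outputs = "y")),
               "missing column")
  # unbalanced panel
  utils::write.csv(data.frame(unit = c("A", "A", "B"),
                              year = c(2000, 2001, 2000),
                              x = 1, y = 1), csv, row.names = FALSE)
  expect_error(load_panel(csv, list(inputs = "x", outputs = "y")),
               "unbalanced")
  # zero input
  utils::write.csv(data.frame(unit = c("A", "B"), year = 2000,
                              x = c(1, 0), y = 1), csv, row.names = FALSE)
  expect_error(load_panel(csv, list(inputs = "x", outputs = "y")),
               "nonpositive input")
  expect_error(load_panel("nope.csv", list(inputs = "x", outputs = "y")),
               "not found")
})

test_that("sown-share apportionment follows the proportional rule", {
  expect_equal(apportion_by_sown_share(100, 0.5), 50)
  expect_equal(apportion_by_sown_share(7.3, 1), 7.3)
  expect_equal(apportion_by_sown_share(7.3, 0), 0)
  expect_error(apportion_by_sown_share(1, 1.2), "\\[0, 1\\]")
  expect_error(apportion_by_sown_share(-1, 0.5), "nonnegative")
})

test_that("carbon aggregation is an inner product and linear in activity", {
  cf <- carbon_coefficients(rep(1, 6))
  expect_equal(aggregate_carbon(rep(1, 6), cf), 6)
  expect_equal(aggregate_carbon(c(2, 0, 0, 0, 0, 0),
                                carbon_coefficients(c(3, 1, 1, 1, 1, 1))), 6)
  set.seed(1)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    a <- runif(k); b <- runif(k); cf <- runif(k)
    # brute-force summation oracle
    expect_equal(aggregate_carbon(a, cf), sum(vapply(
      seq_len(k), function(i) a[i] * cf[i], numeric(1))))
    expect_equal(aggregate_carbon(a + b, cf),
                 aggregate_carbon(a, cf) + aggregate_carbon(b, cf))
  }
  expect_error(aggregate_carbon(1:3, carbon_coefficients(1:2)), "dimension")
  expect_error(aggregate_carbon(c(-1, 1), 1:2), "nonnegative")
  expect_error(carbon_coefficients(c(-1, 2)), "nonnegative")
})
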