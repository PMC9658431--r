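test_that("standardization yields zero mean, unit sd, and rejects constants", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(3)
  z <- standardize(rnorm(50, 10, 4))
  expect_equal(mean(z), 0)
  expect_equal(stats::sd(z), 1)
  expect_error(standardize(rep(2, 10), name = "u2"), "u2")
})

test_that("direct paths are standardized OLS coefficients", {
  set.seed(11)
  # single driver: the path equals the correlation
  x <- rnorm(100)
  y <- 2 * x + rnorm(100)
  P1 <- direct_path_coefficients(cbind(x = x), y)
  expect_equal(unname(P1), cor(x, y), tolerance = 1e-12)
  # exactly orthogonal drivers: each path equals its own correlation
  X <- cbind(a = rep(c(1, 1, -1, -1), 25), b = rep(c(1, -1, 1, -1), 25))
  yo <- 0.5 * X[, 1] - 0.3 * X[, 2] + rnorm(100, 0, 0.2)
  Po <- direct_path_coefficients(X, yo)
  expect_equal(unname(Po), unname(as.vector(cor(X, yo))), tolerance = 1e-12)
  # generating model on the standardized scale (unit-variance response)
  set.seed(12)
  n <- 1e4
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  yy <- 0.7 * z1 + 0.2 * z2 + rnorm(n, 0, sqrt(1 - 0.7^2 - 0.2^2))
  P <- direct_path_coefficients(cbind(z1 = z1, z2 = z2), yy)
  expect_lt(abs(P["z1"] - 0.7), 0.02)
  expect_lt(abs(P["z2"] - 0.2), 0.02)
  # cross-check against lm on standardized variables
  Pl <- coef(lm(standardize(yy) ~ standardize(z1) + standardize(z2)))[-1]
  expect_equal(unname(P), unname(Pl), tolerance = 1e-10)
  expect_error(direct_path_coefficients(cbind(c = rep(1, 100)), yy[1:100]),
               "zero-variance")
  expect_error(direct_path_coefficients(cbind(z1 = z1, z1b = z1), yy),
               "singular|collinear")
})

test_that("indirect paths are r_ij * P_j with empty diagonal", {
  R <- diag(2)
  colnames(R) <- rownames(R) <- c("a", "b")
  ind <- indirect_path_coefficients(R, c(0.5, 0.3))
  expect_true(all(ind$indirect == 0, na.rm = TRUE))
  expect_equal(unname(ind$total), c(0, 0))
  # reference two-season table: one shared correlation drives two cells
  r_rn_vpd <- 0.728  # back-solved: 0.257 / 0.353
  expect_equal(r_rn_vpd * 0.353, 0.257, tolerance = 1e-3)
  expect_equal(r_rn_vpd * 0.744, 0.541, tolerance = 2e-3)
  ref <- reference_path_table()
  ta19 <- ref[ref$year == 2019 & ref$factor == "Ta", ]
  expect_equal(ta19$ind_Rn + ta19$ind_VPD + ta19$ind_u2, 0.919)
})

test_that("decision coefficients reproduce all reference cells to 0.001", {
  expect_equal(decision_coefficients(0.744, 0.952), 0.863, tolerance = 2e-3)
  expect_equal(decision_coefficients(0.353, 0.833), 0.463489,
               tolerance = 1e-6)
  p <- runif(10, -1, 1)
  expect_equal(decision_coefficients(p, p), p^2)
  ref <- reference_path_table()
  expect_true(all(abs(decision_coefficients(ref$P, ref$r) - ref$Rd) <=
                    0.001))
})

test_that("the path identity r = P + total_indirect holds to numerical precision", {
  set.seed(21)
  n <- 500
  Rn <- rnorm(n)
  Ta <- 0.6 * Rn + 0.8 * rnorm(n)
  VPD <- 0.5 * Rn + 0.4 * Ta + 0.5 * rnorm(n)
  u2 <- 0.1 * Rn + rnorm(n)
  y <- 0.8 * Rn + 0.3 * VPD - 0.1 * Ta + 0.05 * u2 + rnorm(n, 0, 0.3)
  X <- cbind(Rn = Rn, Ta = Ta, VPD = VPD, u2 = u2)
  P <- direct_path_coefficients(X, y)
  ind <- indirect_path_coefficients(cor(X), P)
  r <- as.vector(cor(X, y))
  expect_equal(r, unname(P + ind$total), tolerance = 1e-12)
})

test_that("path analysis filters the ventilation window and ranks Rn first", {
  inp <- tiny_inputs(seed = 5)
  fit <- simulate_et(inp$met, inp$crop, inp$soil)
  d <- cbind(fit[, c("timestamp", "Rn", "Ta", "VPD", "ET")],
             u2 = inp$met$u2)
  pa <- path_analysis(d, window = c(9, 16))
  n_days <- length(unique(as.Date(d$timestamp)))
  expect_equal(pa$n, 8L * n_days)  # inclusive bounds: 8 hourly rows/day
  expect_equal(pa$table$driver[which.max(pa$table$r)], "Rn")
  # identity residual is reported and ~0 when paths come from the same data
  expect_true(all(abs(pa$table$residual) < 1e-10))
  expect_output(print(pa), "via_Rn")
  expect_error(path_analysis(d[1:3, ], window = c(9, 16)), "too few")
  expect_error(path_analysis(d[, -2]), "missing column")
})
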