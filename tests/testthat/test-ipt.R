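test_that("radiation partition conserves net radiation exactly", {
  expect_equal(partition_radiation(400, 1), list(Rns = 400, Rnc = 0))
  p <- partition_radiation(400, 0.25)
  expect_equal(p$Rns, 100)
  expect_equal(p$Rnc, 300)
  set.seed(1)
  rn <- runif(100, -50, 600)
  tau <- runif(100, 0.01, 1)
  pp <- partition_radiation(rn, tau)
  expect_equal(pp$Rns + pp$Rnc, rn)
})

test_that("soil heat flux closure is linear in soil net radiation", {
  expect_equal(soil_heat_flux(100, 0.45), 45)
  expect_equal(soil_heat_flux(100, 0), 0)
  expect_equal(soil_heat_flux(-40, 0.45), -18)  # nighttime passes through
  expect_error(soil_heat_flux(100, 1), "f_G")
})

test_that("equilibrium evaporation matches the radiation-limited closed form", {
  expect_equal(equilibrium_evaporation(300, 300, 0.2, 0.067), 0)
  expect_equal(equilibrium_evaporation(350, 50, 0.199, 0.0668), 224.605,
               tolerance = 1e-4)
  # gamma -> 0 limit approaches available energy
  expect_equal(equilibrium_evaporation(300, 0, 0.2, 1e-9), 300,
               tolerance = 1e-6)
})

test_that("bulk coefficient equals the component assembly on random draws", {
  set.seed(101)
  n <- 1000
  f_sw <- runif(n)
  f_t <- runif(n, 0.2, 1)
  f_s <- runif(n)
  k <- runif(n, 0.3, 1.2)
  LAI <- runif(n, 0.05, 4)
  f_G <- runif(n, 0, 0.9)
  delta <- runif(n, 0.08, 0.3)
  gamma <- runif(n, 0.05, 0.08)
  Rn <- runif(n, 20, 600)
  tau <- exp(-k * LAI)
  got <- improved_pt_coefficient(tau, f_sw, f_t, f_s, f_G)
  want <- vapply(seq_len(n), function(i) {
    alpha_e_component_oracle(f_sw[i], f_t[i], f_s[i], k[i], LAI[i],
                             f_G[i], delta[i], gamma[i], Rn[i])
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("unconstrained model with no soil heat flux reduces to classical PT", {
  for (lai in c(0.1, 0.5, 1.7, 3.46)) {
    tau <- transmission_fraction(0.7, lai)
    expect_equal(
      improved_pt_coefficient(tau, f_sw = 1, f_t = 1, f_s = 0, f_G = 0),
      1.26, tolerance = 1e-12)
  }
  # bare soil limit: only the water-stressed soil term remains
  expect_warning(
    a <- improved_pt_coefficient(1, f_sw = 0.6, f_t = 1, f_s = 0,
                                 f_G = 0.45),
    "tau = 1")
  expect_equal(a, 0.6 * 1.26, tolerance = 1e-12)
})

test_that("bulk coefficient responds monotonically to each constraint", {
  tau <- transmission_fraction(0.7, 1.5)
  g <- seq(0, 1, by = 0.05)
  a_sw <- improved_pt_coefficient(tau, f_sw = g, f_t = 0.9, f_s = 0.2)
  a_ft <- improved_pt_coefficient(tau, f_sw = 0.8, f_t = pmax(g, 1e-6),
                                  f_s = 0.2)
  a_fs <- improved_pt_coefficient(tau, f_sw = 0.8, f_t = 0.9, f_s = g)
  expect_true(all(diff(a_sw) >= 0))
  expect_true(all(diff(a_ft) >= 0))
  expect_true(all(diff(a_fs) <= 0))
})

test_that("hourly simulation preserves the flux identity and unit conversion", {
  met <- toy_met(48)
  crop <- toy_crop(unique(as.Date(met$timestamp)), lai = 2)
  h <- simulate_et(met, crop)
  expect_equal(h$lambda_ET, h$lambda_E + h$lambda_T)
  expect_equal(h$Rns + h$Rnc, h$Rn)
  expect_true(all(h$ET >= 0))
  expect_equal(h$ET[h$lambda_ET > 0],
               h$lambda_ET[h$lambda_ET > 0] * 3600 / 2.45e6)
  # a flux of 245 W/m2 is 0.36 mm/h
  i <- which.max(h$lambda_ET)
  expect_equal(h$ET[i] / h$lambda_ET[i], 0.36 / 245, tolerance = 1e-12)
})

test_that("a day with no available energy evaporates nothing", {
  met <- toy_met(24)
  met$Rn <- 0
  crop <- toy_crop(unique(as.Date(met$timestamp)), lai = 2)
  h <- simulate_et(met, crop, params = ipt_params(f_G = 0))
  expect_equal(aggregate_daily(h)$ET, 0)
})

test_that("measured soil heat flux overrides the f_G closure", {
  met <- toy_met(24)
  crop <- toy_crop(unique(as.Date(met$timestamp)), lai = 2)
  met$G <- 10
  h <- simulate_et(met, crop)
  expect_equal(h$G, rep(10, 24))
  hg <- simulate_et(met[setdiff(names(met), "G")], crop)
  expect_equal(hg$G, 0.45 * hg$Rns)
})

test_that("missing crop dates or soil timestamps raise explicit gap errors", {
  met <- toy_met(48)
  crop1 <- toy_crop(as.Date(met$timestamp[1]), lai = 2)  # second day missing
  expect_error(simulate_et(met, crop1), "missing date")
  crop <- toy_crop(unique(as.Date(met$timestamp)), lai = 2)
  soil <- data.frame(timestamp = met$timestamp[-10], theta = 0.25)
  expect_error(simulate_et(met, crop, soil), "missing 1 timestamp")
})

test_that("daily aggregation sums hours, conserves totals and flags gaps", {
  met <- toy_met(48)
  crop <- toy_crop(unique(as.Date(met$timestamp)), lai = 2)
  h <- simulate_et(met, crop)
  h$ET <- rep(0.1, 48)
  d <- aggregate_daily(h)
  expect_equal(d$ET, c(2.4, 2.4))
  expect_false(any(d$flagged))
  d2 <- aggregate_daily(h[-5, ])
  expect_true(d2$flagged[1])
  expect_equal(sum(d2$ET), sum(h$ET[-5]))
  expect_false(aggregate_daily(h[-5, ], max_missing_frac = 0.1)$flagged[1])
  expect_error(aggregate_daily(h[0, ]), "empty")
})

test_that("the ipt object carries fitted values, coefficients and residuals", {
  inp <- tiny_inputs()
  par <- ipt_params(senescence_onset = inp$config$stages$late$start)
  fit0 <- ipt(inp$met, inp$crop, inp$soil, params = par)
  obs <- data.frame(timestamp = fit0$hourly$timestamp,
                    ET = generate_observed_et(fit0$hourly$ET, 0.05,
                                              seed = 9))
  fit <- ipt(inp$met, inp$crop, inp$soil, observed = obs, params = par)
  expect_s3_class(fit, "ipt")
  expect_equal(unname(coef(fit)["f_G"]), 0.45)
  expect_equal(length(fitted(fit)), nrow(inp$met))
  expect_equal(residuals(fit), obs$ET - fit$hourly$ET)
  expect_error(residuals(fit0), "observed")
  ph <- predict(fit, type = "hourly")
  pd <- predict(fit, type = "daily")
  expect_equal(ph$ET, fit$hourly$ET)
  expect_equal(sum(pd$ET), sum(fit$hourly$ET))
  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_equal(dim(sims), c(nrow(inp$met), 3L))
  expect_true(all(sims >= 0))
  expect_output(print(fit), "season ET total")
  expect_output(print(summary(fit)), "d_IA")
})

test_that("the soil heat fraction is recoverable from noisy latent heat flux", {
  inp <- tiny_inputs(seed = 11)
  par <- ipt_params()
  sim <- simulate_et(inp$met, inp$crop, inp$soil, par)
  obs <- with_seed_test(21, sim$lambda_ET * (1 + rnorm(nrow(sim), 0, 0.05)))
  fitfg <- fit_soil_heat_fraction(inp$met, inp$crop, inp$soil, obs,
                                  grid = seq(0.2, 0.7, by = 0.01))
  expect_lt(abs(fitfg$f_G - 0.45), 0.05)
})
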