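test_that("microclimate generation is deterministic under a fixed seed", {
  sc <- tiny_scenario()
  a <- generate_microclimate(sc, seed = 7)
  b <- generate_microclimate(sc, seed = 7)
  expect_identical(a, b)
  c <- generate_microclimate(sc, seed = 8)
  expect_false(isTRUE(all.equal(a$Rn, c$Rn)))
  s1 <- generate_soil_moisture(sc, seed = 7)
  s2 <- generate_soil_moisture(sc, seed = 7)
  expect_identical(s1, s2)
})

test_that("generated radiation hits the stage-mean targets with a 13-14 h peak", {
  sc <- greenhouse_scenario("2019")
  met <- generate_microclimate(sc, seed = 2)
  hr <- as.integer(format(met$timestamp, "%H"))
  stage <- iptet:::scenario_stage(sc, as.Date(met$timestamp))
  for (s in c("initial", "development", "middle", "late")) {
    m <- mean(met$Rn[stage == s & hr >= 6 & hr <= 18])
    target <- sc$stage_means[[s]]$Rn
    expect_lt(abs(m - target) / target, 0.02)
  }
  peak_hr <- as.integer(names(which.max(tapply(met$Rn, hr, mean))))
  expect_true(peak_hr %in% c(13L, 14L))
  # Ta and VPD maxima lag the radiation peak
  ta_hr <- as.integer(names(which.max(tapply(met$Ta, hr, mean))))
  expect_gte(ta_hr, peak_hr)
  # greenhouse wind stays light
  u2_daily <- tapply(met$u2, as.Date(met$timestamp), mean)
  expect_true(all(u2_daily < 0.5))
  expect_true(all(met$u2 >= 0))
})

test_that("crop phenology rises to the configured peak and senesces late", {
  sc <- greenhouse_scenario("2019")
  crop <- generate_crop(sc)
  peak_date <- sc$stages$middle$start +
    floor(as.numeric(sc$stages$middle$end - sc$stages$middle$start) / 2)
  expect_equal(crop$lai[crop$date == peak_date], 3.46)
  expect_equal(max(crop$lai), 3.46)
  expect_true(all(crop$lai[crop$stage == "initial"] < 0.8))
  late <- crop$lai[crop$stage == "late"]
  expect_true(all(diff(late) < 0))
  expect_true(all(crop$height <= 145))
})

test_that("soil moisture dips below the stress threshold only before irrigation starts", {
  sc <- greenhouse_scenario("2019")
  soil <- generate_soil_moisture(sc, seed = 4)
  stage <- iptet:::scenario_stage(sc, as.Date(soil$timestamp))
  Se <- effective_saturation(soil$theta, sc$soil$theta_s, sc$soil$theta_w)
  expect_lt(min(Se[stage == "initial"]), 0.75)
  post <- Se[stage %in% c("development", "middle", "late")]
  expect_true(all(post >= 0.75))
  expect_true(all(water_stress_coefficient(post) == 1))
  expect_true(all(soil$theta_05 >= sc$soil$theta_w &
                    soil$theta_05 <= sc$soil$theta_s))
  expect_true(all(soil$theta_10 >= sc$soil$theta_w &
                    soil$theta_10 <= sc$soil$theta_s))
})

test_that("observed-ET generator is an exact copy at zero noise and nonnegative always", {
  et <- c(0, 0.1, 0.3, 0.2)
  expect_equal(generate_observed_et(et, 0), et)
  obs <- generate_observed_et(rep(0.01, 500), 2, seed = 6)
  expect_true(all(obs >= 0))
  expect_identical(generate_observed_et(et, 0.1, seed = 3),
                   generate_observed_et(et, 0.1, seed = 3))
  expect_error(generate_observed_et(et, -1), "noise_cv")
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(generate_microclimate(tiny_scenario(), seed = 99))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("scenario presets validate their structure", {
  sc <- greenhouse_scenario("2020")
  expect_s3_class(sc, "gh_scenario")
  expect_equal(sc$stage_means$middle$Rn, 142.53)
  expect_error(greenhouse_scenario("2019", start = as.Date("2018-01-01")),
               "span")
  expect_error(greenhouse_scenario("2019", soil = list(theta_w = 0.5)),
               "theta_w")
  expect_output(print(sc), "middle")
})

test_that("end-to-end: simulated season recovers the injected observation noise", {
  inp <- tiny_inputs(seed = 13)
  fit <- simulate_et(inp$met, inp$crop, inp$soil)
  obs <- generate_observed_et(fit$ET, 0.05, seed = 14)
  m <- et_metrics(obs, fit$ET)
  expect_gt(m$d_ia, 0.95)
  # RMSE close to the 5% multiplicative noise level on the active hours
  active <- fit$ET > 0
  expected_rmse <- 0.05 * sqrt(mean(fit$ET[active]^2))
  expect_lt(abs(rmse(obs[active], fit$ET[active]) - expected_rmse) /
              expected_rmse, 0.35)
})
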