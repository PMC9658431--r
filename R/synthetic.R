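# Seeded synthetic greenhouse data: hourly microclimate, daily crop
# phenology, hourly topsoil moisture with drip irrigation events, and
# lysimeter-like "observed" ET.  Analytic diurnal curves plus AR(1)
# noise -- enough to exercise every model code path, not a physical
# greenhouse energy-balance simulator.

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

ar1_noise <- function(n, rho, sd) {
  if (sd == 0 || n == 0L) return(numeric(n))
  z <- stats::rnorm(n)
  x <- numeric(n)
  x[1L] <- z[1L]
  if (n > 1L) {
    a <- sqrt(1 - rho^2)
    for (i in 2:n) x[i] <- rho * x[i - 1L] + a * z[i]
  }
  sd * x
}

# half-sinusoid diurnal shape: 0 outside [sunrise, sunset], rising to 1
# at peak_hour and back to 0 at sunset
diurnal_shape <- function(hours, sunrise, sunset, peak) {
  s <- numeric(length(hours))
  up <- hours >= sunrise & hours <= peak
  down <- hours > peak & hours <= sunset
  s[up] <- sin(pi / 2 * (hours[up] - sunrise) / (peak - sunrise))
  s[down] <- cos(pi / 2 * (hours[down] - peak) / (sunset - peak))
  s
}

#' Generate hourly greenhouse microclimate
#'
#' Net radiation follows a half-sinusoid daytime curve peaking at the
#' configured hour, modulated by day-to-day lognormal AR(1) "cloudiness"
#' and small hourly noise, then rescaled stage-by-stage so that the
#' 6:00-18:00 stage mean matches the configured target exactly.  Air
#' temperature and VPD track the radiation shape with a configurable lag
#' (1 h by default) plus AR(1) noise around the stage means; wind speed
#' is a small positive series with daily mean well below 0.5 m s^-1.
#'
#' @param config A [greenhouse_scenario()] object.
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @return Hourly data frame with `timestamp`, `Rn`, `Ta`, `RH`, `VPD`,
#'   `u2`.
#' @export
generate_microclimate <- function(config, seed = 1) {
  stopifnot(inherits(config, "gh_scenario"))
  with_seed(seed, {
    days <- seq(config$start, config$end, by = "day")
    nd <- length(days)
    hours <- 0:23
    ts <- as.POSIXct(paste(rep(days, each = 24L),
                           sprintf("%02d:00:00", rep(hours, nd))),
                     tz = "UTC")
    hr <- rep(hours, nd)
    stage <- scenario_stage(config, rep(days, each = 24L))
    if (anyNA(stage)) stop("dates outside the stage calendar", call. = FALSE)

    di <- config$diurnal
    shape <- diurnal_shape(hr, di$sunrise, di$sunset, di$peak_hour)
    lag_hr <- (hr - di$lag_hours) %% 24
    shape_lag <- diurnal_shape(lag_hr, di$sunrise, di$sunset, di$peak_hour)

    nz <- config$noise
    cloud <- exp(ar1_noise(nd, nz$rho, nz$rn_day_cv))
    cloud <- cloud / mean(cloud)
    Rn <- shape * rep(cloud, each = 24L) *
      (1 + nz$rn_hour_cv * stats::rnorm(length(hr)))
    Rn <- pmax(Rn, 0)

    # rescale each stage so the 6:00-18:00 mean hits the target
    in_avg <- hr >= 6 & hr <= 18
    for (s in names(config$stages)) {
      sel <- stage == s
      if (!any(sel)) next
      m <- mean(Rn[sel & in_avg])
      if (m <= 0) stop("degenerate radiation draw for stage ", s,
                       call. = FALSE)
      Rn[sel] <- Rn[sel] * config$stage_means[[s]]$Rn / m
    }
    night <- hr < di$sunrise | hr >= di$sunset
    Rn[night] <- di$rn_night + stats::rnorm(sum(night), 0, 1)

    shape_c <- shape_lag - mean(shape_lag[1:24])
    Ta <- numeric(length(hr))
    VPD <- numeric(length(hr))
    u2 <- numeric(length(hr))
    for (s in names(config$stages)) {
      sel <- stage == s
      if (!any(sel)) next
      m <- config$stage_means[[s]]
      Ta[sel] <- m$Ta + config$diurnal$ta_amp * shape_c[sel] +
        ar1_noise(sum(sel), nz$rho, nz$ta_sd)
      VPD[sel] <- pmax(0.02, m$VPD * (1 + config$diurnal$vpd_amp_frac *
                                        shape_c[sel]) +
                         ar1_noise(sum(sel), nz$rho, nz$vpd_sd))
      u2[sel] <- pmax(0, m$u2 + config$diurnal$u2_amp *
                        (shape[sel] - mean(shape[1:24])) +
                        ar1_noise(sum(sel), nz$rho, nz$u2_sd))
    }
    RH <- pmin(100, pmax(5, 100 * (1 - VPD / saturation_vapor_pressure(Ta))))

    data.frame(timestamp = ts, Rn = Rn, Ta = Ta, RH = RH, VPD = VPD,
               u2 = u2)
  })
}

#' Generate daily crop state (LAI and plant height)
#'
#' Deterministic phenology: LAI rises from ~0.1 at transplanting through
#' the development stage, peaks at the configured maximum (default 3.46)
#' in the middle of the middle stage, and declines through the late stage
#' (leaf senescence) -- a downward-opening-parabola-like trajectory.
#' Sparse knots are interpolated daily with the shape-preserving PCHIP of
#' [interpolate_lai()].
#'
#' @param config A [greenhouse_scenario()] object.
#' @return Daily data frame with `date`, `lai`, `height` (cm) and
#'   `stage`.
#' @export
generate_crop <- function(config) {
  stopifnot(inherits(config, "gh_scenario"))
  st <- config$stages
  peak_date <- st$middle$start +
    floor(as.numeric(st$middle$end - st$middle$start) / 2)
  lai_peak <- config$crop$lai_peak
  h_peak <- config$crop$height_peak
  dev_mid <- st$development$start +
    floor(as.numeric(st$development$end - st$development$start) / 2)
  knots <- data.frame(
    date = c(st$initial$start, st$initial$end, dev_mid, st$middle$start,
             peak_date, st$late$start, st$late$end),
    lai = c(0.12, 0.55, 0.45 * lai_peak, 0.87 * lai_peak, lai_peak,
            0.95 * lai_peak, 0.70 * lai_peak),
    height = c(20, 48, 0.62 * h_peak, 0.93 * h_peak, h_peak,
               0.99 * h_peak, 0.95 * h_peak)
  )
  dates <- seq(config$start, config$end, by = "day")
  data.frame(
    date = dates,
    lai = interpolate_lai(knots$date, knots$lai, dates),
    height = interpolate_lai(knots$date, knots$height, dates),
    stage = scenario_stage(config, dates)
  )
}

#' Generate hourly topsoil moisture with drip irrigation events
#'
#' Exponential drydown between irrigation events with an instantaneous
#' refill toward `refill_frac * theta_s`.  The initial stage receives
#' only the transplanting irrigation, so effective saturation dips below
#' 0.75 (an early-season water deficit); from the development stage
#' onward events fire whenever saturation reaches the trigger, keeping
#' `Se >= 0.75` and hence the soil water stress coefficient at 1.
#'
#' @param config A [greenhouse_scenario()] object.
#' @param seed Integer seed for the small sensor-noise component.
#' @return Hourly data frame with `timestamp`, `theta_05`, `theta_10`
#'   (the two sensor depths, cm^3 cm^-3) and their mean `theta`.
#' @export
generate_soil_moisture <- function(config, seed = 1) {
  stopifnot(inherits(config, "gh_scenario"))
  so <- config$soil
  if (so$theta_w >= so$theta_s) stop("theta_w must be below theta_s",
                                     call. = FALSE)
  with_seed(seed, {
    days <- seq(config$start, config$end, by = "day")
    nd <- length(days)
    n <- nd * 24L
    ts <- as.POSIXct(paste(rep(days, each = 24L),
                           sprintf("%02d:00:00", rep(0:23, nd))),
                     tz = "UTC")
    stage <- scenario_stage(config, rep(days, each = 24L))
    trigger_theta <- so$theta_w + so$trigger_se * (so$theta_s - so$theta_w)

    theta <- numeric(n)
    th <- so$theta0
    for (i in seq_len(n)) {
      rate <- if (stage[i] == "initial") so$drydown_initial else
        so$drydown_later
      th <- so$theta_w + (th - so$theta_w) * exp(-rate / 24)
      if (stage[i] != "initial" && th <= trigger_theta) {
        th <- so$refill_frac * so$theta_s
      }
      theta[i] <- th
    }
    clip <- function(x) pmin(pmax(x, so$theta_w), so$theta_s)
    theta_05 <- clip(theta + stats::rnorm(n, 0, so$sensor_sd))
    theta_10 <- clip(theta + stats::rnorm(n, 0, so$sensor_sd))
    data.frame(timestamp = ts, theta_05 = theta_05, theta_10 = theta_10,
               theta = (theta_05 + theta_10) / 2)
  })
}

#' Generate lysimeter-like observed ET
#'
#' Multiplicative Gaussian perturbation of a model ET series, truncated
#' at zero: `observed = pmax(0, model * (1 + eps))`,
#' `eps ~ N(0, noise_cv)`.
#'
#' @param et Model ET series (any units).
#' @param noise_cv Coefficient of variation of the noise (>= 0).
#' @param seed Optional integer seed; `NULL` draws from the current RNG
#'   state (used by [simulate.ipt()], which seeds once for all
#'   replicates).
#' @return Perturbed non-negative series, same length as `et`.
#' @export
generate_observed_et <- function(et, noise_cv = 0.05, seed = NULL) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  draw <- function() pmax(0, et * (1 + stats::rnorm(length(et), 0, noise_cv)))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate a complete synthetic season
#'
#' Convenience wrapper producing aligned microclimate, crop and soil
#' series for one scenario.  All randomness flows from `seed` (the soil
#' generator uses `seed + 1` so its noise is independent of the
#' microclimate draw).
#'
#' @param config A [greenhouse_scenario()] object.
#' @param seed Integer seed.
#' @return List with `met`, `crop`, `soil` and the `config`.
#' @export
generate_scenario <- function(config, seed = 1) {
  list(met = generate_microclimate(config, seed),
       crop = generate_crop(config),
       soil = generate_soil_moisture(config, seed + 1L),
       config = config)
}
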