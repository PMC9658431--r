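# Core model: radiation/energy partition, equilibrium evaporation, the
# bulk coefficient alpha_e, hourly lambda-ET and ET depth, daily totals,
# and the `ipt` model object with its methods.

#' Partition net radiation between soil and canopy
#'
#' \eqn{R_{ns} = \tau R_n}, \eqn{R_{nc} = (1 - \tau) R_n}; the two parts
#' sum to `Rn` exactly.
#'
#' @param Rn Net radiation, W m^-2.
#' @param tau Transmission fraction in (0, 1].
#' @return A list with components `Rns` and `Rnc` (W m^-2).
#' @export
partition_radiation <- function(Rn, tau) {
  if (any(!is.finite(tau) | tau <= 0 | tau > 1)) {
    stop("tau must lie in (0, 1]", call. = FALSE)
  }
  list(Rns = tau * Rn, Rnc = (1 - tau) * Rn)
}

#' Soil heat flux as a fraction of soil net radiation
#'
#' \eqn{G = f_G R_{ns}}.  Used as closure when no measured G is available;
#' a measured G column always takes precedence in [simulate_et()].
#'
#' @param Rns Net radiation reaching the soil, W m^-2.
#' @param f_G Fraction in \[0, 1) (0.45 for the greenhouse soil studied).
#' @return Soil heat flux G, W m^-2 (negative Rns passes through).
#' @export
soil_heat_flux <- function(Rns, f_G = 0.45) {
  if (f_G < 0 || f_G >= 1) stop("f_G must lie in [0, 1)", call. = FALSE)
  f_G * Rns
}

#' Equilibrium evaporation
#'
#' The radiation-limited latent heat flux
#' \eqn{\lambda ET_{eq} = \Delta/(\Delta + \gamma)\,(R_n - G)}.
#'
#' @param Rn Net radiation, W m^-2.
#' @param G Soil heat flux, W m^-2.
#' @param delta Slope of the saturation vapour pressure curve, kPa K^-1.
#' @param gamma Psychrometric constant, kPa K^-1.
#' @return Equilibrium latent heat flux, W m^-2.
#' @export
equilibrium_evaporation <- function(Rn, G, delta, gamma) {
  if (any(delta <= 0) || any(gamma <= 0)) {
    stop("delta and gamma must be positive", call. = FALSE)
  }
  delta / (delta + gamma) * (Rn - G)
}

#' Bulk improved Priestley-Taylor coefficient
#'
#' Closed form obtained by assembling the soil and canopy latent-heat
#' components over the equilibrium evaporation with the soil heat flux
#' closure \eqn{G = f_G R_{ns}}:
#' \deqn{\alpha_e = \frac{f_{sw}\,\alpha_{s0}(1 - f_G)\tau +
#'   (1 - f_s)\,f_t\,\alpha_{c0}(1 - \tau)}{1 - f_G\,\tau},
#'   \qquad \tau = e^{-k\,\mathrm{LAI}}.}
#' With no constraints active and \eqn{f_G = 0} it reduces exactly to the
#' classical coefficient \eqn{\alpha_0} for any LAI.
#'
#' @param tau Transmission fraction in (0, 1].
#' @param f_sw Soil water stress coefficient in \[0, 1\].
#' @param f_t Temperature constraint in (0, 1\].
#' @param f_s Leaf senescence index in \[0, 1\].
#' @param f_G Soil heat flux fraction in \[0, 1).
#' @param alpha_0 Recommended Priestley-Taylor coefficient.
#' @param tau_c Critical transmission fraction.
#' @return alpha_e (dimensionless).
#' @examples
#' improved_pt_coefficient(tau = 0.4, f_sw = 1, f_t = 1, f_s = 0, f_G = 0)
#' @export
improved_pt_coefficient <- function(tau, f_sw = 1, f_t = 1, f_s = 0,
                                    f_G = 0.45, alpha_0 = 1.26,
                                    tau_c = 0.55) {
  a_s0 <- alpha_s0(tau, tau_c, alpha_0)
  a_c0 <- alpha_c0(alpha_0, a_s0, tau)
  (f_sw * a_s0 * (1 - f_G) * tau + (1 - f_s) * f_t * a_c0 * (1 - tau)) /
    (1 - f_G * tau)
}

.soil_theta <- function(soil) {
  if ("theta" %in% names(soil)) return(soil$theta)
  depth_cols <- intersect(c("theta_05", "theta_10"), names(soil))
  if (length(depth_cols) == 0L) {
    stop("soil table needs a 'theta' column or 'theta_05'/'theta_10' columns",
         call. = FALSE)
  }
  rowMeans(soil[, depth_cols, drop = FALSE])
}

.match_series <- function(ref_ts, ts, what) {
  idx <- match(ref_ts, ts)
  if (anyNA(idx)) {
    missing <- ref_ts[is.na(idx)]
    shown <- utils::head(format(missing), 10L)
    stop(sprintf("%s series is missing %d timestamp(s): %s%s", what,
                 length(missing), paste(shown, collapse = ", "),
                 if (length(missing) > 10L) ", ..." else ""),
         call. = FALSE)
  }
  idx
}

#' Hourly evapotranspiration with the improved Priestley-Taylor model
#'
#' Runs the full model over aligned hourly meteorology, daily crop state
#' and (optionally) hourly topsoil moisture.  Per hour it derives the
#' transmission fraction, partitions net radiation, computes the three
#' constraint coefficients, the bulk coefficient alpha_e, the latent heat
#' fluxes (total, soil and canopy) and the ET depth in mm.
#'
#' @param met Hourly data frame with columns `timestamp` (POSIXct,
#'   strictly increasing), `Rn` (W m^-2), `Ta` (degrees C) and either
#'   `VPD` (kPa) or `RH` (percent); optional columns `u2` (m s^-1) and a
#'   measured `G` (W m^-2), which overrides the f_G closure.
#' @param crop Daily data frame with columns `date` and `lai`, covering
#'   every date in `met`.
#' @param soil Optional hourly data frame with `timestamp` and topsoil
#'   water content as `theta` or as `theta_05`/`theta_10` (their mean is
#'   used); when absent, f_sw falls back to `params$fsw_override` or 1.
#' @param params An [ipt_params()] object.
#' @return Hourly data frame with columns `timestamp`, `Rn`, `Ta`, `VPD`,
#'   `lai`, `tau`, `Rns`, `Rnc`, `G`, `Se`, `f_sw`, `f_t`, `f_s`,
#'   `alpha_e`, `lambda_eq`, `lambda_E`, `lambda_T`, `lambda_ET`
#'   (W m^-2) and `ET` (mm h^-1).
#' @seealso [ipt()] for the model-object interface.
#' @export
simulate_et <- function(met, crop, soil = NULL, params = ipt_params()) {
  stopifnot(inherits(params, "ipt_params"))
  need <- c("timestamp", "Rn", "Ta")
  if (!all(need %in% names(met))) {
    stop("met table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ts <- met$timestamp
  if (!inherits(ts, "POSIXct")) {
    stop("met$timestamp must be POSIXct", call. = FALSE)
  }
  if (is.unsorted(ts, strictly = TRUE)) {
    stop("met timestamps must be strictly increasing", call. = FALSE)
  }
  if (!all(c("date", "lai") %in% names(crop))) {
    stop("crop table needs columns: date, lai", call. = FALSE)
  }

  Ta <- met$Ta
  .check_ta(Ta, ts)
  VPD <- if ("VPD" %in% names(met)) {
    met$VPD
  } else if ("RH" %in% names(met)) {
    vpd_from_t_rh(Ta, met$RH, ts)
  } else {
    stop("met table needs a VPD or RH column", call. = FALSE)
  }

  # broadcast daily LAI to hours
  dates <- as.Date(ts, tz = attr(ts, "tzone") %||% "UTC")
  crop_dates <- as.Date(crop$date)
  di <- match(dates, crop_dates)
  if (anyNA(di)) {
    miss <- unique(dates[is.na(di)])
    stop("crop series is missing date(s): ",
         paste(utils::head(format(miss), 10L), collapse = ", "),
         call. = FALSE)
  }
  lai <- crop$lai[di]

  tau <- transmission_fraction(params$k, lai)
  rad <- partition_radiation(met$Rn, tau)
  G <- if ("G" %in% names(met) && !all(is.na(met$G))) {
    ifelse(is.na(met$G), soil_heat_flux(rad$Rns, params$f_G), met$G)
  } else {
    soil_heat_flux(rad$Rns, params$f_G)
  }

  # soil water stress
  if (!is.null(soil)) {
    si <- .match_series(ts, soil$timestamp, "soil moisture")
    theta <- .soil_theta(soil)[si]
    Se <- effective_saturation(theta, params$theta_s, params$theta_w)
    f_sw <- water_stress_coefficient(Se)
  } else {
    Se <- rep(NA_real_, length(ts))
    f_sw <- rep(params$fsw_override %||% 1, length(ts))
  }
  if (!is.null(params$fsw_override)) {
    f_sw <- rep(params$fsw_override, length(ts))
  }

  f_t <- temperature_constraint(Ta, params$T_opt)
  f_s <- if (is.null(params$senescence_onset)) {
    rep(0, length(ts))
  } else {
    t_sen <- pmax(0, as.numeric(dates - params$senescence_onset))
    senescence_index(t_sen, params$CDC, literal = params$fs_literal)
  }

  delta <- delta_slope(Ta, ts)
  gamma <- psychrometric_constant(params$elevation)
  a_s0 <- alpha_s0(tau, params$tau_c, params$alpha_0)
  a_c0 <- alpha_c0(params$alpha_0, a_s0, tau)

  drive <- delta / (delta + gamma)
  lambda_E <- f_sw * a_s0 * drive * (rad$Rns - G)
  lambda_T <- (1 - f_s) * f_t * a_c0 * drive * rad$Rnc
  lambda_ET <- lambda_E + lambda_T
  lambda_eq <- equilibrium_evaporation(met$Rn, G, delta, gamma)
  alpha_e <- ifelse(lambda_eq != 0, lambda_ET / lambda_eq, NA_real_)

  ET <- lambda_ET * 3600 / params$lambda_v   # mm per hour (rho_w = 1000)
  if (params$clip_negative_et) ET <- pmax(0, ET)

  data.frame(
    timestamp = ts, Rn = met$Rn, Ta = Ta, VPD = VPD, lai = lai, tau = tau,
    Rns = rad$Rns, Rnc = rad$Rnc, G = G, Se = Se, f_sw = f_sw, f_t = f_t,
    f_s = f_s, alpha_e = alpha_e, lambda_eq = lambda_eq,
    lambda_E = lambda_E, lambda_T = lambda_T, lambda_ET = lambda_ET,
    ET = ET
  )
}

#' Aggregate hourly ET to daily totals
#'
#' @param hourly Hourly output of [simulate_et()] (or any data frame with
#'   `timestamp` and `ET`).
#' @param max_missing_frac Fraction of a day's 24 hours that may be
#'   missing before the day is flagged (default 0: any gap flags the day).
#' @return Data frame with `date`, `ET` (mm d^-1), `n_hours` and
#'   `flagged`.
#' @export
aggregate_daily <- function(hourly, max_missing_frac = 0) {
  if (NROW(hourly) == 0L) stop("empty hourly series", call. = FALSE)
  stopifnot(max_missing_frac >= 0, max_missing_frac < 1)
  ts <- hourly$timestamp
  date <- as.Date(ts, tz = attr(ts, "tzone") %||% "UTC")
  et <- tapply(hourly$ET, date, sum)
  n <- tapply(hourly$ET, date, length)
  out <- data.frame(
    date = as.Date(names(et)),
    ET = as.numeric(et),
    n_hours = as.integer(n),
    row.names = NULL
  )
  out$flagged <- (24L - out$n_hours) / 24 > max_missing_frac
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the improved Priestley-Taylor model to a greenhouse season
#'
#' The central constructor: runs [simulate_et()] over the supplied
#' series, aggregates to daily totals, and returns a classed model object
#' with the usual methods (`print`, `summary`, `coef`, `fitted`,
#' `predict`, `residuals`, `simulate`, `plot`).
#'
#' @inheritParams simulate_et
#' @param observed Optional hourly lysimeter ET, a data frame with
#'   `timestamp` and `ET` (mm h^-1); enables residuals and fit metrics.
#' @return An object of class `ipt` with components `hourly`, `daily`,
#'   `params`, `observed` (matched to the hourly grid, or NULL) and
#'   `call`.
#' @examples
#' sc <- greenhouse_scenario("2019",
#'                           start = as.Date("2019-03-12"),
#'                           end = as.Date("2019-03-25"))
#' inp <- generate_scenario(sc, seed = 1)
#' fit <- ipt(inp$met, inp$crop, inp$soil)
#' fit
#' @export
ipt <- function(met, crop, soil = NULL, observed = NULL,
                params = ipt_params()) {
  hourly <- simulate_et(met, crop, soil, params)
  daily <- aggregate_daily(hourly)
  obs <- NULL
  if (!is.null(observed)) {
    if (!all(c("timestamp", "ET") %in% names(observed))) {
      stop("observed table needs columns: timestamp, ET", call. = FALSE)
    }
    oi <- .match_series(hourly$timestamp, observed$timestamp, "observed ET")
    obs <- observed$ET[oi]
  }
  structure(
    list(hourly = hourly, daily = daily, params = params, observed = obs,
         call = match.call()),
    class = "ipt"
  )
}

#' @export
print.ipt <- function(x, ...) {
  h <- x$hourly
  cat("Improved Priestley-Taylor ET model\n")
  cat(sprintf("  %d hourly steps, %s to %s (%d days)\n",
              nrow(h), format(min(h$timestamp)), format(max(h$timestamp)),
              nrow(x$daily)))
  cat(sprintf("  season ET total %.1f mm; daily mean %.2f mm/d (max %.2f)\n",
              sum(x$daily$ET), mean(x$daily$ET), max(x$daily$ET)))
  a <- h$alpha_e[is.finite(h$alpha_e) & h$Rn > 0]
  cat(sprintf("  daytime alpha_e: mean %.2f (sd %.2f)\n",
              mean(a), stats::sd(a)))
  if (!is.null(x$observed)) cat("  observed hourly ET attached\n")
  invisible(x)
}

#' @export
coef.ipt <- function(object, ...) {
  p <- object$params
  c(alpha_0 = p$alpha_0, k = p$k, tau_c = p$tau_c, CDC = p$CDC,
    T_opt = p$T_opt, f_G = p$f_G)
}

#' @export
fitted.ipt <- function(object, ...) {
  stats::setNames(object$hourly$ET, format(object$hourly$timestamp))
}

#' Predict hourly or daily ET from a fitted model
#'
#' @param object An `ipt` object.
#' @param newdata Optional list with components `met`, `crop` and
#'   optionally `soil` to re-run the model on new inputs.
#' @param type `"hourly"` (mm h^-1 series) or `"daily"` (mm d^-1 totals).
#' @param ... Unused.
#' @return A data frame of predictions.
#' @export
predict.ipt <- function(object, newdata = NULL,
                        type = c("hourly", "daily"), ...) {
  type <- match.arg(type)
  hourly <- if (is.null(newdata)) {
    object$hourly
  } else {
    simulate_et(newdata$met, newdata$crop, newdata$soil, object$params)
  }
  if (type == "hourly") {
    hourly[, c("timestamp", "lambda_ET", "lambda_E", "lambda_T",
               "alpha_e", "ET")]
  } else {
    aggregate_daily(hourly)
  }
}

#' @export
residuals.ipt <- function(object, ...) {
  if (is.null(object$observed)) {
    stop("no observed ET attached to this model; refit with `observed =`",
         call. = FALSE)
  }
  object$observed - object$hourly$ET
}

#' Simulate lysimeter-like observations from a fitted model
#'
#' Draws `nsim` replicates of hourly "observed" ET as the model series
#' perturbed by multiplicative Gaussian noise, truncated at zero (see
#' [generate_observed_et()]).
#'
#' @param object An `ipt` object.
#' @param nsim Number of replicates.
#' @param seed Integer seed (required for reproducibility; `NULL` leaves
#'   the RNG state alone).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param ... Unused.
#' @return Data frame with one column per replicate (`sim_1`, ...).
#' @export
simulate.ipt <- function(object, nsim = 1, seed = NULL, noise_cv = 0.05,
                         ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim, generate_observed_et(object$hourly$ET, noise_cv))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
summary.ipt <- function(object, ...) {
  h <- object$hourly
  a <- h$alpha_e[is.finite(h$alpha_e) & h$Rn > 0]
  metrics <- if (!is.null(object$observed)) {
    et_metrics(object$observed, h$ET)
  } else NULL
  structure(
    list(n_hours = nrow(h), n_days = nrow(object$daily),
         range = range(h$timestamp),
         total_et = sum(object$daily$ET),
         daily = summary(object$daily$ET),
         alpha_e_mean = mean(a), alpha_e_sd = stats::sd(a),
         metrics = metrics, params = object$params),
    class = "summary.ipt"
  )
}

#' @export
print.summary.ipt <- function(x, ...) {
  cat("Improved Priestley-Taylor ET model -- summary\n")
  cat(sprintf("  %d hours over %d days (%s to %s)\n", x$n_hours, x$n_days,
              format(x$range[1]), format(x$range[2])))
  cat(sprintf("  season total ET: %.1f mm\n", x$total_et))
  cat("  daily ET (mm/d):\n")
  print(x$daily)
  cat(sprintf("  daytime alpha_e: mean %.3f, sd %.3f (alpha_0 = %.2f)\n",
              x$alpha_e_mean, x$alpha_e_sd, x$params$alpha_0))
  if (!is.null(x$metrics)) {
    cat("  fit to observed hourly ET:\n")
    print(x$metrics)
  }
  invisible(x)
}

#' Diagnostic plots for a fitted model
#'
#' Two base-graphics panels: the daily ET trajectory, and daytime alpha_e
#' over the season with the classical 1.26 reference line.
#'
#' @param x An `ipt` object.
#' @param which Panels to draw (subset of 1:2).
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.ipt <- function(x, which = 1:2, ...) {
  op <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    plot(x$daily$date, x$daily$ET, type = "l", xlab = "date",
         ylab = "ET (mm/d)", main = "Daily evapotranspiration", ...)
  }
  if (2 %in% which) {
    h <- x$hourly
    day <- is.finite(h$alpha_e) & h$Rn > 50
    plot(h$timestamp[day], h$alpha_e[day], pch = ".", xlab = "date",
         ylab = expression(alpha[e]),
         main = "Bulk Priestley-Taylor coefficient (daytime)", ...)
    graphics::abline(h = x$params$alpha_0, lty = 2)
  }
  invisible(x)
}
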