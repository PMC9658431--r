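# Meteorological physics: saturation vapour pressure, VPD, slope of the
# saturation curve and the psychrometric constant.  FAO-56 conventions.

.check_ta <- function(Ta, timestamps = NULL, what = "Ta") {
  bad <- !is.finite(Ta) | Ta <= -40 | Ta >= 60
  if (any(bad)) {
    lab <- if (!is.null(timestamps)) {
      paste(format(timestamps[bad]), collapse = ", ")
    } else {
      paste("index", paste(which(bad), collapse = ", "))
    }
    stop(sprintf("%s outside (-40, 60) degC at: %s", what, lab), call. = FALSE)
  }
  invisible(Ta)
}

#' Saturation vapour pressure of air
#'
#' Tetens-form saturation vapour pressure over water,
#' \eqn{e_s(T_a) = 0.6108 \exp(17.27 T_a / (T_a + 237.3))} (kPa), the
#' convention of the reference-evapotranspiration literature.
#'
#' @param Ta Air temperature, degrees C.  Must lie in (-40, 60).
#' @param timestamps Optional vector of timestamps parallel to `Ta`; used
#'   only to name offending records in error messages.
#' @return Saturation vapour pressure, kPa.
#' @examples
#' saturation_vapor_pressure(26)  # ~3.36 kPa
#' @export
saturation_vapor_pressure <- function(Ta, timestamps = NULL) {
  .check_ta(Ta, timestamps)
  0.6108 * exp(17.27 * Ta / (Ta + 237.3))
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' @param Ta Air temperature, degrees C.
#' @param RH Relative humidity, percent, in \[0, 100\].
#' @inheritParams saturation_vapor_pressure
#' @return VPD, kPa (non-negative; 0 for saturated air).
#' @examples
#' vpd_from_t_rh(20, 50)  # ~1.17 kPa
#' @export
vpd_from_t_rh <- function(Ta, RH, timestamps = NULL) {
  bad <- !is.finite(RH) | RH < 0 | RH > 100
  if (any(bad)) {
    lab <- if (!is.null(timestamps)) {
      paste(format(timestamps[bad]), collapse = ", ")
    } else {
      paste("index", paste(which(bad), collapse = ", "))
    }
    stop(sprintf("RH outside [0, 100] %% at: %s", lab), call. = FALSE)
  }
  pmax(0, saturation_vapor_pressure(Ta, timestamps) * (1 - RH / 100))
}

#' Slope of the saturation vapour pressure curve
#'
#' \eqn{\Delta = 4098 e_s(T_a) / (T_a + 237.3)^2} (kPa K^-1), strictly
#' increasing in `Ta` over the valid range.
#'
#' @inheritParams saturation_vapor_pressure
#' @return Slope Delta, kPa K^-1.
#' @examples
#' delta_slope(26)  # ~0.199 kPa/K
#' @export
delta_slope <- function(Ta, timestamps = NULL) {
  4098 * saturation_vapor_pressure(Ta, timestamps) / (Ta + 237.3)^2
}

#' Psychrometric constant from site elevation
#'
#' \eqn{\gamma = 0.665\times10^{-3} P} with barometric pressure
#' \eqn{P = 101.3 ((293 - 0.0065 z)/293)^{5.26}} kPa.  Computed once per
#' site; pressure is treated as constant over a season.
#'
#' @param elevation Site elevation above sea level, m.
#' @return Psychrometric constant gamma, kPa K^-1.
#' @examples
#' psychrometric_constant(78)  # ~0.0668 kPa/K
#' @export
psychrometric_constant <- function(elevation = 0) {
  stopifnot(is.numeric(elevation), length(elevation) == 1L, is.finite(elevation))
  P <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
  0.665e-3 * P
}
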