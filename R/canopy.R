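# Canopy structure: Beer-Lambert extinction, transmission fraction and
# shape-preserving daily interpolation of weekly LAI observations.

#' Beer-Lambert extinction coefficient from paired PAR readings
#'
#' \eqn{k = -\ln(\mathrm{PAR}_s/\mathrm{PAR}_o)/\mathrm{LAI}} from
#' photosynthetically active radiation measured simultaneously above the
#' canopy (`PARo`) and at the soil surface (`PARs`).
#'
#' @param PARs PAR reaching the ground, umol m^-2 s^-1.
#' @param PARo PAR above the canopy, umol m^-2 s^-1.
#' @param LAI Leaf area index at the time of measurement (> 0).
#' @return Extinction coefficient k (dimensionless, >= 0).
#' @examples
#' extinction_coefficient(200, 1000, 2)  # ~0.805
#' @export
extinction_coefficient <- function(PARs, PARo, LAI) {
  if (any(!is.finite(PARs) | !is.finite(PARo) | PARs <= 0 | PARo <= 0)) {
    stop("PARs and PARo must be finite and positive", call. = FALSE)
  }
  if (any(PARs > PARo)) {
    stop("PARs exceeds PARo at index ",
         paste(which(PARs > PARo), collapse = ", "),
         ": below-canopy PAR cannot exceed above-canopy PAR", call. = FALSE)
  }
  if (any(!is.finite(LAI) | LAI <= 0)) {
    stop("LAI must be positive to infer an extinction coefficient", call. = FALSE)
  }
  -log(PARs / PARo) / LAI
}

#' Season extinction coefficient from repeated weekly PAR calibrations
#'
#' Aggregates repeated (PARs, PARo, LAI) triples into a single season
#' constant as the median of the per-triple coefficients.
#'
#' @param PARs,PARo,LAI Parallel vectors of calibration measurements, or a
#'   data frame with those columns passed as `PARs`.
#' @return The season extinction coefficient (median of per-triple k).
#' @export
fit_extinction_coefficient <- function(PARs, PARo = NULL, LAI = NULL) {
  if (is.data.frame(PARs)) {
    d <- PARs
    need <- c("PARs", "PARo", "LAI")
    if (!all(need %in% names(d))) {
      stop("calibration table needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    PARs <- d$PARs; PARo <- d$PARo; LAI <- d$LAI
  }
  ok <- is.finite(PARs) & is.finite(PARo) & is.finite(LAI) &
    PARs > 0 & PARo > 0 & PARs <= PARo & LAI > 0
  if (!any(ok)) stop("no valid (PARs, PARo, LAI) calibration triples", call. = FALSE)
  stats::median(extinction_coefficient(PARs[ok], PARo[ok], LAI[ok]))
}

#' Daily LAI by shape-preserving piecewise cubic interpolation
#'
#' Interpolates sparse (typically weekly) LAI observations to a daily
#' series with a monotonicity-preserving piecewise cubic Hermite
#' interpolant (PCHIP).  The interpolant passes exactly through the
#' observations and never overshoots the local data range, which keeps a
#' leaf-area curve free of spurious oscillation.  No extrapolation is
#' performed.
#'
#' @param obs_dates Observation dates (`Date`), strictly increasing.
#' @param obs_lai Observed LAI at `obs_dates`.
#' @param target_dates Dates at which daily LAI is wanted; must lie within
#'   the observation span.
#' @return Numeric vector of interpolated LAI at `target_dates`.
#' @export
interpolate_lai <- function(obs_dates, obs_lai, target_dates) {
  obs_dates <- as.Date(obs_dates)
  target_dates <- as.Date(target_dates)
  if (length(obs_dates) < 2L) {
    stop("at least two LAI observations are required", call. = FALSE)
  }
  if (length(obs_dates) != length(obs_lai)) {
    stop("obs_dates and obs_lai differ in length", call. = FALSE)
  }
  x <- as.numeric(obs_dates)
  if (any(diff(x) <= 0)) {
    stop("observation dates must be strictly increasing", call. = FALSE)
  }
  xt <- as.numeric(target_dates)
  out <- xt < x[1L] | xt > x[length(x)]
  if (any(out)) {
    stop("extrapolation requested outside [",
         format(obs_dates[1L]), ", ", format(obs_dates[length(obs_dates)]),
         "]: ", paste(format(target_dates[out]), collapse = ", "),
         call. = FALSE)
  }
  y <- as.numeric(obs_lai)
  if (length(x) == 2L) {
    # two knots: the shape-preserving interpolant degenerates to the chord
    return(stats::approx(x, y, xout = xt)$y)
  }
  pracma::pchip(x, y, xt)
}

#' Fraction of net radiation transmitted to the soil surface
#'
#' Beer-Lambert transmission \eqn{\tau = \exp(-k\,\mathrm{LAI})}: the
#' share of net radiation that penetrates the canopy and reaches the soil.
#'
#' @param k Extinction coefficient (>= 0).
#' @param LAI Leaf area index (>= 0).
#' @return Transmission fraction tau in (0, 1].
#' @examples
#' transmission_fraction(0.7, 2)  # ~0.247
#' @export
transmission_fraction <- function(k, LAI) {
  if (any(!is.finite(k) | k < 0)) stop("k must be >= 0", call. = FALSE)
  if (any(!is.finite(LAI) | LAI < 0)) stop("LAI must be >= 0", call. = FALSE)
  exp(-k * LAI)
}
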