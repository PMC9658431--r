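# Calibration helpers.

#' Recover the soil heat flux fraction from observed latent heat flux
#'
#' Grid least squares: re-runs the model over a grid of `f_G` values and
#' returns the value minimising the sum of squared differences between
#' modelled and observed hourly latent heat flux.
#'
#' @param met,crop,soil Input series as in [simulate_et()].
#' @param lambda_et_obs Observed hourly latent heat flux, W m^-2
#'   (aligned with `met`).
#' @param params Baseline [ipt_params()]; every grid point reuses it with
#'   `f_G` replaced.
#' @param grid Candidate `f_G` values (default `seq(0, 0.9, by = 0.005)`).
#' @return List with `f_G` (the minimiser), `grid` and `sse`.
#' @export
fit_soil_heat_fraction <- function(met, crop, soil = NULL, lambda_et_obs,
                                   params = ipt_params(),
                                   grid = seq(0, 0.9, by = 0.005)) {
  if (length(lambda_et_obs) != nrow(met)) {
    stop("lambda_et_obs must align with the met series", call. = FALSE)
  }
  sse <- vapply(grid, function(fg) {
    p <- params
    p$f_G <- fg
    sim <- simulate_et(met, crop, soil, p)
    sum((sim$lambda_ET - lambda_et_obs)^2)
  }, numeric(1))
  list(f_G = grid[which.min(sse)], grid = grid, sse = sse)
}
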