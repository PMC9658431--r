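# Model parameter container.

#' Parameters of the improved Priestley-Taylor model
#'
#' Collects every tunable constant of the model with the defaults used for
#' drip-irrigated greenhouse tomato.  All of them can be overridden here
#' or from a YAML run configuration (see [read_run_config()]).
#'
#' @param alpha_0 Recommended Priestley-Taylor coefficient (1.26).
#' @param k Canopy extinction coefficient; default 0.7, a typical measured
#'   value for a greenhouse tomato canopy (calibrate with
#'   [fit_extinction_coefficient()] when paired PAR data exist).
#' @param tau_c Critical transmission fraction at maximum canopy cover
#'   (0.55).
#' @param CDC Canopy decline coefficient, d^-1 (0.08 for greenhouse
#'   tomato).
#' @param T_opt Optimum air temperature, degrees C (26 for tomato).
#' @param f_G Fraction of soil net radiation conducted into the soil as
#'   heat flux (0.45); used when no measured G is supplied.
#' @param lambda_v Latent heat of vaporization, J kg^-1 (2.45e6).
#' @param elevation Site elevation, m (78); sets the psychrometric
#'   constant.
#' @param theta_s,theta_w Saturated and wilting-point topsoil water
#'   content, cm^3 cm^-3 (0.32 and 0.09, a silt loam).
#' @param senescence_onset `Date` on which canopy senescence starts
#'   (`NULL` means no senescence: f_s = 0 throughout).
#' @param clip_negative_et Clip negative (condensation) ET depths to zero
#'   (default TRUE; weighing lysimeters report ET >= 0 at night).
#' @param fs_literal Use the literal algebraic reading of the senescence
#'   index (see [senescence_index()]).
#' @param fsw_override Optional fixed value for the soil water stress
#'   coefficient (e.g. 1 to disable soil-moisture limitation); `NULL`
#'   (default) computes f_sw from topsoil moisture at every step.
#' @return An object of class `ipt_params` (a validated list).
#' @examples
#' ipt_params()
#' ipt_params(k = 0.64, T_opt = 25)
#' @export
ipt_params <- function(alpha_0 = 1.26, k = 0.7, tau_c = 0.55, CDC = 0.08,
                       T_opt = 26, f_G = 0.45, lambda_v = 2.45e6,
                       elevation = 78, theta_s = 0.32, theta_w = 0.09,
                       senescence_onset = NULL, clip_negative_et = TRUE,
                       fs_literal = FALSE, fsw_override = NULL) {
  stopifnot(alpha_0 > 1, k > 0, tau_c > 0, tau_c < 1, CDC >= 0, T_opt > 0,
            f_G >= 0, f_G < 1, lambda_v > 0, theta_w < theta_s)
  if (!is.null(senescence_onset)) senescence_onset <- as.Date(senescence_onset)
  if (!is.null(fsw_override)) {
    stopifnot(is.numeric(fsw_override), length(fsw_override) == 1L,
              fsw_override >= 0, fsw_override <= 1)
  }
  structure(
    list(alpha_0 = alpha_0, k = k, tau_c = tau_c, CDC = CDC, T_opt = T_opt,
         f_G = f_G, lambda_v = lambda_v, elevation = elevation,
         theta_s = theta_s, theta_w = theta_w,
         senescence_onset = senescence_onset,
         clip_negative_et = clip_negative_et, fs_literal = fs_literal,
         fsw_override = fsw_override),
    class = "ipt_params"
  )
}

#' @export
print.ipt_params <- function(x, ...) {
  cat("Improved Priestley-Taylor model parameters\n")
  cat(sprintf("  alpha_0 = %.2f   k = %.3f   tau_c = %.2f   CDC = %.3f /d\n",
              x$alpha_0, x$k, x$tau_c, x$CDC))
  cat(sprintf("  T_opt = %.1f C   f_G = %.2f   lambda_v = %.3g J/kg\n",
              x$T_opt, x$f_G, x$lambda_v))
  cat(sprintf("  site: elevation %.0f m (gamma = %.4f kPa/K), theta_s = %.2f, theta_w = %.2f\n",
              x$elevation, psychrometric_constant(x$elevation),
              x$theta_s, x$theta_w))
  cat(sprintf("  senescence onset: %s;  clip negative ET: %s\n",
              if (is.null(x$senescence_onset)) "none"
              else format(x$senescence_onset),
              x$clip_negative_et))
  invisible(x)
}
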