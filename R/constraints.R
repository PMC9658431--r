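# Constraint coefficients that modulate the Priestley-Taylor coefficient:
# soil-water stress (f_sw), air-temperature constraint (f_t), leaf
# senescence (f_s), and the energy-limited soil/canopy coefficients.

#' Effective saturation of the topsoil
#'
#' Linear rescaling of measured topsoil (0-0.1 m) volumetric water content
#' between wilting point and saturation,
#' \eqn{S_e = (\theta - \theta_w)/(\theta_s - \theta_w)}.  `theta` is
#' clipped to \[`theta_w`, `theta_s`\] first, so \eqn{S_e \in [0, 1]}.
#'
#' @param theta Measured volumetric water content, cm^3 cm^-3.
#' @param theta_s Saturated water content (default 0.32, a silt loam).
#' @param theta_w Wilting-point water content (default 0.09).
#' @return Effective saturation Se in \[0, 1\].
#' @export
effective_saturation <- function(theta, theta_s = 0.32, theta_w = 0.09) {
  if (theta_w >= theta_s) {
    stop("theta_w must be smaller than theta_s", call. = FALSE)
  }
  th <- pmin(pmax(theta, theta_w), theta_s)
  (th - theta_w) / (theta_s - theta_w)
}

#' Soil evaporative water stress coefficient
#'
#' Piecewise-linear reduction of soil evaporation with drying topsoil:
#' \eqn{f_{sw} = 1} when \eqn{S_e \ge 0.75}, else \eqn{f_{sw} = S_e}.
#'
#' @param Se Effective saturation in \[0, 1\].
#' @param threshold Saturation above which soil evaporation is unstressed
#'   (default 0.75).
#' @return f_sw in \[0, 1\].
#' @export
water_stress_coefficient <- function(Se, threshold = 0.75) {
  if (any(!is.finite(Se) | Se < 0 | Se > 1)) {
    stop("Se must lie in [0, 1]", call. = FALSE)
  }
  ifelse(Se >= threshold, 1, Se)
}

#' Temperature constraint on canopy transpiration
#'
#' Gaussian penalty on relative deviation of air temperature from the crop
#' optimum: \eqn{f_t = \exp(-(T_a/T_{opt} - 1)^2)}.  Equals 1 only at
#' `Ta == T_opt`.
#'
#' @param Ta Air temperature, degrees C.
#' @param T_opt Optimum growth temperature, degrees C (26 for tomato).
#' @return f_t in (0, 1].
#' @export
temperature_constraint <- function(Ta, T_opt = 26) {
  if (T_opt <= 0) stop("T_opt must be positive", call. = FALSE)
  exp(-(Ta / T_opt - 1)^2)
}

#' Leaf senescence index
#'
#' Canopy-decline family \eqn{f_s = 0.05(\exp((CDC/0.98)\,t) - 1)} clipped
#' to \[0, 1\], where `t` counts days since senescence onset (so
#' \eqn{f_s(0) = 0}) and CDC is the canopy decline coefficient.  The
#' alternative literal form \eqn{0.05\exp(0.98\,CDC\,t - 1)} (which does
#' not vanish at onset) is available via `literal = TRUE` for sensitivity
#' checks.
#'
#' @param t Days since senescence onset (>= 0; 0 before onset).
#' @param CDC Canopy decline coefficient, d^-1 (0.08 for greenhouse
#'   tomato).
#' @param literal Use the alternative algebraic reading (default FALSE).
#' @return f_s in \[0, 1\].
#' @export
senescence_index <- function(t, CDC = 0.08, literal = FALSE) {
  if (any(!is.finite(t) | t < 0)) stop("t must be >= 0", call. = FALSE)
  if (CDC < 0) stop("CDC must be >= 0", call. = FALSE)
  fs <- if (literal) {
    0.05 * exp(CDC * 0.98 * t - 1)
  } else {
    0.05 * (exp((CDC / 0.98) * t) - 1)
  }
  pmin(pmax(fs, 0), 1)
}

#' Energy-limited Priestley-Taylor coefficient for the soil surface
#'
#' Under a dense canopy (\eqn{\tau \le \tau_c}) soil evaporation is
#' energy-limited at \eqn{\alpha_{s0} = 1}; as the canopy opens,
#' \eqn{\alpha_{s0}} rises linearly to the bulk recommendation
#' \eqn{\alpha_0} at \eqn{\tau = 1}:
#' \deqn{\alpha_{s0} = \alpha_0 - (\alpha_0 - 1)(1 - \tau)/(1 - \tau_c).}
#'
#' @param tau Transmission fraction in (0, 1].
#' @param tau_c Critical transmission at maximum canopy cover (default
#'   0.55).
#' @param alpha_0 Recommended Priestley-Taylor coefficient (default 1.26).
#' @return alpha_s0 in \[1, alpha_0\]; continuous at `tau = tau_c`.
#' @export
alpha_s0 <- function(tau, tau_c = 0.55, alpha_0 = 1.26) {
  if (any(!is.finite(tau) | tau <= 0 | tau > 1)) {
    stop("tau must lie in (0, 1]", call. = FALSE)
  }
  if (tau_c <= 0 || tau_c >= 1) stop("tau_c must lie in (0, 1)", call. = FALSE)
  ifelse(tau <= tau_c, 1, alpha_0 - (alpha_0 - 1) * (1 - tau) / (1 - tau_c))
}

#' Energy-limited Priestley-Taylor coefficient for the canopy
#'
#' Defined so that the energy-weighted mean of the soil and canopy
#' coefficients recovers the bulk coefficient exactly:
#' \eqn{\alpha_{c0} = (\alpha_0 - \alpha_{s0}\tau)/(1 - \tau)}, hence
#' \eqn{\alpha_{s0}\tau + \alpha_{c0}(1-\tau) = \alpha_0}.  At
#' \eqn{\tau = 1} (bare soil) the canopy term carries no energy and the
#' limit \eqn{\alpha_0} is returned with a warning.
#'
#' @param alpha_0 Recommended Priestley-Taylor coefficient.
#' @param a_s0 Soil coefficient from [alpha_s0()].
#' @param tau Transmission fraction in (0, 1].
#' @return alpha_c0 (dimensionless).
#' @export
alpha_c0 <- function(alpha_0, a_s0, tau) {
  if (any(!is.finite(tau) | tau <= 0 | tau > 1)) {
    stop("tau must lie in (0, 1]", call. = FALSE)
  }
  bare <- tau == 1
  if (any(bare)) {
    warning("tau = 1 (no canopy): alpha_c0 set to alpha_0; ",
            "the canopy term carries zero energy", call. = FALSE)
  }
  out <- rep_len(alpha_0, length(tau))
  if (any(!bare)) {
    out[!bare] <- (alpha_0 - rep_len(a_s0, length(tau))[!bare] * tau[!bare]) /
      (1 - tau[!bare])
  }
  out
}
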