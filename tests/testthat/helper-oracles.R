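# Independent oracles, implemented from first principles and kept free of
# any package internals, so each dual-route check compares two genuinely
# different code paths.

# Shape-preserving piecewise cubic Hermite interpolation (Fritsch-Carlson
# family with Moler's weighted-harmonic-mean interior slopes and clipped
# one-sided end slopes), written directly from the textbook description.
pchip_oracle <- function(x, y, xq) {
  n <- length(x)
  h <- diff(x)
  delta <- diff(y) / h
  d <- numeric(n)
  if (n == 2L) {
    d[] <- delta
  } else {
    for (k in 2:(n - 1L)) {
      if (delta[k - 1L] * delta[k] <= 0) {
        d[k] <- 0
      } else {
        w1 <- 2 * h[k] + h[k - 1L]
        w2 <- h[k] + 2 * h[k - 1L]
        d[k] <- (w1 + w2) / (w1 / delta[k - 1L] + w2 / delta[k])
      }
    }
    end_slope <- function(h1, h2, d1, d2) {
      d0 <- ((2 * h1 + h2) * d1 - h1 * d2) / (h1 + h2)
      if (sign(d0) != sign(d1)) {
        0
      } else if (sign(d1) != sign(d2) && abs(d0) > abs(3 * d1)) {
        3 * d1
      } else {
        d0
      }
    }
    d[1L] <- end_slope(h[1L], h[2L], delta[1L], delta[2L])
    d[n] <- end_slope(h[n - 1L], h[n - 2L], delta[n - 1L], delta[n - 2L])
  }
  vapply(xq, function(q) {
    i <- findInterval(q, x, rightmost.closed = TRUE)
    i <- min(max(i, 1L), n - 1L)
    s <- q - x[i]
    hi <- h[i]
    del <- delta[i]
    c2 <- (3 * del - 2 * d[i] - d[i + 1L]) / hi
    c3 <- (d[i] - 2 * del + d[i + 1L]) / hi^2
    y[i] + s * (d[i] + s * (c2 + s * c3))
  }, numeric(1))
}

# Bulk coefficient assembled from the component latent-heat fluxes over
# the equilibrium evaporation (radiation partition + soil/canopy
# coefficients + soil-heat-flux closure), with every sub-formula inlined.
alpha_e_component_oracle <- function(f_sw, f_t, f_s, k, LAI, f_G,
                                     delta, gamma, Rn,
                                     alpha_0 = 1.26, tau_c = 0.55) {
  tau <- exp(-k * LAI)
  Rns <- tau * Rn
  Rnc <- (1 - tau) * Rn
  G <- f_G * Rns
  a_s0 <- if (tau <= tau_c) 1 else {
    alpha_0 - (alpha_0 - 1) * (1 - tau) / (1 - tau_c)
  }
  a_c0 <- (alpha_0 - a_s0 * tau) / (1 - tau)
  drive <- delta / (delta + gamma)
  lam_E <- f_sw * a_s0 * drive * (Rns - G)
  lam_T <- (1 - f_s) * f_t * a_c0 * drive * Rnc
  lam_eq <- drive * (Rn - G)
  (lam_E + lam_T) / lam_eq
}
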