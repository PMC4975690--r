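# Independent oracles used across the suite.  These deliberately avoid the
# package's own closed forms.

# Post-selection mean and variance of N(z_bar, s2) weighted by a Gaussian
# fitness function, by adaptive quadrature.
quadrature_selection <- function(z_bar, s2, theta, omega_z2) {
  sd <- sqrt(s2)
  logf <- function(z) -(z - z_bar)^2 / (2 * s2) - (z - theta)^2 / (2 * omega_z2)
  lo <- min(z_bar, theta) - 15 * sd
  hi <- max(z_bar, theta) + 15 * sd
  # rescale by the (numerically located) mode so the integrand is O(1)
  # even when the two Gaussians barely overlap
  C <- stats::optimize(logf, c(lo, hi), maximum = TRUE)$objective
  qd <- function(f) stats::integrate(function(z) f(z) * exp(logf(z) - C),
                                     lo, hi, rel.tol = 1e-12,
                                     subdivisions = 1000L)$value
  Z <- qd(function(z) rep(1, length(z)))
  m1 <- qd(identity) / Z
  m2 <- qd(function(z) z^2) / Z
  list(mean = m1, var = m2 - m1^2)
}

# Central finite-difference gradient of log mean fitness through the
# one-generation maps, times the genetic variances.
fd_trait_response <- function(traits, params, theta, cue, h = 1e-6) {
  lw <- function(st) {
    d <- develop_moments(st, params, cue)
    log(mean_fitness(d$z_bar, d$sigma_z2, st$b_bar, st$m_bar, params, theta))
  }
  g <- numeric(3)
  nm <- c("a_bar", "b_bar", "m_bar")
  for (j in 1:3) {
    up <- traits; up[[nm[j]]] <- up[[nm[j]]] + h
    dn <- traits; dn[[nm[j]]] <- dn[[nm[j]]] - h
    g[j] <- (lw(up) - lw(dn)) / (2 * h)
  }
  stats::setNames(g * c(params$G_aa, params$G_bb, params$G_mm), nm)
}

# Iterate development + selection at frozen trait means until the
# transmitted moments converge; returns the equilibrated trait_state.
frozen_moment_equilibrium <- function(a_bar, b_bar, m_bar, params, cue,
                                      theta, n_iter = 2000) {
  st <- trait_state(a_bar = a_bar, b_bar = b_bar, m_bar = m_bar,
                    z_bar_star = 0, sigma_z2_star = NULL)
  for (i in seq_len(n_iter)) {
    dev <- develop_moments(st, params, cue)
    sel <- gaussian_selection(dev$z_bar, dev$sigma_z2, theta,
                              params$omega_z2)
    k <- params$omega_z2 / (params$omega_z2 + dev$sigma_z2)
    st$z_bar_star <- sel$z_bar_star
    st$sigma_z2_star <- sel$sigma_z2_star
    st$cov_a <- 0.5 * k * dev$kappa_a
    st$cov_b <- 0.5 * k * dev$kappa_b
    st$cov_m <- 0.5 * k * dev$kappa_m
  }
  st
}

fig_step_config <- function() preset("fig2")
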