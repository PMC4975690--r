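#' Population mean phenotype before selection
#'
#' \eqn{\bar z_t = \bar a_t + \bar b_t \epsilon_{t-\tau} + \bar m_t
#' \bar z^*_{t-1}}: the expectation of the individual phenotype model
#' (elevation + linear reaction norm on the developmental cue + linear
#' transgenerational reaction norm on the maternal post-selection
#' phenotype; the residual has mean zero).
#'
#' @param traits a [trait_state()].
#' @param cue developmental cue \eqn{\epsilon_{t-\tau}}.
#' @return Mean phenotype (phenotype units).
#' @export
#' @examples
#' mean_phenotype(trait_state(0.1, 0.5, -0.2, z_bar_star = 2), cue = 1)  # 0.2
mean_phenotype <- function(traits, cue) {
  traits$a_bar + traits$b_bar * cue + traits$m_bar * traits$z_bar_star
}

#' Gaussian survival selection on a Gaussian phenotype distribution
#'
#' Exact post-selection mean and variance of `N(z_bar, sigma_z2)`
#' weighted by `exp(-(z - theta)^2 / (2 omega_z2))`:
#' \deqn{\bar z^* = \bar z - \frac{\sigma_z^2}{\omega_z^2 + \sigma_z^2}
#'   (\bar z - \theta), \qquad
#'   \sigma_z^{2*} = \frac{\sigma_z^2 \omega_z^2}{\omega_z^2 + \sigma_z^2}.}
#'
#' @param z_bar mean phenotype before selection.
#' @param sigma_z2 phenotypic variance before selection (> 0).
#' @param theta selective optimum.
#' @param omega_z2 squared width of the fitness function (> 0).
#' @return List with `z_bar_star` and `sigma_z2_star`.
#' @export
gaussian_selection <- function(z_bar, sigma_z2, theta, omega_z2) {
  if (any(sigma_z2 <= 0))
    param_error("sigma_z2 must be positive")
  check_scalar(omega_z2, "omega_z2", lower = 0, open_lower = TRUE)
  shrink <- sigma_z2 / (omega_z2 + sigma_z2)
  list(z_bar_star = z_bar - shrink * (z_bar - theta),
       sigma_z2_star = sigma_z2 * omega_z2 / (omega_z2 + sigma_z2))
}

#' One-generation development of the phenotypic moments
#'
#' Given the previous generation's transmitted state (maternal mean
#' phenotype, post-selection variance, retained trait-phenotype
#' cross-moments), computes the current generation's mean phenotype,
#' phenotypic variance, the pre-selection covariances between each trait
#' and the phenotype, and the partial derivative of the variance with
#' respect to the mean maternal-effect coefficient (previous-generation
#' state held fixed).
#'
#' The variance follows from the phenotype model under a Gaussian moment
#' closure (third and higher central moments dropped):
#' \deqn{\sigma_z^2 = G_{aa} + G_{bb}\epsilon^2
#'   + G_{mm}(\bar z^{*2} + \sigma_z^{2*}) + \bar m^2 \sigma_z^{2*}
#'   + 2\bar m \bar z^* C_m + C_m^2 + 2\bar m (C_a + \epsilon C_b)
#'   + \sigma_e^2,}
#' where \eqn{C_x = \mathrm{Cov}(x_t, \bar z^*_{t-1})} are the retained
#' cross-moments.  Iterated at fixed trait means in a constant
#' environment this map converges to the closed-form equilibrium of
#' [equilibrium_variance()].
#'
#' @param traits a [trait_state()] carrying the transmitted moments.
#' @param params a [model_params()].
#' @param cue developmental cue \eqn{\epsilon_{t-\tau}}.
#' @return List with `z_bar`, `sigma_z2`, `kappa_a`, `kappa_b`, `kappa_m`
#'   (pre-selection covariances of a, b, m with z) and `dsigma_dm`.
#' @export
develop_moments <- function(traits, params, cue) {
  m <- traits$m_bar
  zs <- traits$z_bar_star
  ss <- traits$sigma_z2_star
  if (is.null(ss)) ss <- params$G_aa + params$G_bb * cue^2 + params$sigma_e2
  Ca <- traits$cov_a; Cb <- traits$cov_b; Cm <- traits$cov_m
  if (abs(m) >= 0.95)
    divergence_error(sprintf(
      "|m_bar| = %g >= 0.95: phenotypic variances tend to go to infinity for these values",
      abs(m)))
  sigma_z2 <- params$G_aa + params$G_bb * cue^2 +
    params$G_mm * (zs^2 + ss) + m^2 * ss +
    2 * m * zs * Cm + Cm^2 + 2 * m * (Ca + cue * Cb) + params$sigma_e2
  list(z_bar = traits$a_bar + traits$b_bar * cue + m * zs,
       sigma_z2 = sigma_z2,
       kappa_a = params$G_aa + m * Ca,
       kappa_b = params$G_bb * cue + m * Cb,
       kappa_m = params$G_mm * zs + m * Cm,
       dsigma_dm = 2 * (m * ss + zs * Cm + Ca + cue * Cb))
}

#' Approximate population mean fitness
#'
#' Weak-selection approximation of mean fitness under the Gaussian
#' fitness function with plasticity and maternal-effect costs:
#' \deqn{\bar W = W_{max}\sqrt{\gamma_z\gamma_b\gamma_m\,
#'   \omega_z^2\omega_b^2\omega_m^2}\,
#'   \exp\!\left(-\tfrac12\left[\gamma_z(\bar z-\theta)^2 +
#'   \gamma_b \bar b^2 + \gamma_m \bar m^2\right]\right),}
#' with \eqn{\gamma_z = 1/(\omega_z^2+\sigma_z^2)},
#' \eqn{\gamma_b = 1/(\omega_b^2+G_{bb})},
#' \eqn{\gamma_m = 1/(\omega_m^2+G_{mm})}.  Higher-order terms in the
#' inverse widths are dropped.
#'
#' @param z_bar mean phenotype.
#' @param sigma_z2 phenotypic variance (> 0).
#' @param b_bar,m_bar mean plasticity and maternal-effect coefficient.
#' @param params a [model_params()].
#' @param theta selective optimum.
#' @return Mean fitness in `(0, W_max]`.
#' @export
mean_fitness <- function(z_bar, sigma_z2, b_bar, m_bar, params, theta) {
  if (any(sigma_z2 <= 0)) param_error("sigma_z2 must be positive")
  gz <- 1 / (params$omega_z2 + sigma_z2)
  gb <- 1 / (params$omega_b2 + params$G_bb)
  gm <- 1 / (params$omega_m2 + params$G_mm)
  params$W_max *
    sqrt(gz * gb * gm * params$omega_z2 * params$omega_b2 * params$omega_m2) *
    exp(-0.5 * (gz * (z_bar - theta)^2 + gb * b_bar^2 + gm * m_bar^2))
}

#' Per-generation response of the mean traits
#'
#' Multivariate breeder's equation with a diagonal G matrix:
#' \eqn{\Delta \bar x = G_{xx}\, \partial \ln \bar W / \partial \bar x}
#' for \eqn{\bar x \in \{\bar a, \bar b, \bar m\}}, where the gradient of
#' log mean fitness is taken through the one-generation maps of
#' [develop_moments()] with the previous generation's state held fixed:
#' \deqn{\frac{\partial \ln \bar W}{\partial \bar x} =
#'   -\gamma_z(\bar z-\theta)\frac{\partial \bar z}{\partial \bar x}
#'   + \tfrac12\gamma_z\left[\gamma_z(\bar z-\theta)^2 - 1\right]
#'     \frac{\partial \sigma_z^2}{\partial \bar x}
#'   - \gamma_b \bar b\,[x = b] - \gamma_m \bar m\,[x = m],}
#' with \eqn{\partial\bar z/\partial\bar a = 1},
#' \eqn{\partial\bar z/\partial\bar b = \epsilon_{t-\tau}},
#' \eqn{\partial\bar z/\partial\bar m = \bar z^*_{t-1}}, and
#' \eqn{\partial\sigma_z^2/\partial\bar m} from [develop_moments()]
#' (the variance does not depend on \eqn{\bar a} or \eqn{\bar b} within a
#' generation).  This gradient agrees with central finite differences of
#' [mean_fitness()] composed with the one-generation maps.
#'
#' @param traits a [trait_state()].
#' @param params a [model_params()].
#' @param theta selective optimum at this generation.
#' @param cue developmental cue at this generation.
#' @return Named numeric vector `c(a_bar = , b_bar = , m_bar = )` of
#'   per-generation changes.
#' @export
trait_update <- function(traits, params, theta, cue) {
  dev <- develop_moments(traits, params, cue)
  gz <- 1 / (params$omega_z2 + dev$sigma_z2)
  gb <- 1 / (params$omega_b2 + params$G_bb)
  gm <- 1 / (params$omega_m2 + params$G_mm)
  d <- dev$z_bar - theta
  grad_a <- -gz * d
  grad_b <- -gz * d * cue - gb * traits$b_bar
  var_coef <- 0.5 * gz * (gz * d^2 - 1)
  grad_m <- -gz * d * traits$z_bar_star + var_coef * dev$dsigma_dm -
    gm * traits$m_bar
  dm <- params$G_mm * grad_m
  c(a_bar = params$G_aa * grad_a,
    b_bar = params$G_bb * grad_b,
    m_bar = sign(dm) * min(abs(dm), .M_STEP_CAP))
}

# Trust-region cap on the per-generation maternal-effect response.  The
# Euler iteration of the breeder's equation is stiff when started far
# from equilibrium (large |m_bar| starts let the phenotype cascade
# inflate z_bar and the selection gradient within a few generations);
# capping |delta m_bar| at 0.1 per generation keeps such transients
# integrable without affecting any regime of interest, where the
# per-generation response is orders of magnitude smaller.
.M_STEP_CAP <- 0.1

#' Initial selection response of a novel maternal effect
#'
#' Closed form for the first-generation change of the mean maternal
#' effect when a small amount of genetic variance \eqn{0 < G_{mm} < 1}
#' is introduced into a stationary population at its optimum
#' (\eqn{\bar m = 0}, \eqn{\bar z = \theta}, plasticity absent):
#' \deqn{\Delta\bar m = -\tfrac12 G_{mm}\,\gamma_z\,k\,
#'   (G_{aa} + G_{mm}\bar z^2), \qquad
#'   k = \frac{\omega_z^2}{\omega_z^2+\sigma_z^2},}
#' where \eqn{\sigma_z^2} is the equilibrium phenotypic variance at
#' \eqn{\bar m = 0}.  The value is negative for all admissible
#' parameters: in stationary environments maternal effects initially
#' evolve toward negative values (phenotypic-variance reduction, i.e.
#' canalization).
#'
#' @param z_bar equilibrium mean phenotype (= the optimum).
#' @param G_aa,G_mm additive genetic variances; `G_mm` in `(0, 1)`.
#' @param omega_z2 inverse selection strength (> 0).
#' @param sigma_e2 residual developmental variance (> 0).
#' @return The (negative) per-generation change of the mean maternal
#'   effect.
#' @export
delta_m_initial <- function(z_bar, G_aa, G_mm, omega_z2, sigma_e2 = 1) {
  check_scalar(G_mm, "G_mm", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(G_aa, "G_aa", lower = 0)
  check_scalar(omega_z2, "omega_z2", lower = 0, open_lower = TRUE)
  params <- model_params(G_aa = G_aa, G_bb = 0, G_mm = G_mm,
                         omega_z2 = omega_z2, sigma_e2 = sigma_e2)
  s2 <- equilibrium_variance(0, z_bar, 0, params)
  gz <- 1 / (omega_z2 + s2)
  k <- omega_z2 * gz
  -0.5 * G_mm * gz * k * (G_aa + G_mm * z_bar^2)
}

#' Equilibrium phenotypic variance in a constant environment
#'
#' Closed-form fixed point of the variance recursion at fixed trait
#' means under weak selection:
#' \deqn{\sigma_z^2 \approx \frac{1}{1 - G_{mm} - \bar m^2}\left[
#'   \frac{2+\bar m}{2-\bar m}\left(G_{aa} + G_{bb}\epsilon^2 +
#'   G_{mm}\bar z^2\right) + \frac{\bar z^2 G_{mm}^2}{(2-\bar m)^2}
#'   + \sigma_e^2\right].}
#' The \eqn{(2-\bar m)} denominators arise from the geometric
#' parent-offspring covariance chain of the maternal cascade; the
#' residual variance is recycled through the cascade and therefore sits
#' inside the leading factor.  Valid while
#' \eqn{1 - G_{mm} - \bar m^2 > 0}; the variance diverges otherwise.
#'
#' @param m_bar mean maternal-effect coefficient, `|m_bar| < 0.95`.
#' @param z_bar mean phenotype at equilibrium.
#' @param eps constant environmental value.
#' @param params a [model_params()].
#' @return Equilibrium phenotypic variance.
#' @export
equilibrium_variance <- function(m_bar, z_bar, eps, params) {
  if (abs(m_bar) >= 0.95)
    divergence_error(sprintf(
      "|m_bar| = %g >= 0.95: phenotypic variances tend to go to infinity for these values",
      abs(m_bar)))
  denom <- 1 - params$G_mm - m_bar^2
  if (denom <= 0)
    divergence_error(sprintf(
      "1 - G_mm - m_bar^2 = %g <= 0: variance cascade diverges", denom))
  num <- (2 + m_bar) / (2 - m_bar) *
    (params$G_aa + params$G_bb * eps^2 + params$G_mm * z_bar^2) +
    z_bar^2 * params$G_mm^2 / (2 - m_bar)^2 + params$sigma_e2
  num / denom
}

# Shared iteration core.  `init` is an L x 3 matrix of (a, b, m) starting
# values; all state updates are elementwise so L chains run in lockstep on
# one environmental realization.  Returns the final state and, when
# record_every > 0 and L == 1, the recorded trajectory.
.iterate_core <- function(params, envdf, init, n_generations,
                          record_every = 1L) {
  Gaa <- params$G_aa; Gbb <- params$G_bb; Gmm <- params$G_mm
  wz2 <- params$omega_z2; se2 <- params$sigma_e2; Wmax <- params$W_max
  gb <- 1 / (params$omega_b2 + Gbb)
  gm <- 1 / (params$omega_m2 + Gmm)
  pref <- Wmax * sqrt(gb * gm * params$omega_b2 * params$omega_m2 * wz2)

  cuev <- envdf$cue; epsv <- envdf$epsilon; thv <- envdf$theta
  L <- nrow(init)
  a <- init[, 1]; b <- init[, 2]; m <- init[, 3]
  if (any(abs(m) >= 0.95))
    divergence_error("initial |m_bar| >= 0.95")
  zstar <- rep(0, L)
  sstar <- rep(Gaa + Gbb * cuev[1]^2 + se2, L)
  Ca <- Cb <- Cm <- rep(0, L)

  do_rec <- record_every > 0L && L == 1L
  if (do_rec) {
    rec_idx <- seq.int(1L, n_generations, by = record_every)
    if (rec_idx[length(rec_idx)] != n_generations)
      rec_idx <- c(rec_idx, n_generations)
    rec <- matrix(NA_real_, length(rec_idx), 11L)
    ri <- 1L
  }

  for (t in seq_len(n_generations)) {
    cue <- cuev[t]; th <- thv[t]
    z <- a + b * cue + m * zstar
    s2 <- Gaa + Gbb * cue * cue + Gmm * (zstar * zstar + sstar) +
      m * m * sstar + 2 * m * zstar * Cm + Cm * Cm +
      2 * m * (Ca + cue * Cb) + se2
    if (any(!is.finite(s2)) || any(s2 > 1e9))
      divergence_error(sprintf(
        "phenotypic variance diverged at generation %d", t - 1L),
        generation = t - 1L)
    gz <- 1 / (wz2 + s2)
    d <- z - th

    if (do_rec && t == rec_idx[ri]) {
      W <- pref * sqrt(gz) *
        exp(-0.5 * (gz * d * d + gb * b * b + gm * m * m))
      zs_now <- z - s2 * gz * d
      rec[ri, ] <- c(t - 1L, a, b, m, z, zs_now, s2, th, epsv[t], cue, W)
      ri <- ri + 1L
    }

    k <- wz2 * gz
    zs <- z - s2 * gz * d
    dsm <- 2 * (m * sstar + zstar * Cm + Ca + cue * Cb)
    var_coef <- 0.5 * gz * (gz * d * d - 1)
    grad_d <- -gz * d
    a_new <- a + Gaa * grad_d
    b_new <- b + Gbb * (grad_d * cue - gb * b)
    dm <- Gmm * (grad_d * zstar + var_coef * dsm - gm * m)
    m_new <- m + pmax(pmin(dm, .M_STEP_CAP), -.M_STEP_CAP)

    kap_a <- Gaa + m * Ca
    kap_b <- Gbb * cue + m * Cb
    kap_m <- Gmm * zstar + m * Cm
    zstar <- zs
    sstar <- k * s2
    Ca <- 0.5 * k * kap_a
    Cb <- 0.5 * k * kap_b
    Cm <- 0.5 * k * kap_m
    a <- a_new; b <- b_new; m <- m_new

    if (any(abs(m) >= 0.95) || any(!is.finite(m)))
      divergence_error(sprintf(
        "|m_bar| reached 0.95 at generation %d: phenotypic variances tend to go to infinity for these values",
        t - 1L), generation = t - 1L)
  }

  final <- cbind(a_bar = a, b_bar = b, m_bar = m, z_bar_star = zstar,
                 sigma_z2_star = sstar, cov_a = Ca, cov_b = Cb, cov_m = Cm)
  traj <- NULL
  if (do_rec) {
    traj <- as.data.frame(rec)
    names(traj) <- c("generation", "a_bar", "b_bar", "m_bar", "z_bar",
                     "z_bar_star", "sigma_z2", "theta", "epsilon", "cue",
                     "mean_fitness")
    class(traj) <- c("matevolve_trajectory", "data.frame")
  }
  list(final = final, trajectory = traj)
}

.as_env_series <- function(env, n_generations, seed) {
  if (is.data.frame(env)) {
    if (nrow(env) < n_generations)
      param_error("environmental series shorter than n_generations")
    return(env)
  }
  environment_series(env, n_generations, seed)
}

#' Iterate the mean-trait recursions
#'
#' Runs the deterministic engine: per generation the environment is
#' sampled, the population develops (mean and variance via the moment
#' closure of [develop_moments()]), the state is recorded, survival
#' selection acts ([gaussian_selection()]), and the mean traits respond
#' via the multivariate breeder's equation ([trait_update()]).
#' Deterministic given the noise seed.
#'
#' @param model a [model_params()].
#' @param env an [env_params()] object, or a precomputed environmental
#'   series from [environment_series()] (useful to share one noise
#'   realization across engines).
#' @param n_generations run length (>= 1).
#' @param init a [trait_state()] with the starting mean traits
#'   (default: all three at `1e-4`).
#' @param seed integer seed for the environmental noise.
#' @param record_every record one row every this many generations
#'   (1 = every generation); the final generation is always recorded.
#' @return A trajectory data frame (class `"matevolve_trajectory"`) with
#'   columns `generation`, `a_bar`, `b_bar`, `m_bar`, `z_bar`,
#'   `z_bar_star`, `sigma_z2`, `theta`, `epsilon`, `cue`,
#'   `mean_fitness`, with the final [trait_state()] attached as
#'   attribute `"final_state"`.
#' @export
#' @examples
#' env <- env_params("constant", epsilon_const = 5, sigma_xi2 = 0)
#' traj <- run_analytic(model_params(), env, n_generations = 200)
#' tail(traj$m_bar, 1)
run_analytic <- function(model, env, n_generations,
                         init = trait_state(), seed = NULL,
                         record_every = 1L) {
  stopifnot(inherits(model, "model_params"))
  check_scalar(n_generations, "n_generations", lower = 1)
  n_generations <- as.integer(n_generations)
  envdf <- .as_env_series(env, n_generations, seed)
  init_mat <- matrix(c(init$a_bar, init$b_bar, init$m_bar), 1L, 3L)
  out <- .iterate_core(model, envdf, init_mat, n_generations,
                       record_every = max(1L, as.integer(record_every)))
  traj <- out$trajectory
  fs <- out$final[1L, ]
  attr(traj, "final_state") <- trait_state(
    a_bar = fs[["a_bar"]], b_bar = fs[["b_bar"]], m_bar = fs[["m_bar"]],
    z_bar_star = fs[["z_bar_star"]], sigma_z2_star = fs[["sigma_z2_star"]],
    cov_a = fs[["cov_a"]], cov_b = fs[["cov_b"]], cov_m = fs[["cov_m"]])
  traj
}

#' Iterate many initial conditions in lockstep
#'
#' Runs the deterministic engine for an ensemble of starting mean-trait
#' values under one shared environmental realization and returns the
#' final states only.  Used to verify that trajectories are insensitive
#' to initial conditions.
#'
#' @param model a [model_params()].
#' @param env an [env_params()] or precomputed series.
#' @param init_matrix numeric matrix with columns (a_bar, b_bar, m_bar),
#'   one row per chain; `|m_bar|` must be below 0.95.
#' @param n_generations run length.
#' @param seed seed for the environmental noise.
#' @return Matrix of final states, one row per chain, columns `a_bar`,
#'   `b_bar`, `m_bar`, `z_bar_star`, `sigma_z2_star`, `cov_a`, `cov_b`,
#'   `cov_m`.
#' @export
iterate_ensemble <- function(model, env, init_matrix, n_generations,
                             seed = NULL) {
  stopifnot(inherits(model, "model_params"))
  init_matrix <- as.matrix(init_matrix)
  if (ncol(init_matrix) != 3L)
    param_error("init_matrix must have 3 columns (a_bar, b_bar, m_bar)")
  n_generations <- as.integer(n_generations)
  envdf <- .as_env_series(env, n_generations, seed)
  .iterate_core(model, envdf, init_matrix, n_generations,
                record_every = 0L)$final
}
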