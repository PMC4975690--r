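#' Map an environmental value to the selective optimum
#'
#' The optimum phenotype is a linear function of the environment,
#' \eqn{\theta = A + B \epsilon}.
#'
#' @param env_value environmental state (env units); vectorized.
#' @param params an [env_params()] object supplying `A` and `B`.
#' @return Optimum in phenotype units.
#' @export
#' @examples
#' optimum(5, env_params("constant", A = 0, B = 2))  # 10
optimum <- function(env_value, params) {
  params$A + params$B * env_value
}

# Smallest q <= 10000 such that tau * q is (numerically) an integer.  The
# noise grid must contain both integer times t and the cue times t - tau,
# so the grid step is 1/q.
.grid_denominator <- function(tau) {
  if (tau == 0) return(1L)
  for (q in 1:10000) {
    if (abs(tau * q - round(tau * q)) < 1e-9) return(as.integer(q))
  }
  param_error(sprintf(
    "tau = %g is not a rational fraction of a generation (denominator <= 10000)",
    tau))
}

#' Autocorrelated Gaussian background noise
#'
#' Generates a stationary AR(1) Gaussian series on a grid of spacing
#' `step_size` generations, parameterized so that the *per-generation*
#' lag-1 autocorrelation is exactly `rho` and the marginal variance is
#' `sigma_xi2` regardless of the grid refinement: the per-step
#' autoregressive coefficient is `rho^step_size` and the innovation
#' variance `sigma_xi2 * (1 - rho^(2 step_size))`.  Values `h`
#' generations apart then have correlation `rho^h`; in particular the
#' developmental cue and the selection-time noise are correlated
#' `rho^tau`.
#'
#' @param n_steps number of grid points (>= 1).
#' @param step_size grid spacing in generations (> 0).
#' @param sigma_xi2 marginal variance (>= 0); 0 returns exact zeros.
#' @param rho per-generation lag-1 autocorrelation in `[0, 1)`.
#' @param seed optional integer seed for reproducibility.
#' @return Numeric vector of length `n_steps`.
#' @export
ar1_noise <- function(n_steps, step_size = 1, sigma_xi2, rho, seed = NULL) {
  check_scalar(n_steps, "n_steps", lower = 1)
  check_scalar(step_size, "step_size", lower = 0, open_lower = TRUE)
  check_scalar(sigma_xi2, "sigma_xi2", lower = 0)
  check_scalar(rho, "rho", lower = 0, upper = 1, open_upper = TRUE)
  n_steps <- as.integer(n_steps)
  if (sigma_xi2 == 0) return(numeric(n_steps))
  if (!is.null(seed)) set.seed(seed)
  phi <- rho^step_size
  x1 <- stats::rnorm(1L, 0, sqrt(sigma_xi2))
  if (n_steps == 1L) return(x1)
  innov <- stats::rnorm(n_steps - 1L, 0, sqrt(sigma_xi2 * (1 - phi^2)))
  rest <- stats::filter(innov, phi, method = "recursive", init = x1)
  c(x1, as.numeric(rest))
}

# Noise process evaluated on the refined grid covering [-1, n_generations].
# Returns a list with $h, $s0 (first grid time) and $values, plus an O(1)
# lookup helper via .xi_at().
.make_noise <- function(params, n_generations, seed = NULL) {
  q <- .grid_denominator(params$tau)
  h <- 1 / q
  s0 <- -1
  n_pts <- (n_generations + 1L) * q + 1L
  values <- ar1_noise(n_pts, step_size = h, sigma_xi2 = params$sigma_xi2,
                      rho = params$rho, seed = seed)
  list(h = h, s0 = s0, values = values)
}

.xi_at <- function(noise, s) {
  i <- round((s - noise$s0) / noise$h) + 1
  if (any(abs((s - noise$s0) / noise$h - (i - 1)) > 1e-6))
    param_error("requested noise at a time not on the simulation grid")
  if (any(i < 1) || any(i > length(noise$values)))
    param_error("requested noise outside the simulated time window")
  noise$values[i]
}

# Deterministic component of epsilon(s) per scenario ("two_patch" has no
# global deterministic series; patches are handled by the IBM).
.eps_det <- function(s, params) {
  switch(params$scenario,
         constant = rep(params$epsilon_const, length(s)),
         step = params$delta * as.numeric(s >= params$t_switch),
         sinusoid = sin(params$f * s),
         stochastic = numeric(length(s)),
         two_patch = param_error(
           "the two-patch scenario has no single environmental series; use run_ibm()"))
}

#' Realize the environmental series for a run
#'
#' Evaluates, for generations `t = 0, ..., n_generations - 1`, the
#' developmental cue \eqn{\epsilon_{t-\tau}}, the environment at selection
#' \eqn{\epsilon_t}, and the optimum \eqn{\theta_t}, including one shared
#' AR(1) background-noise realization on a sub-generation grid (see
#' [ar1_noise()]).
#'
#' @param params an [env_params()] object (any scenario except
#'   `"two_patch"`).
#' @param n_generations number of generations.
#' @param seed optional integer seed for the noise.
#' @return A data frame with columns `t`, `cue`, `epsilon`, `theta`.
#' @export
environment_series <- function(params, n_generations, seed = NULL) {
  check_scalar(n_generations, "n_generations", lower = 1)
  n_generations <- as.integer(n_generations)
  t <- seq.int(0L, n_generations - 1L)
  noise <- .make_noise(params, n_generations, seed)
  cue <- .eps_det(t - params$tau, params) + .xi_at(noise, t - params$tau)
  epsilon <- .eps_det(t, params) + .xi_at(noise, t)
  data.frame(t = t, cue = cue, epsilon = epsilon,
             theta = optimum(epsilon, params))
}

#' Sample the environment at one generation
#'
#' @param t generation index (>= 0).
#' @param params an [env_params()] object.
#' @param noise optional noise process created internally by
#'   [environment_series()]; `NULL` means noiseless (deterministic part
#'   only), which is exact when `sigma_xi2 = 0`.
#' @return A one-row data frame with `t`, `cue`, `env_at_selection`,
#'   `theta`.
#' @export
sample_environment <- function(t, params, noise = NULL) {
  check_scalar(t, "t", lower = 0)
  xi_cue <- if (is.null(noise)) 0 else .xi_at(noise, t - params$tau)
  xi_sel <- if (is.null(noise)) 0 else .xi_at(noise, t)
  env <- .eps_det(t, params) + xi_sel
  data.frame(t = t,
             cue = .eps_det(t - params$tau, params) + xi_cue,
             env_at_selection = env,
             theta = optimum(env, params))
}

#' Lag-1 autocorrelation of the sinusoidal optimum
#'
#' Pearson correlation between \eqn{\sin(f t)} and \eqn{\sin(f (t+1))}
#' over integer generations, the autocorrelation in selective conditions
#' between the maternal and offspring generations when background noise
#' is small.  Analytically this equals \eqn{\cos(f)} for a long window;
#' it is approximately zero at \eqn{f = \pi/2}.
#'
#' @param f angular frequency in `(0, pi]`.
#' @param n_periods minimum number of full periods covered (>= 1).
#' @return Correlation in `[-1, 1]`.
#' @export
theta_lag1_autocorrelation <- function(f, n_periods = 200) {
  check_scalar(f, "f", lower = 0, upper = pi, open_lower = TRUE)
  check_scalar(n_periods, "n_periods", lower = 1)
  n <- max(2000L, ceiling(n_periods * 2 * pi / f))
  t <- seq.int(0L, n - 1L)
  x <- sin(f * t)
  y <- sin(f * (t + 1))
  if (stats::sd(x) < 1e-8 || stats::sd(y) < 1e-8)
    degenerate_error(sprintf(
      "sampled optimum series has (numerically) zero variance at f = %g", f))
  stats::cor(x, y)
}

#' Correlation between the developmental cue and the selective optimum
#'
#' Pearson correlation of the cue series \eqn{\epsilon_{t-\tau}} against
#' the optimum series \eqn{\theta_t} over the same generations; for a
#' noiseless sinusoid this equals \eqn{\cos(f \tau)}.  Indicates how
#' informative within-generation plasticity can be.
#'
#' @param trajectory a data frame with columns `cue` and `theta`
#'   (a trajectory from [run_analytic()] or [environment_series()]).
#' @return Correlation in `[-1, 1]`.
#' @export
lagged_cue_optimum_correlation <- function(trajectory) {
  if (!all(c("cue", "theta") %in% names(trajectory)))
    param_error("trajectory must have 'cue' and 'theta' columns")
  x <- trajectory$cue
  y <- trajectory$theta
  if (length(x) < 3) param_error("trajectory too short for a correlation")
  if (stats::sd(x) < 1e-10 || stats::sd(y) < 1e-10)
    degenerate_error("cue or optimum series has zero variance")
  stats::cor(x, y)
}
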