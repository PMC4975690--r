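#' Model parameters for selection, costs and genetic variances
#'
#' Bundles the constants of the phenotype model and the Gaussian fitness
#' function: additive genetic variances of reaction-norm elevation
#' (`G_aa`), plasticity slope (`G_bb`) and the maternal-effect coefficient
#' (`G_mm`); the inverse selection-strength parameter `omega_z2` (larger
#' means weaker stabilizing selection around the optimum); inverse cost
#' measures `omega_b2` and `omega_m2` for plasticity and maternal effects;
#' the residual developmental variance `sigma_e2`; and the maximal
#' individual fitness `W_max`.
#'
#' Defaults are the step-shift scenario values (weak selection,
#' `omega_z2 = 40`, small costs `omega_b2 = omega_m2 = 100`).
#'
#' @param G_aa,G_bb,G_mm additive genetic variances (>= 0; `G_mm < 1` is
#'   required because the maternal variance cascade diverges otherwise).
#' @param omega_z2 squared width of the Gaussian fitness function
#'   (phenotype units squared, > 0).
#' @param omega_b2,omega_m2 squared inverse cost of plasticity and of the
#'   maternal effect (> 0).
#' @param sigma_e2 residual (environmental) developmental variance (> 0).
#' @param W_max maximal fitness (> 0), conventionally 1.
#' @return An object of class `"model_params"` (a validated list).
#' @export
#' @examples
#' model_params(G_mm = 0.045, omega_z2 = 0.7)
model_params <- function(G_aa = 0.1, G_bb = 0.045, G_mm = 0.005,
                         omega_z2 = 40, omega_b2 = 100, omega_m2 = 100,
                         sigma_e2 = 1, W_max = 1) {
  check_scalar(G_aa, "G_aa", lower = 0)
  check_scalar(G_bb, "G_bb", lower = 0)
  check_scalar(G_mm, "G_mm", lower = 0, upper = 1, open_upper = TRUE)
  check_scalar(omega_z2, "omega_z2", lower = 0, open_lower = TRUE)
  check_scalar(omega_b2, "omega_b2", lower = 0, open_lower = TRUE)
  check_scalar(omega_m2, "omega_m2", lower = 0, open_lower = TRUE)
  check_scalar(sigma_e2, "sigma_e2", lower = 0, open_lower = TRUE)
  check_scalar(W_max, "W_max", lower = 0, open_lower = TRUE)
  structure(list(G_aa = G_aa, G_bb = G_bb, G_mm = G_mm,
                 omega_z2 = omega_z2, omega_b2 = omega_b2,
                 omega_m2 = omega_m2, sigma_e2 = sigma_e2, W_max = W_max),
            class = "model_params")
}

#' Environment process parameters
#'
#' Describes the environmental time series \eqn{\epsilon} and the map to
#' the selective optimum \eqn{\theta_t = A + B \epsilon_t}.  Individuals
#' perceive the environment a fraction `tau` of a generation before
#' selection (the developmental cue is \eqn{\epsilon_{t-\tau}}).
#' Background stochasticity \eqn{\xi} is a stationary Gaussian AR(1)
#' series with marginal variance `sigma_xi2` and per-generation lag-1
#' autocorrelation `rho`, superimposed on the deterministic scenario:
#' `"constant"` (`epsilon_const`), `"step"` (a shift of size `delta` at
#' generation `t_switch`), `"sinusoid"` (`sin(f t)`, amplitude 1),
#' `"stochastic"` (noise only), or `"two_patch"` (two habitats at
#' \eqn{\epsilon = \pm 1} with migration probability `dispersal_d`;
#' individual-based engine only).
#'
#' @param scenario scenario name.
#' @param A baseline optimum (phenotype units).
#' @param B sensitivity of the optimum to the environment.
#' @param tau developmental time-lag, fraction of a generation in `[0, 1)`.
#' @param sigma_xi2 variance of the background noise (>= 0).
#' @param rho per-generation lag-1 autocorrelation of the noise in `[0, 1)`.
#' @param delta step magnitude (step scenario).
#' @param t_switch generation at which the step occurs (the step function
#'   is 1 for all times `s >= t_switch`).
#' @param f angular frequency of the sinusoid in `[0, pi]`, per generation.
#' @param epsilon_const environment value of the constant scenario.
#' @param dispersal_d migration probability in `[0, 1]` (two-patch only).
#' @return An object of class `"env_params"`.
#' @export
#' @examples
#' env_params("step", delta = 10, t_switch = 10)
env_params <- function(scenario = c("constant", "step", "sinusoid",
                                    "stochastic", "two_patch"),
                       A = 0, B = 2, tau = 0.25, sigma_xi2 = 0.01,
                       rho = 0.5, delta = 10, t_switch = 10, f = 0.5,
                       epsilon_const = 0, dispersal_d = 0.5) {
  scenario <- match.arg(scenario)
  check_scalar(A, "A")
  check_scalar(B, "B")
  check_scalar(tau, "tau", lower = 0, upper = 1, open_upper = TRUE)
  check_scalar(sigma_xi2, "sigma_xi2", lower = 0)
  check_scalar(rho, "rho", lower = 0, upper = 1, open_upper = TRUE)
  check_scalar(delta, "delta")
  check_scalar(t_switch, "t_switch", lower = 0)
  check_scalar(f, "f", lower = 0)
  check_scalar(epsilon_const, "epsilon_const")
  check_scalar(dispersal_d, "dispersal_d", lower = 0, upper = 1)
  if (tau > 0) .grid_denominator(tau)  # fails early if tau is irrational-like
  structure(list(scenario = scenario, A = A, B = B, tau = tau,
                 sigma_xi2 = sigma_xi2, rho = rho, delta = delta,
                 t_switch = t_switch, f = f, epsilon_const = epsilon_const,
                 dispersal_d = dispersal_d),
            class = "env_params")
}

#' Individual-based simulation parameters
#'
#' @param N population size (constant across generations, >= 2).
#' @param w_min survival floor in `[0, 1)`; survival probability is
#'   `w_min + (1 - w_min) * W(z, b, m)`, preventing premature extinction
#'   far from the optimum.
#' @param mu_a,mu_b,mu_m per-allele mutation probabilities in `[0, 1]`.
#' @param sigma_mut_a2,sigma_mut_b2,sigma_mut_m2 variances of the Gaussian
#'   increment added to an allelic value upon mutation
#'   (continuum-of-alleles model).
#' @param n_generations default run length.
#' @param n_replicates default number of replicate runs.
#' @return An object of class `"ibm_params"`.
#' @export
ibm_params <- function(N = 5000, w_min = 0.1,
                       mu_a = 0.02, mu_b = 0.02, mu_m = 0.02,
                       sigma_mut_a2 = 0.0025, sigma_mut_b2 = 0.0025,
                       sigma_mut_m2 = 0.0025,
                       n_generations = 50000, n_replicates = 10) {
  check_scalar(N, "N", lower = 2)
  check_scalar(w_min, "w_min", lower = 0, upper = 1, open_upper = TRUE)
  for (nm in c("mu_a", "mu_b", "mu_m"))
    check_scalar(get(nm), nm, lower = 0, upper = 1)
  for (nm in c("sigma_mut_a2", "sigma_mut_b2", "sigma_mut_m2"))
    check_scalar(get(nm), nm, lower = 0)
  check_scalar(n_generations, "n_generations", lower = 1)
  check_scalar(n_replicates, "n_replicates", lower = 1)
  structure(list(N = as.integer(N), w_min = w_min,
                 mu_a = mu_a, mu_b = mu_b, mu_m = mu_m,
                 sigma_mut_a2 = sigma_mut_a2, sigma_mut_b2 = sigma_mut_b2,
                 sigma_mut_m2 = sigma_mut_m2,
                 n_generations = as.integer(n_generations),
                 n_replicates = as.integer(n_replicates)),
            class = "ibm_params")
}

#' Population mean-trait state for the deterministic engine
#'
#' Holds the mean elevation, plasticity slope and maternal-effect
#' coefficient together with the transmitted phenotypic moments: the
#' maternal (post-selection) mean phenotype `z_bar_star`, the
#' post-selection phenotypic variance `sigma_z2_star`, and the retained
#' cross-moments `cov_a`, `cov_b`, `cov_m` — the covariances between the
#' current generation's trait values and the maternal post-selection
#' phenotype that close the variance recursion (Gaussian closure).
#'
#' @param a_bar,b_bar,m_bar mean trait values; `|m_bar|` must stay below
#'   0.95, beyond which the phenotypic variance cascade diverges.
#' @param z_bar_star maternal post-selection mean phenotype (founders: 0).
#' @param sigma_z2_star maternal post-selection phenotypic variance; `NULL`
#'   means "use the no-maternal-effect value `G_aa + G_bb cue^2 + sigma_e2`
#'   at the first developmental step".
#' @param cov_a,cov_b,cov_m retained parent-offspring cross-moments
#'   (founders: 0).
#' @return An object of class `"trait_state"`.
#' @export
trait_state <- function(a_bar = 1e-4, b_bar = 1e-4, m_bar = 1e-4,
                        z_bar_star = 0, sigma_z2_star = NULL,
                        cov_a = 0, cov_b = 0, cov_m = 0) {
  check_scalar(a_bar, "a_bar")
  check_scalar(b_bar, "b_bar")
  check_scalar(m_bar, "m_bar", lower = -0.95, upper = 0.95,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(z_bar_star, "z_bar_star")
  if (!is.null(sigma_z2_star))
    check_scalar(sigma_z2_star, "sigma_z2_star", lower = 0, open_lower = TRUE)
  check_scalar(cov_a, "cov_a")
  check_scalar(cov_b, "cov_b")
  check_scalar(cov_m, "cov_m")
  structure(list(a_bar = a_bar, b_bar = b_bar, m_bar = m_bar,
                 z_bar_star = z_bar_star, sigma_z2_star = sigma_z2_star,
                 cov_a = cov_a, cov_b = cov_b, cov_m = cov_m),
            class = "trait_state")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters:\n")
  cat(sprintf("  G_aa=%g G_bb=%g G_mm=%g\n", x$G_aa, x$G_bb, x$G_mm))
  cat(sprintf("  omega_z2=%g omega_b2=%g omega_m2=%g\n",
              x$omega_z2, x$omega_b2, x$omega_m2))
  cat(sprintf("  sigma_e2=%g W_max=%g\n", x$sigma_e2, x$W_max))
  invisible(x)
}

#' @export
print.env_params <- function(x, ...) {
  cat(sprintf("Environment: %s (A=%g, B=%g, tau=%g, sigma_xi2=%g, rho=%g)\n",
              x$scenario, x$A, x$B, x$tau, x$sigma_xi2, x$rho))
  invisible(x)
}
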