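#' Preset experiment configurations
#'
#' Frozen parameter sets for the study's canonical regimes.  Each preset
#' bundles a [model_params()], an [env_params()] and an [ibm_params()]:
#'
#' * `"fig1"` — constant environment at its optimum (epsilon = 5, so
#'   theta = 10 with B = 2); weak selection; small maternal variance.
#' * `"fig2"` — sudden environmental step of delta = 10 at generation 10
#'   with autocorrelated background noise.
#' * `"fig3"` — slow sinusoidal environment (f = 0.5) with equal
#'   plasticity and maternal variances.
#' * `"fig4"` — sinusoidal frequency sweep under weak selection
#'   (omega_z2 = 40); `"fig4_strong"` — the same under strong selection
#'   (omega_z2 = 0.7).
#' * `"fig5"` — slow sinusoid for the selection-strength x
#'   plasticity-cost grid (individual-based).
#' * `"fig6"` — noiseless sinusoid for developmental time-lag effects.
#' * `"figS5"` — stochastic (AR(1)-only) environment under strong
#'   selection.
#' * `"figS6"` — two-patch spatial environment with migration
#'   (individual-based only; a documented reconstruction).
#'
#' @param name preset name.
#' @return A list with elements `model`, `env`, `ibm` (class
#'   `"run_config"`).
#' @export
#' @examples
#' preset("fig2")$env$delta  # 10
preset <- function(name = c("fig1", "fig2", "fig3", "fig4", "fig4_strong",
                            "fig5", "fig6", "figS5", "figS6")) {
  name <- match.arg(name)
  ibm <- ibm_params()
  cfg <- switch(name,
    fig1 = list(
      model = model_params(G_aa = 0.1, G_bb = 0.045, G_mm = 0.005,
                           omega_z2 = 40, omega_b2 = 100, omega_m2 = 100,
                           sigma_e2 = 1),
      env = env_params("constant", A = 0, B = 2, epsilon_const = 5,
                       tau = 0.25, sigma_xi2 = 0, rho = 0.5)),
    fig2 = list(
      model = model_params(G_aa = 0.1, G_bb = 0.045, G_mm = 0.005,
                           omega_z2 = 40, omega_b2 = 100, omega_m2 = 100,
                           sigma_e2 = 1),
      env = env_params("step", A = 0, B = 2, delta = 10, t_switch = 10,
                       tau = 0.25, sigma_xi2 = 0.01, rho = 0.5)),
    fig3 = list(
      model = model_params(G_aa = 0.1, G_bb = 0.045, G_mm = 0.045,
                           omega_z2 = 40, omega_b2 = 100, omega_m2 = 100,
                           sigma_e2 = 1),
      env = env_params("sinusoid", A = 0, B = 2, f = 0.5, tau = 0.25,
                       sigma_xi2 = 0.01, rho = 0.5)),
    fig4 = list(
      model = model_params(G_aa = 0.1, G_bb = 0.045, G_mm = 0.045,
                           omega_z2 = 40, omega_b2 = 100, omega_m2 = 100,
                           sigma_e2 = 1),
      env = env_params("sinusoid", A = 0, B = 2, f = 0.5, tau = 0.25,
                       sigma_xi2 = 0.01, rho = 0.5)),
    fig4_strong = list(
      model = model_params(G_aa = 0.1, G_bb = 0.045, G_mm = 0.045,
                           omega_z2 = 0.7, omega_b2 = 100, omega_m2 = 100,
                           sigma_e2 = 1),
      env = env_params("sinusoid", A = 0, B = 2, f = 0.5, tau = 0.25,
                       sigma_xi2 = 0.01, rho = 0.5)),
    fig5 = list(
      model = model_params(G_aa = 0.1, G_bb = 0.045, G_mm = 0.045,
                           omega_z2 = 0.7, omega_b2 = 100, omega_m2 = 100,
                           sigma_e2 = 1),
      env = env_params("sinusoid", A = 0, B = 2, f = 0.5, tau = 0.25,
                       sigma_xi2 = 0.01, rho = 0.5)),
    fig6 = list(
      model = model_params(G_aa = 0.1, G_bb = 0.045, G_mm = 0.045,
                           omega_z2 = 40, omega_b2 = 100, omega_m2 = 100,
                           sigma_e2 = 1),
      env = env_params("sinusoid", A = 0, B = 2, f = 0.5, tau = 0.01,
                       sigma_xi2 = 0, rho = 0.5)),
    figS5 = list(
      model = model_params(G_aa = 0.1, G_bb = 0.045, G_mm = 0.045,
                           omega_z2 = 0.7, omega_b2 = 100, omega_m2 = 100,
                           sigma_e2 = 1),
      env = env_params("stochastic", A = 0, B = 2, tau = 0.25,
                       sigma_xi2 = 1, rho = 0.9)),
    figS6 = list(
      model = model_params(G_aa = 0.1, G_bb = 0.045, G_mm = 0.045,
                           omega_z2 = 0.7, omega_b2 = 100, omega_m2 = 100,
                           sigma_e2 = 1),
      env = env_params("two_patch", A = 0, B = 2, tau = 0.25,
                       sigma_xi2 = 0, dispersal_d = 0.5)))
  cfg$ibm <- ibm
  cfg$preset <- name
  cfg$schema_version <- 1L
  class(cfg) <- "run_config"
  cfg
}

# Freeze loci for the deterministic engine: zero genetic variance and a
# zero starting value.
.apply_variant_analytic <- function(model, init, variant) {
  if (variant %in% c("m_only", "none")) {
    model$G_bb <- 0; init$b_bar <- 0
  }
  if (variant %in% c("b_only", "none")) {
    model$G_mm <- 0; init$m_bar <- 0
  }
  list(model = model, init = init)
}

#' Run a preset or configuration through either engine
#'
#' @param config a `"run_config"` from [preset()] or [load_config()].
#' @param engine `"analytic"` or `"ibm"`.
#' @param variant which loci evolve (see [run_ibm()]).
#' @param n_generations run length (default: 50000 analytic, the
#'   configured value for the IBM).
#' @param n_replicates IBM replicates (ignored for the analytic engine).
#' @param seed integer seed.
#' @param record_every trajectory thinning.
#' @return A trajectory data frame (analytic) or an `"ibm_result"`.
#' @export
run_scenario <- function(config, engine = c("analytic", "ibm"),
                         variant = c("both", "m_only", "b_only", "none"),
                         n_generations = NULL, n_replicates = NULL,
                         seed = 1, record_every = 1L) {
  stopifnot(inherits(config, "run_config"))
  engine <- match.arg(engine)
  variant <- match.arg(variant)
  if (engine == "analytic") {
    if (is.null(n_generations)) n_generations <- 50000L
    va <- .apply_variant_analytic(config$model, trait_state(), variant)
    run_analytic(va$model, config$env, n_generations, init = va$init,
                 seed = seed, record_every = record_every)
  } else {
    run_ibm(config$model, config$env, config$ibm, variant = variant,
            n_generations = n_generations, n_replicates = n_replicates,
            seed = seed, record_every = record_every)
  }
}

#' Steady-cycle trait means
#'
#' Evolved values under periodic forcing: the time-average of each trait
#' over the last `n_periods` full forcing periods, after discarding at
#' least the first `discard` fraction of the run as transient.
#'
#' @param trajectory a trajectory data frame.
#' @param period forcing period in generations (`2 * pi / f` for the
#'   sinusoid; use 1 for constant trajectories).
#' @param n_periods number of full periods to average over.
#' @param discard fraction of the run treated as transient.
#' @param traits columns to average.
#' @return Named numeric vector of steady-cycle means.
#' @export
steady_cycle_mean <- function(trajectory, period, n_periods = 10,
                              discard = 0.8,
                              traits = c("a_bar", "b_bar", "m_bar")) {
  n <- nrow(trajectory)
  w <- max(1L, round(n_periods * period))
  if (w > (1 - discard) * n)
    param_error(sprintf(
      "trajectory too short: %d generations cannot hold %d averaging generations after discarding %.0f%%",
      n, w, 100 * discard))
  idx <- seq.int(n - w + 1L, n)
  vapply(traits, function(v) mean(trajectory[[v]][idx]), numeric(1))
}

#' Correlation between the maternal phenotype and the offspring optimum
#'
#' Pearson correlation between the mean post-selection maternal
#' phenotype \eqn{\bar z^*_{t-1}} and the selective optimum
#' \eqn{\theta_t} experienced by her offspring.  The evolved sign of the
#' mean maternal effect tracks this correlation.
#'
#' @param trajectory a trajectory with columns `z_bar_star` and `theta`.
#' @param discard fraction of initial generations dropped as transient.
#' @return Correlation in `[-1, 1]`.
#' @export
maternal_info_correlation <- function(trajectory, discard = 0) {
  if (!all(c("z_bar_star", "theta") %in% names(trajectory)))
    param_error("trajectory must have 'z_bar_star' and 'theta' columns")
  n <- nrow(trajectory)
  start <- max(1L, floor(discard * n) + 1L)
  idx <- seq.int(start, n)
  if (length(idx) < 3) param_error("trajectory too short for a correlation")
  x <- trajectory$z_bar_star[idx[-length(idx)]]
  y <- trajectory$theta[idx[-1]]
  if (stats::sd(x) < 1e-10 || stats::sd(y) < 1e-10)
    degenerate_error("maternal phenotype or optimum series has zero variance")
  stats::cor(x, y)
}

#' Centered moving average
#'
#' Smoother used before sign-change detection on noisy trajectories; the
#' default 25-generation window is wide relative to the background-noise
#' scale yet short relative to the evolutionary transients of interest.
#'
#' @param x numeric vector.
#' @param window odd window length in generations.
#' @return Smoothed vector (ends use shrinking windows).
#' @export
smooth_trajectory <- function(x, window = 25L) {
  n <- length(x)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

.steady_summary <- function(traj, period, n_periods) {
  steady_cycle_mean(traj, period = period, n_periods = n_periods)
}

#' Sweep the frequency of environmental change
#'
#' Runs the chosen engine across a grid of sinusoid frequencies and
#' summarizes the evolved (steady-cycle) trait means per grid point;
#' individual-based points carry the across-replicate standard
#' deviation.  Per-point failures are recorded and the sweep continues.
#' Point `i`, replicate `r` uses seed `seed + 1000 * i + r - 1`, so
#' points are independent and reproducible.
#'
#' @param f_values numeric grid of angular frequencies (non-empty).
#' @param config a `"run_config"`.
#' @param engine `"analytic"` or `"ibm"`.
#' @param variant which loci evolve.
#' @param n_generations run length per point.
#' @param n_replicates IBM replicates per point.
#' @param seed base seed.
#' @param n_periods periods averaged by [steady_cycle_mean()].
#' @return Long-format data frame: `f`, `engine`, `variant`, `trait`,
#'   `value`, `sd` (NA for the deterministic engine), `error`.
#' @export
frequency_sweep <- function(f_values, config, engine = c("analytic", "ibm"),
                            variant = c("both", "m_only", "b_only", "none"),
                            n_generations = 20000L, n_replicates = 3L,
                            seed = 1, n_periods = 10) {
  if (length(f_values) < 1) param_error("f_values must be non-empty")
  engine <- match.arg(engine)
  variant <- match.arg(variant)
  out <- vector("list", length(f_values))
  for (i in seq_along(f_values)) {
    f <- f_values[[i]]
    cfg <- config
    cfg$env$f <- f
    period <- 2 * pi / f
    res <- tryCatch({
      if (engine == "analytic") {
        traj <- run_scenario(cfg, "analytic", variant,
                             n_generations = n_generations,
                             seed = seed + 1000L * i, record_every = 1L)
        sm <- .steady_summary(traj, period, n_periods)
        data.frame(f = f, engine = engine, variant = variant,
                   trait = names(sm), value = unname(sm), sd = NA_real_,
                   error = NA_character_)
      } else {
        per <- lapply(seq_len(n_replicates), function(r) {
          ib <- run_ibm(cfg$model, cfg$env, cfg$ibm, variant = variant,
                        n_generations = n_generations, n_replicates = 1,
                        seed = seed + 1000L * i + r - 1L)
          .steady_summary(ib$replicates[[1]], period, n_periods)
        })
        mat <- do.call(rbind, per)
        data.frame(f = f, engine = engine, variant = variant,
                   trait = colnames(mat), value = colMeans(mat),
                   sd = apply(mat, 2, stats::sd), error = NA_character_)
      }
    }, matevolve_error = function(e) {
      data.frame(f = f, engine = engine, variant = variant,
                 trait = NA_character_, value = NA_real_, sd = NA_real_,
                 error = conditionMessage(e))
    })
    out[[i]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Grid over selection strength and plasticity cost
#'
#' Two-parameter analogue of [frequency_sweep()]: evolved steady-cycle
#' trait means across a grid of `omega_z2` (inverse selection strength)
#' and `omega_b2` (inverse plasticity cost) values at fixed forcing
#' frequency.
#'
#' @param omega_z2_values,omega_b2_values numeric grids (non-empty).
#' @inheritParams frequency_sweep
#' @return Long-format data frame: `omega_z2`, `omega_b2`, `engine`,
#'   `variant`, `trait`, `value`, `sd`, `error`.
#' @export
selection_cost_grid <- function(omega_z2_values, omega_b2_values, config,
                                engine = c("analytic", "ibm"),
                                variant = c("both", "m_only", "b_only", "none"),
                                n_generations = 20000L, n_replicates = 3L,
                                seed = 1, n_periods = 10) {
  if (length(omega_z2_values) < 1 || length(omega_b2_values) < 1)
    param_error("parameter grids must be non-empty")
  engine <- match.arg(engine)
  variant <- match.arg(variant)
  grid <- expand.grid(omega_z2 = omega_z2_values,
                      omega_b2 = omega_b2_values)
  out <- vector("list", nrow(grid))
  period <- 2 * pi / config$env$f
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$model$omega_z2 <- grid$omega_z2[i]
    cfg$model$omega_b2 <- grid$omega_b2[i]
    res <- tryCatch({
      if (engine == "analytic") {
        traj <- run_scenario(cfg, "analytic", variant,
                             n_generations = n_generations,
                             seed = seed + 1000L * i, record_every = 1L)
        sm <- .steady_summary(traj, period, n_periods)
        data.frame(omega_z2 = grid$omega_z2[i], omega_b2 = grid$omega_b2[i],
                   engine = engine, variant = variant, trait = names(sm),
                   value = unname(sm), sd = NA_real_, error = NA_character_)
      } else {
        per <- lapply(seq_len(n_replicates), function(r) {
          ib <- run_ibm(cfg$model, cfg$env, cfg$ibm, variant = variant,
                        n_generations = n_generations, n_replicates = 1,
                        seed = seed + 1000L * i + r - 1L)
          .steady_summary(ib$replicates[[1]], period, n_periods)
        })
        mat <- do.call(rbind, per)
        data.frame(omega_z2 = grid$omega_z2[i], omega_b2 = grid$omega_b2[i],
                   engine = engine, variant = variant, trait = colnames(mat),
                   value = colMeans(mat), sd = apply(mat, 2, stats::sd),
                   error = NA_character_)
      }
    }, matevolve_error = function(e) {
      data.frame(omega_z2 = grid$omega_z2[i], omega_b2 = grid$omega_b2[i],
                 engine = engine, variant = variant, trait = NA_character_,
                 value = NA_real_, sd = NA_real_,
                 error = conditionMessage(e))
    })
    out[[i]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
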