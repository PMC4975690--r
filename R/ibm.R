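#' Develop an individual phenotype
#'
#' Per-individual realization of the phenotype model:
#' `z = a + b * cue + m * maternal_z_star + e`, with
#' `e ~ Normal(0, sigma_e2)`.  Vectorized over individuals.
#'
#' @param a,b,m trait values (sums of the two allelic values per locus).
#' @param cue developmental cue (scalar or per-individual).
#' @param maternal_z_star mother's post-selection phenotype (founders: 0).
#' @param sigma_e2 residual developmental variance (>= 0).
#' @return Phenotype vector.
#' @export
develop_phenotype <- function(a, b, m, cue, maternal_z_star, sigma_e2) {
  n <- length(a)
  e <- if (sigma_e2 > 0) stats::rnorm(n, 0, sqrt(sigma_e2)) else 0
  a + b * cue + m * maternal_z_star + e
}

#' Individual survival probability
#'
#' `w = w_min + (1 - w_min) * W_max * exp(-(z - theta)^2 / (2 omega_z2)
#' - b^2 / (2 omega_b2) - m^2 / (2 omega_m2))`: Gaussian stabilizing
#' selection on the phenotype plus nonlinear survival costs of expressing
#' plasticity and the maternal effect, floored at `w_min` to prevent
#' premature extinction far from the optimum.
#'
#' @param z phenotype.
#' @param b,m expressed plasticity and maternal-effect trait values.
#' @param theta selective optimum (scalar or per-individual).
#' @param params a [model_params()].
#' @param w_min survival floor in `[0, 1)`.
#' @return Survival probabilities in `[w_min, 1]`.
#' @export
survival_probability <- function(z, b, m, theta, params, w_min = 0.1) {
  W <- params$W_max * exp(
    -(z - theta)^2 / (2 * params$omega_z2) -
      b^2 / (2 * params$omega_b2) -
      m^2 / (2 * params$omega_m2))
  w_min + (1 - w_min) * W
}

#' Continuum-of-alleles mutation
#'
#' Each allelic value mutates independently with probability `mu`; a
#' mutation adds a `Normal(0, sigma2)` increment to the old value.
#'
#' @param x vector of allelic values.
#' @param mu per-allele mutation probability.
#' @param sigma2 variance of the mutational increment.
#' @return Mutated vector (same length).
#' @export
mutate_alleles <- function(x, mu, sigma2) {
  if (mu <= 0 || sigma2 <= 0) return(x)
  hit <- which(stats::runif(length(x)) < mu)
  if (length(hit)) x[hit] <- x[hit] + stats::rnorm(length(hit), 0, sqrt(sigma2))
  x
}

#' Random mating among survivors
#'
#' Produces `n_offspring` offspring from a pool of surviving
#' hermaphrodites: each offspring's mother is drawn uniformly (with
#' replacement) from the survivors, the sperm donor uniformly from the
#' survivors excluding the mother (no selfing), and one allele per locus
#' is inherited from each parent with the three loci segregating
#' independently.  Expected clutch size per survivor is
#' `n_offspring / n_survivors`.  The offspring's maternal phenotype is
#' the mother's own (post-selection) phenotype.
#'
#' @param survivors a list with allele vectors `a1, a2, b1, b2, m1, m2`
#'   and phenotype `z` (plus optional `patch`), all of equal length >= 2.
#' @param n_offspring number of offspring to produce.
#' @return A list with the offspring allele vectors, `z_mat` (maternal
#'   phenotypes), `mother` (index of each offspring's mother in the
#'   survivor pool) and, if present in the input, natal `patch`.
#' @export
reproduce <- function(survivors, n_offspring) {
  ns <- length(survivors$z)
  if (ns < 2)
    extinction_error(sprintf(
      "only %d survivor(s): population cannot reproduce", ns))
  mp <- sample.int(ns, n_offspring, replace = TRUE)
  dp <- sample.int(ns - 1L, n_offspring, replace = TRUE)
  dp <- dp + (dp >= mp)  # exclude selfing, keep the draw uniform
  pick <- function(c1, c2, idx) {
    s <- stats::runif(n_offspring) < 0.5
    v <- c1[idx]
    v[s] <- c2[idx][s]
    v
  }
  off <- list(
    a1 = pick(survivors$a1, survivors$a2, mp),
    a2 = pick(survivors$a1, survivors$a2, dp),
    b1 = pick(survivors$b1, survivors$b2, mp),
    b2 = pick(survivors$b1, survivors$b2, dp),
    m1 = pick(survivors$m1, survivors$m2, mp),
    m2 = pick(survivors$m1, survivors$m2, dp),
    z_mat = survivors$z[mp],
    mother = mp)
  if (!is.null(survivors$patch)) off$patch <- survivors$patch[mp]
  off
}

# Founder population: alleles drawn N(init/2, G0/2) per allele so the
# trait mean is init and the standing additive variance is G0.
.founders <- function(N, init, G0, two_patch = FALSE) {
  draw <- function(mu, v) {
    if (v > 0) stats::rnorm(N, mu / 2, sqrt(v / 2)) else rep(mu / 2, N)
  }
  pop <- list(a1 = draw(init[["a"]], G0[["a"]]),
              a2 = draw(init[["a"]], G0[["a"]]),
              b1 = draw(init[["b"]], G0[["b"]]),
              b2 = draw(init[["b"]], G0[["b"]]),
              m1 = draw(init[["m"]], G0[["m"]]),
              m2 = draw(init[["m"]], G0[["m"]]),
              z_mat = rep(0, N))
  if (two_patch) pop$patch <- rep(c(-1, 1), length.out = N)
  pop
}

.apply_variant_ibm <- function(ibm, variant, G0, init) {
  if (variant %in% c("m_only", "none")) {
    ibm$mu_b <- 0; G0[["b"]] <- 0; init[["b"]] <- 0
  }
  if (variant %in% c("b_only", "none")) {
    ibm$mu_m <- 0; G0[["m"]] <- 0; init[["m"]] <- 0
  }
  list(ibm = ibm, G0 = G0, init = init)
}

.run_ibm_once <- function(model, env, ibm, variant, seed, record_every,
                          init, G0, n_generations) {
  set.seed(seed)
  two_patch <- inherits(env, "env_params") && env$scenario == "two_patch"
  if (!two_patch) {
    envdf <- .as_env_series(env, n_generations, seed = seed + 10^6)
    cuev <- envdf$cue; epsv <- envdf$epsilon; thv <- envdf$theta
  } else {
    d <- env$dispersal_d
  }
  N <- ibm$N
  wmin <- ibm$w_min
  pop <- .founders(N, init, G0, two_patch)

  rec_idx <- seq.int(1L, n_generations, by = record_every)
  if (rec_idx[length(rec_idx)] != n_generations)
    rec_idx <- c(rec_idx, n_generations)
  rec <- matrix(NA_real_, length(rec_idx), 14L)
  ri <- 1L

  for (t in seq_len(n_generations)) {
    if (two_patch) {
      mig <- stats::runif(N) < d
      pop$patch[mig] <- -pop$patch[mig]
      cue <- pop$patch
      eps <- pop$patch
      th <- env$A + env$B * eps
    } else {
      cue <- cuev[t]; eps <- epsv[t]; th <- thv[t]
    }
    a <- pop$a1 + pop$a2
    b <- pop$b1 + pop$b2
    m <- pop$m1 + pop$m2
    z <- develop_phenotype(a, b, m, cue, pop$z_mat, model$sigma_e2)
    w <- survival_probability(z, b, m, th, model, wmin)

    if (t == rec_idx[ri]) {
      rec[ri, ] <- c(t - 1L, mean(a), mean(b), mean(m), mean(z),
                     stats::var(z), mean(th), mean(eps), mean(cue),
                     mean(w), NA_real_,
                     stats::var(a), stats::var(b), stats::var(m))
    }

    alive <- which(stats::runif(N) < w)
    if (length(alive) < 2)
      extinction_error(sprintf(
        "population went extinct at generation %d (%d survivor(s))",
        t - 1L, length(alive)), generation = t - 1L)
    surv <- list(a1 = pop$a1[alive], a2 = pop$a2[alive],
                 b1 = pop$b1[alive], b2 = pop$b2[alive],
                 m1 = pop$m1[alive], m2 = pop$m2[alive],
                 z = z[alive])
    if (two_patch) surv$patch <- pop$patch[alive]
    if (t == rec_idx[ri]) {
      rec[ri, 11L] <- mean(surv$z)
      ri <- ri + 1L
    }

    off <- reproduce(surv, N)
    off$a1 <- mutate_alleles(off$a1, ibm$mu_a, ibm$sigma_mut_a2)
    off$a2 <- mutate_alleles(off$a2, ibm$mu_a, ibm$sigma_mut_a2)
    off$b1 <- mutate_alleles(off$b1, ibm$mu_b, ibm$sigma_mut_b2)
    off$b2 <- mutate_alleles(off$b2, ibm$mu_b, ibm$sigma_mut_b2)
    off$m1 <- mutate_alleles(off$m1, ibm$mu_m, ibm$sigma_mut_m2)
    off$m2 <- mutate_alleles(off$m2, ibm$mu_m, ibm$sigma_mut_m2)
    pop <- list(a1 = off$a1, a2 = off$a2, b1 = off$b1, b2 = off$b2,
                m1 = off$m1, m2 = off$m2, z_mat = off$z_mat)
    if (two_patch) pop$patch <- off$patch
  }

  traj <- as.data.frame(rec)
  names(traj) <- c("generation", "a_bar", "b_bar", "m_bar", "z_bar",
                   "sigma_z2", "theta", "epsilon", "cue", "mean_fitness",
                   "z_bar_star", "var_a", "var_b", "var_m")
  class(traj) <- c("matevolve_trajectory", "data.frame")
  traj
}

#' Run the individual-based simulator
#'
#' Forward simulation of `N` diploid hermaphrodites with discrete,
#' non-overlapping generations and three unlinked additive loci coding
#' for elevation, plasticity and the maternal-effect coefficient.  Life
#' cycle per generation: development of the phenotype from the genotype,
#' the developmental cue and the mother's post-selection phenotype
#' ([develop_phenotype()]); stochastic survival
#' ([survival_probability()]); random mating among survivors with
#' Mendelian segregation ([reproduce()]); continuum-of-alleles mutation
#' ([mutate_alleles()]).  Genetic variances are emergent under
#' mutation-selection balance; founders carry standing additive variance
#' `standing_variance` so that early-generation responses are comparable
#' to the deterministic engine.
#'
#' Replicate `r` uses seed `seed + r - 1`, so runs are exactly
#' reproducible and extensible.
#'
#' @param model a [model_params()] (the genetic variances `G_aa`,
#'   `G_bb`, `G_mm` are used only for the founder standing variance; the
#'   simulator's variances are emergent).
#' @param env an [env_params()] (any scenario, including `"two_patch"`)
#'   or a precomputed environmental series.
#' @param ibm an [ibm_params()].
#' @param variant `"both"` (a, b, m all evolve), `"m_only"` (plasticity
#'   locus frozen at 0 with zero mutation), `"b_only"`, or `"none"`.
#' @param n_generations,n_replicates overrides of the [ibm_params()]
#'   defaults.
#' @param seed base integer seed.
#' @param record_every record one row every this many generations.
#' @param init named starting trait means `c(a=, b=, m=)`.
#' @param standing_variance named founder additive variances
#'   `c(a=, b=, m=)`; default = the model's G values.
#' @return List of class `"ibm_result"` with `replicates` (list of
#'   per-replicate trajectory data frames) and `aggregate`
#'   (per-generation across-replicate mean and SD of the trait means).
#' @export
run_ibm <- function(model, env, ibm = ibm_params(),
                    variant = c("both", "m_only", "b_only", "none"),
                    n_generations = NULL, n_replicates = NULL, seed = 1,
                    record_every = 1L,
                    init = c(a = 1e-4, b = 1e-4, m = 1e-4),
                    standing_variance = NULL) {
  stopifnot(inherits(model, "model_params"), inherits(ibm, "ibm_params"))
  variant <- match.arg(variant)
  if (is.null(n_generations)) n_generations <- ibm$n_generations
  if (is.null(n_replicates)) n_replicates <- ibm$n_replicates
  n_generations <- as.integer(n_generations)
  if (is.null(standing_variance))
    standing_variance <- c(a = model$G_aa, b = model$G_bb, m = model$G_mm)
  va <- .apply_variant_ibm(ibm, variant, standing_variance, init)
  record_every <- max(1L, as.integer(record_every))

  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    reps[[r]] <- .run_ibm_once(model, env, va$ibm, variant,
                               seed = seed + r - 1L,
                               record_every = record_every,
                               init = va$init, G0 = va$G0,
                               n_generations = n_generations)
  }
  structure(list(replicates = reps,
                 aggregate = aggregate_replicates(reps),
                 variant = variant, seed = seed),
            class = "ibm_result")
}

#' @export
print.ibm_result <- function(x, ...) {
  n <- nrow(x$replicates[[1]])
  cat(sprintf("Individual-based run: %d replicate(s), %d recorded generations, variant '%s'\n",
              length(x$replicates), n, x$variant))
  invisible(x)
}
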