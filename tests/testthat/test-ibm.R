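test_that("individual development follows the phenotype model", {
  expect_equal(develop_phenotype(1, 0, 0, cue = 7, maternal_z_star = 3,
                                 sigma_e2 = 0), 1)
  expect_equal(develop_phenotype(0, 2, 0.5, cue = 1.5, maternal_z_star = 2,
                                 sigma_e2 = 0), 4)
  # population mean over many founders equals the deterministic mean
  set.seed(5)
  n <- 2e5
  a <- stats::rnorm(n, 0.3, 0.1); b <- stats::rnorm(n, 0.5, 0.1)
  m <- stats::rnorm(n, -0.2, 0.05)
  z <- develop_phenotype(a, b, m, cue = 2, maternal_z_star = 1.5,
                         sigma_e2 = 1)
  expect_equal(mean(z),
               mean_phenotype(trait_state(0.3, 0.5, -0.2, z_bar_star = 1.5),
                              cue = 2),
               tolerance = 0.02)
})

test_that("survival probability is the floored Gaussian fitness", {
  p <- model_params(omega_z2 = 0.7)
  expect_equal(survival_probability(3, 0, 0, theta = 3, p, w_min = 0.1), 1)
  expect_equal(survival_probability(1e4, 0, 0, theta = 0, p, w_min = 0.1),
               0.1)
  expect_equal(survival_probability(2, 0, 0, theta = 0, p, w_min = 0.1),
               0.1 + 0.9 * exp(-4 / 1.4))
  # the floor bounds the empirical survival fraction from below
  set.seed(6)
  n <- 40000
  w <- survival_probability(stats::rnorm(n, 50, 1), 0, 0, 0, p, 0.1)
  frac <- mean(stats::runif(n) < w)
  expect_gte(frac, 0.1 * (1 - 3 / sqrt(n)))
})

test_that("mutation is rare, unbiased and of the stated variance", {
  expect_identical(mutate_alleles(1:10 / 10, mu = 0, sigma2 = 0.0025),
                   1:10 / 10)
  expect_identical(mutate_alleles(1:10 / 10, mu = 0.5, sigma2 = 0),
                   1:10 / 10)
  set.seed(7)
  x0 <- numeric(1e6)
  x1 <- mutate_alleles(x0, mu = 0.02, sigma2 = 0.0025)
  changed <- x1 != 0
  expect_equal(mean(changed), 0.02, tolerance = 0.03)
  expect_equal(stats::var(x1[changed]), 0.0025, tolerance = 0.05)
  expect_equal(mean(x1[changed]), 0, tolerance = 3 * sqrt(0.0025 / sum(changed)))
})

test_that("reproduction is Mendelian, non-selfing and census-preserving", {
  # heterozygote x homozygote: the het parent transmits each allele 1/2
  surv <- list(a1 = c(0, 0), a2 = c(1, 0), b1 = c(0, 0), b2 = c(0, 0),
               m1 = c(0, 0), m2 = c(0, 0), z = c(1, 2))
  set.seed(8)
  n <- 1e5
  off <- reproduce(surv, n)
  expect_length(off$a1, n)
  trait <- off$a1 + off$a2
  expect_true(all(trait %in% c(0, 1)))
  expect_equal(mean(trait), 0.5, tolerance = 3 * 0.5 / sqrt(n))
  # with two survivors and no selfing, parents are always the pair
  expect_true(all(off$mother %in% 1:2))
  # expected clutch size is N / n_surv
  surv5 <- list(a1 = numeric(5), a2 = numeric(5), b1 = numeric(5),
                b2 = numeric(5), m1 = numeric(5), m2 = numeric(5), z = 1:5)
  off5 <- reproduce(surv5, 10000)
  counts <- tabulate(off5$mother, 5)
  expect_true(all(abs(counts - 2000) < 5 * sqrt(2000)))
  # offspring maternal phenotype is the mother's phenotype
  expect_identical(off5$z_mat, surv5$z[off5$mother])
  # fewer than 2 survivors is an extinction signal
  surv1 <- lapply(surv, function(v) v[1])
  expect_error(reproduce(surv1, 10), class = "matevolve_extinction")
})

test_that("monomorphic populations without mutation do not evolve", {
  model <- model_params()
  env <- env_params("constant", epsilon_const = 0, sigma_xi2 = 0)
  ibm <- ibm_params(N = 200, mu_a = 0, mu_b = 0, mu_m = 0,
                    n_generations = 30, n_replicates = 1)
  res <- run_ibm(model, env, ibm, seed = 1,
                 standing_variance = c(a = 0, b = 0, m = 0))
  tr <- res$replicates[[1]]
  expect_equal(tr$a_bar, rep(1e-4, nrow(tr)))
  expect_equal(tr$b_bar, rep(1e-4, nrow(tr)))
  expect_equal(tr$m_bar, rep(1e-4, nrow(tr)))
  expect_equal(tr$var_a, rep(0, nrow(tr)))
})

test_that("founders carry the requested standing additive variance", {
  model <- model_params()
  env <- env_params("constant", epsilon_const = 0, sigma_xi2 = 0)
  ibm <- ibm_params(N = 20000, n_generations = 1, n_replicates = 1)
  res <- run_ibm(model, env, ibm, seed = 2)
  tr <- res$replicates[[1]]
  expect_equal(tr$var_a[1], model$G_aa, tolerance = 0.05)
  expect_equal(tr$var_b[1], model$G_bb, tolerance = 0.05)
  expect_equal(tr$var_m[1], model$G_mm, tolerance = 0.05)
  expect_equal(tr$a_bar[1], 1e-4, tolerance = 0.05)
})

test_that("a population held far from its optimum goes extinct without the floor", {
  model <- model_params(omega_z2 = 0.7)
  env <- env_params("constant", epsilon_const = 500, sigma_xi2 = 0)
  ibm <- ibm_params(N = 50, w_min = 0, n_generations = 200,
                    n_replicates = 1)
  err <- tryCatch(run_ibm(model, env, ibm, seed = 3),
                  matevolve_extinction = function(e) e)
  expect_s3_class(err, "matevolve_extinction")
  expect_true(is.finite(err$generation))
})

test_that("per-locus genic variances stabilize under mutation-selection balance", {
  cfg <- preset("fig1")
  ibm <- ibm_params(N = 500, n_generations = 4000, n_replicates = 1)
  res <- run_ibm(cfg$model, cfg$env, ibm, seed = 4, record_every = 5)
  tr <- res$replicates[[1]]
  n <- nrow(tr)
  w1 <- tr$var_a[(n %/% 2):(3 * n %/% 4)]
  w2 <- tr$var_a[(3 * n %/% 4):n]
  # late-run windows agree within a factor ~2 (drift allowance)
  expect_lt(abs(log(mean(w2) / mean(w1))), log(2.5))
  expect_gt(mean(w2), 0)
})

test_that("frequent dispersal between opposite habitats selects against maternal transmission", {
  cfg <- preset("figS6")
  cfg$env$dispersal_d <- 0.9
  ibm <- ibm_params(N = 1000, n_generations = 3000, n_replicates = 2)
  res <- run_ibm(cfg$model, cfg$env, ibm, variant = "m_only", seed = 7,
                 record_every = 10)
  m_end <- vapply(res$replicates,
                  function(tr) mean(utils::tail(tr$m_bar, 50)), numeric(1))
  expect_true(all(m_end < -0.3))
})
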