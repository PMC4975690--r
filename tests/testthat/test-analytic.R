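test_that("the mean phenotype is the expectation of the phenotype model", {
  expect_equal(mean_phenotype(trait_state(1.5, 0, 0), cue = 99), 1.5)
  expect_equal(mean_phenotype(trait_state(0, 2, 0), cue = 3), 6)
  expect_equal(
    mean_phenotype(trait_state(0.1, 0.5, -0.2, z_bar_star = 2), cue = 1),
    0.2)
})

test_that("Gaussian selection matches quadrature of the Gaussian product", {
  # symmetry: no directional shift at the optimum
  s <- gaussian_selection(3, 2, theta = 3, omega_z2 = 10)
  expect_equal(s$z_bar_star, 3)
  # vanishing selection limit
  s <- gaussian_selection(0, 2, theta = 10, omega_z2 = 1e12)
  expect_equal(s$z_bar_star, 0, tolerance = 1e-9)
  expect_equal(s$sigma_z2_star, 2, tolerance = 1e-9)
  # worked value
  s <- gaussian_selection(0, 2, theta = 10, omega_z2 = 40)
  expect_equal(s$z_bar_star, 10 * 2 / 42)
  expect_equal(s$sigma_z2_star, 80 / 42)
  # quadrature oracle across a parameter sweep
  cases <- expand.grid(z = c(-3, 0, 5), s2 = c(0.5, 2), th = c(0, 10),
                       w2 = c(0.7, 40))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    got <- gaussian_selection(cs$z, cs$s2, cs$th, cs$w2)
    want <- quadrature_selection(cs$z, cs$s2, cs$th, cs$w2)
    expect_equal(got$z_bar_star, want$mean, tolerance = 1e-10)
    expect_equal(got$sigma_z2_star, want$var, tolerance = 1e-10)
  }
  expect_error(gaussian_selection(0, -1, 0, 40), class = "matevolve_param_error")
})

test_that("mean fitness reduces correctly in limiting cases", {
  p <- model_params(G_bb = 0, G_mm = 0, omega_z2 = 1e14, omega_b2 = 1e14,
                    omega_m2 = 1e14)
  expect_equal(mean_fitness(5, 2, 0, 0, p, theta = 5), 1, tolerance = 1e-9)
  p2 <- model_params(G_bb = 0, G_mm = 0, omega_z2 = 40)
  expect_equal(mean_fitness(5, 2, 0, 0, p2, theta = 5), sqrt(40 / 42))
})

test_that("the variance map has the expected fixed points", {
  # no maternal pathway: one-generation fixed point
  p <- model_params(G_aa = 0.1, G_bb = 0.045, G_mm = 0)
  st <- frozen_moment_equilibrium(2, 1, 0, p, cue = 3, theta = 2 + 3)
  dev <- develop_moments(st, p, cue = 3)
  expect_equal(dev$sigma_z2, 0.1 + 0.045 * 9 + 1, tolerance = 1e-9)
  # no genetics at all: sigma_e2 every generation
  p0 <- model_params(G_aa = 0, G_bb = 0, G_mm = 0, sigma_e2 = 1)
  dev0 <- develop_moments(trait_state(1, 0, 0), p0, cue = 0)
  expect_equal(dev0$sigma_z2, 1)
})

test_that("the iterated variance recursion matches the closed-form equilibrium", {
  p <- preset("fig1")$model
  # fixed trait means chosen so the mean settles at the optimum z = 10;
  # the closed form is a weak-selection approximation around the
  # negative-m equilibria a constant environment actually evolves
  for (m in c(-0.4, -0.2, -0.1, 0, 0.1)) {
    st <- frozen_moment_equilibrium(10 * (1 - m), 0, m, p, cue = 5,
                                    theta = 10)
    dev <- develop_moments(st, p, cue = 5)
    expect_equal(dev$sigma_z2, equilibrium_variance(m, 10, 5, p),
                 tolerance = 1e-2)
  }
  # printed trivials
  expect_equal(equilibrium_variance(0, 0, 2,
                                    model_params(G_mm = 0, sigma_e2 = 1)),
               0.1 + 0.045 * 4 + 1)
  expect_equal(equilibrium_variance(0, 7, 0,
                                    model_params(G_aa = 0, G_bb = 0, G_mm = 0)),
               1)
  # divergence guards
  expect_error(equilibrium_variance(0.96, 0, 0, p),
               class = "matevolve_divergence")
  expect_error(equilibrium_variance(0.9, 0, 0, model_params(G_mm = 0.3)),
               class = "matevolve_divergence")
})

test_that("trait responses equal the finite-difference fitness gradient", {
  p <- preset("fig2")$model
  # no genetic variance, no response
  p0 <- model_params(G_aa = 0, G_bb = 0, G_mm = 0)
  expect_equal(unname(trait_update(trait_state(1, 1, 0.3, z_bar_star = 2,
                                               sigma_z2_star = 1.5),
                                   p0, theta = 0, cue = 1)),
               c(0, 0, 0))
  # cost-driven decay of plasticity at the optimum
  st <- trait_state(a_bar = 5, b_bar = 0.8, m_bar = 0, z_bar_star = 0,
                    sigma_z2_star = 1.2)
  dev <- develop_moments(st, p, cue = 0)
  du <- trait_update(st, p, theta = dev$z_bar, cue = 0)
  expect_equal(du[["b_bar"]],
               -p$G_bb * st$b_bar / (p$omega_b2 + p$G_bb))
  expect_lt(du[["b_bar"]], 0)
  # randomized gradient-consistency sweep (excluding near-divergent m_bar)
  set.seed(11)
  for (i in 1:40) {
    st <- trait_state(a_bar = stats::runif(1, -2, 2),
                      b_bar = stats::runif(1, -1, 1),
                      m_bar = stats::runif(1, -0.7, 0.7),
                      z_bar_star = stats::runif(1, -5, 5),
                      sigma_z2_star = stats::runif(1, 0.5, 3),
                      cov_a = stats::runif(1, -0.1, 0.1),
                      cov_b = stats::runif(1, -0.1, 0.1),
                      cov_m = stats::runif(1, -0.1, 0.1))
    theta <- stats::runif(1, -5, 15)
    cue <- stats::runif(1, -3, 3)
    got <- trait_update(st, p, theta, cue)
    want <- fd_trait_response(st, p, theta, cue)
    for (v in names(got))
      expect_lt(abs(got[[v]] - want[[v]]), 1e-4 * abs(want[[v]]) + 1e-8)
  }
})

test_that("a novel maternal effect initially evolves negative", {
  # sign over a randomized valid-parameter sweep
  set.seed(21)
  for (i in 1:200) {
    dm <- delta_m_initial(z_bar = stats::runif(1, -20, 20),
                          G_aa = stats::runif(1, 0.01, 1),
                          G_mm = stats::runif(1, 0.001, 0.5),
                          omega_z2 = stats::runif(1, 1, 100),
                          sigma_e2 = stats::runif(1, 0.1, 2))
    expect_lt(dm, 0)
  }
  # vanishing variance limit
  expect_equal(delta_m_initial(10, 0.1, 1e-9, 40), 0, tolerance = 1e-10)
  expect_error(delta_m_initial(10, 0.1, 1.2, 40),
               class = "matevolve_param_error")
  # closed form agrees with the breeder's-equation response in the same
  # limit (m = 0, z = theta, plasticity absent, equilibrated moments)
  p <- model_params(G_aa = 0.1, G_bb = 0, G_mm = 0.005, omega_z2 = 40)
  st <- frozen_moment_equilibrium(10, 0, 0, p, cue = 0, theta = 10)
  du <- trait_update(st, p, theta = 10, cue = 0)
  expect_equal(delta_m_initial(10, 0.1, 0.005, 40), du[["m_bar"]],
               tolerance = 1e-3)
})

test_that("with plasticity and maternal effects absent the step response is the classical geometric approach", {
  cfg <- preset("fig2")
  cfg$env$sigma_xi2 <- 0
  model <- cfg$model
  model$G_bb <- 0
  model$G_mm <- 0
  traj <- run_analytic(model, cfg$env, 600,
                       init = trait_state(b_bar = 0, m_bar = 0))
  s2 <- model$G_aa + model$sigma_e2
  r <- 1 - model$G_aa / (model$omega_z2 + s2)
  expect_equal(stats::sd(traj$sigma_z2), 0, tolerance = 1e-12)
  d <- traj$z_bar - traj$theta
  i0 <- which(traj$generation == 10)
  for (t in c(50, 100, 300, 550)) {
    expect_equal(d[i0 + t], d[i0] * r^t, tolerance = 1e-8)
  }
})

test_that("the stability guard reports divergence instead of silent NaNs", {
  env <- env_params("constant", epsilon_const = 0, sigma_xi2 = 0)
  expect_error(
    iterate_ensemble(preset("fig1")$model, env,
                     matrix(c(0, 0, 0.96), 1), 100),
    class = "matevolve_divergence")
  # a cascade that genuinely blows up: high maternal variance and a large
  # |m| start with selection and costs too weak to canalize the cascade
  err <- tryCatch(
    run_analytic(model_params(G_mm = 0.6, omega_z2 = 1e12,
                              omega_m2 = 1e12), env, 5000,
                 init = trait_state(m_bar = 0.85)),
    matevolve_divergence = function(e) e)
  expect_s3_class(err, "matevolve_divergence")
  expect_true(is.finite(err$generation))
})

test_that("one engine step equals the composition of the exported operations", {
  cfg <- preset("fig2")
  cfg$env$sigma_xi2 <- 0
  st <- trait_state()
  traj <- run_analytic(cfg$model, cfg$env, 2)
  es <- environment_series(cfg$env, 2)
  dev <- develop_moments(st, cfg$model, es$cue[1])
  expect_equal(traj$z_bar[1], dev$z_bar)
  expect_equal(traj$sigma_z2[1], dev$sigma_z2)
  du <- trait_update(st, cfg$model, es$theta[1], es$cue[1])
  expect_equal(traj$a_bar[2], st$a_bar + du[["a_bar"]])
  expect_equal(traj$b_bar[2], st$b_bar + du[["b_bar"]])
  expect_equal(traj$m_bar[2], st$m_bar + du[["m_bar"]])
  sel <- gaussian_selection(dev$z_bar, dev$sigma_z2, es$theta[1],
                            cfg$model$omega_z2)
  expect_equal(traj$z_bar_star[1], sel$z_bar_star)
})
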