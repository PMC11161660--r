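test_that("Gibbs full conditionals match brute-force grid integration", {
  spec <- model_spec(variant = 2)
  hyper <- hyperpriors(spec, mu0 = 0, kappa0 = 10, a0 = 2, b0 = 1)
  phi_mat <- cbind(baseline = c(-1, 0, 1), diffusion = c(-1, 0, 1))
  tau <- c(baseline = 1, diffusion = 1)

  # empirical mean/var of the mu draw with tau held fixed
  draws <- withr::with_seed(21, {
    vapply(1:20000, function(i) {
      gibbs_update_population(phi_mat, spec, hyper, tau)$mu[["baseline"]]
    }, numeric(1))
  })
  # brute-force posterior over mu: N(0,10^2) prior x product of N(phi_i; mu, 1)
  g <- seq(-5, 5, length.out = 4001)
  lp <- dnorm(g, 0, 10, log = TRUE) +
    colSums(vapply(g, function(m) dnorm(c(-1, 0, 1), m, 1, log = TRUE),
                   numeric(3)))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  m_grid <- sum(w * g)
  v_grid <- sum(w * (g - m_grid)^2)
  expect_lt(abs(mean(draws) - m_grid), 4 * sqrt(v_grid / length(draws)) + 1e-3)
  expect_lt(abs(var(draws) - v_grid), 1e-2 * v_grid + 1e-3)
})

test_that("a collapsing hyperprior pins the population mean and tau stays positive", {
  spec <- model_spec(variant = 2)
  tight <- hyperpriors(spec, mu0 = c(baseline = 2.5, diffusion = -1),
                       kappa0 = 1e-8)
  phi_mat <- cbind(baseline = rnorm(5, 0, 3), diffusion = rnorm(5))
  withr::with_seed(22, {
    taus <- numeric(2000)
    for (i in 1:2000) {
      u <- gibbs_update_population(phi_mat, spec, tight,
                                   c(baseline = 1, diffusion = 1))
      if (i <= 5) {
        expect_equal(u$mu[["baseline"]], 2.5, tolerance = 1e-4)
        expect_equal(u$mu[["diffusion"]], -1, tolerance = 1e-4)
      }
      taus[i] <- u$tau[["baseline"]]
    }
    expect_true(all(taus > 0))
  })
})

test_that("an identical proposal (zero scales, rho = 1) is always accepted", {
  spec <- model_spec(variant = 2)
  cfg <- obs_config()
  ser <- make_series(c(baseline = -3, diffusion = -1), c(0, 10, 30), seed = 23)
  aux <- withr::with_seed(24, make_aux(50, 3))
  phi <- c(baseline = -3, diffusion = -1)
  res <- particle_filter_loglik(ser$times, ser$scores, phi, spec, cfg, aux)
  state <- list(phi = phi, aux = aux, loglik = res$loglik,
                increments = res$increments)
  pop <- list(mu = c(baseline = -3, diffusion = -1),
              tau = c(baseline = 1, diffusion = 1))
  withr::with_seed(25, {
    for (i in 1:20) {
      state <- cpm_mh_individual_step(state, pop, spec, cfg, ser$times,
                                      ser$scores, scales = 0, rho = 1)
      expect_true(state$accepted)
      expect_identical(state$loglik, res$loglik)
    }
  })
})

test_that("with an exact likelihood the MH kernel recovers the grid posterior", {
  # one simulated individual; baseline treated as known so the diffusion
  # posterior is one-dimensional and can be integrated on a grid
  cfg <- obs_config()
  phi_true <- c(baseline = inverse_link(8, cfg), diffusion = -1.0)
  ser <- make_series(phi_true, times = c(0, 4, 9, 20, 33, 47), seed = 26)
  prior_mean <- -1; prior_sd <- 1

  ref <- oracle_grid_posterior_phi2(ser$times, ser$scores,
                                    phi_true[["baseline"]], cfg,
                                    prior_mean, prior_sd)

  spec_d <- model_spec("wiener", random = "diffusion")
  exact_ll <- function(phi, aux) {
    list(loglik = oracle_grid_loglik(ser$times, ser$scores, phi, cfg,
                                     n_grid = 201),
         increments = NULL)
  }
  pop <- list(mu = c(diffusion = prior_mean), tau = c(diffusion = prior_sd))
  n_iter <- 4000
  draws <- withr::with_seed(27, {
    phi <- phi_true
    phi["diffusion"] <- prior_mean
    state <- list(phi = phi, aux = make_aux(1, length(ser$times)),
                  loglik = exact_ll(phi, NULL)$loglik, increments = NULL)
    out <- numeric(n_iter)
    for (i in seq_len(n_iter)) {
      state <- cpm_mh_individual_step(state, pop, spec_d, cfg, ser$times,
                                      ser$scores, scales = 0.5, rho = 1,
                                      loglik_fun = exact_ll)
      out[i] <- state$phi[["diffusion"]]
    }
    out
  })
  expect_lt(abs(mean(draws[-(1:500)]) - ref$mean), 0.05)
})

test_that("the full sampler is reproducible and rejects under-observed individuals", {
  co <- generate_cohort(cohort_config(n_individuals = 5, zero_fraction = 0,
                                      n_obs_fixed = 5, gap_median_days = 10,
                                      gap_sdlog = 0.5, seed = 28))
  cfg <- sampler_config(iterations = 60, burnin = 30, n_particles = 30,
                        seed = 4)
  f1 <- fit_trajectories(co$data, config = cfg)
  f2 <- fit_trajectories(co$data, config = cfg)
  expect_identical(f1$phi_draws, f2$phi_draws)
  expect_identical(f1$pop_draws, f2$pop_draws)
  expect_identical(f1$increments, f2$increments)
  expect_equal(dim(f1$phi_draws), c(30, 5, 2))

  bad <- rbind(co$data,
               tibble::tibble(individual_id = "lonely", time_days = 0,
                              sidas_total = 3L))
  expect_error(fit_trajectories(bad, config = cfg), "lonely")
})

test_that("fixed-effect variants share one diffusion value across individuals", {
  co <- generate_cohort(cohort_config(n_individuals = 4, zero_fraction = 0,
                                      n_obs_fixed = 6, gap_median_days = 7,
                                      gap_sdlog = 0.5, seed = 29))
  fit <- fit_trajectories(co$data, spec = model_spec(variant = 1),
                          config = sampler_config(iterations = 80, burnin = 40,
                                                  n_particles = 30, seed = 5))
  # every individual's diffusion equals the shared fixed draw, draw by draw
  for (k in c(1, 20, 40)) {
    expect_equal(unname(fit$phi_draws[k, , "diffusion"]),
                 rep(unname(fit$pop_draws[k, "fixed_diffusion"]), 4))
  }
  expect_true("mu_baseline" %in% colnames(fit$pop_draws))
  expect_false("mu_diffusion" %in% colnames(fit$pop_draws))
})

test_that("higher auxiliary correlation raises the acceptance rate", {
  cfg <- obs_config()
  spec <- model_spec(variant = 2)
  phi <- c(baseline = -3, diffusion = -0.9)
  ser <- make_series(phi, times = cumsum(c(0, rep(5, 11))), seed = 30)
  pop <- list(mu = phi, tau = c(baseline = 1, diffusion = 1))
  run_chain <- function(rho, seed) {
    withr::with_seed(seed, {
      aux <- make_aux(20, length(ser$times))
      res <- particle_filter_loglik(ser$times, ser$scores, phi, spec, cfg, aux)
      state <- list(phi = phi, aux = aux, loglik = res$loglik,
                    increments = res$increments)
      acc <- 0
      for (i in 1:150) {
        state <- cpm_mh_individual_step(state, pop, spec, cfg, ser$times,
                                        ser$scores, scales = 0.15, rho = rho)
        acc <- acc + state$accepted
      }
      acc / 150
    })
  }
  acc_hi <- mean(vapply(1:10, function(s) run_chain(0.99, 100 + s), numeric(1)))
  acc_lo <- mean(vapply(1:10, function(s) run_chain(0, 200 + s), numeric(1)))
  expect_gt(acc_hi, acc_lo)
})
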