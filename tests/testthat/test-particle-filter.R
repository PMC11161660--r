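spec_w <- model_spec(variant = 2)

test_that("a single observation at t = 0 gives the exact likelihood", {
  cfg <- obs_config()
  phi <- c(baseline = -2, diffusion = -1)
  for (np in c(1, 7, 100)) {
    aux <- withr::with_seed(1, make_aux(np, 1))
    res <- particle_filter_loglik(0, 4L, phi, spec_w, cfg, aux)
    expect_equal(res$loglik, observation_loglik(4L, -2, cfg), tolerance = 1e-12)
    expect_equal(res$increments, res$loglik)
  }
})

test_that("the filter is a deterministic function of its auxiliaries", {
  cfg <- obs_config()
  phi <- c(baseline = -3, diffusion = -1)
  ser <- make_series(phi, times = c(0, 5, 12, 30, 31), seed = 2)
  aux <- withr::with_seed(3, make_aux(60, 5))
  r1 <- particle_filter_loglik(ser$times, ser$scores, phi, spec_w, cfg, aux)
  r2 <- particle_filter_loglik(ser$times, ser$scores, phi, spec_w, cfg, aux)
  expect_identical(r1, r2)
  expect_equal(sum(r1$increments), r1$loglik, tolerance = 1e-10)
  expect_error(particle_filter_loglik(numeric(0), integer(0), phi, spec_w,
                                      cfg, aux), "no observations")
})

test_that("Crank-Nicolson refresh preserves the marginal and hits the edges", {
  aux <- withr::with_seed(4, make_aux(100, 10))
  fresh <- withr::with_seed(5, make_aux(100, 10))
  expect_identical(refresh_aux(aux, 1, fresh)$particle_normals,
                   aux$particle_normals)
  expect_identical(refresh_aux(aux, 0, fresh)$particle_normals,
                   fresh$particle_normals)
  expect_error(refresh_aux(aux, 1.2, fresh), "rho")

  big <- withr::with_seed(6, make_aux(400, 300))
  bf <- withr::with_seed(7, make_aux(400, 300))
  mixed <- refresh_aux(big, 0.8, bf)
  r <- cor(as.vector(big$particle_normals), as.vector(mixed$particle_normals))
  expect_lt(abs(r - 0.8), 0.01)
  expect_lt(abs(sd(as.vector(mixed$particle_normals)) - 1), 0.01)
})

test_that("2-observation likelihood estimates centre on Gauss-Hermite quadrature", {
  cfg <- obs_config()
  phi <- c(baseline = inverse_link(6, cfg), diffusion = -0.9)
  times <- c(0, 14)
  scores <- c(6L, 11L)
  exact <- oracle_gh_loglik_2obs(times, scores, phi, cfg)

  ests <- withr::with_seed(8, {
    vapply(1:200, function(i) {
      particle_filter_loglik(times, scores, phi, spec_w, cfg,
                             make_aux(400, 2))$loglik
    }, numeric(1))
  })
  # unbiasedness on the likelihood scale
  lik <- exp(ests - exact)
  expect_lt(abs(mean(lik) - 1), 3 * sd(lik) / sqrt(length(lik)))
  # negligible jensen bias at 400 particles: log-scale agreement too
  expect_lt(abs(mean(ests) - exact), 3 * sd(ests) / sqrt(length(ests)) + 0.01)
})

test_that("filter agrees with the Kalman filter in linear-Gaussian mode", {
  cfg <- obs_config(sigma_y = 1, family = "gaussian")
  phi <- c(baseline = 0, diffusion = -0.5)
  times <- cumsum(c(0, rexp(9, 1 / 10)))
  ys <- withr::with_seed(9, {
    x <- simulate_latent_path(phi, spec_w, times, rnorm(9))
    round(x + rnorm(10, 0, 1), 3)
  })
  exact <- oracle_kalman_loglik(times, ys, phi, 1)
  ests <- withr::with_seed(10, {
    vapply(1:200, function(i) {
      particle_filter_loglik(times, ys, phi, spec_w, cfg,
                             make_aux(500, 10))$loglik
    }, numeric(1))
  })
  lik <- exp(ests - exact)
  expect_lt(abs(mean(lik) - 1), 3 * sd(lik) / sqrt(length(lik)))
  expect_lt(abs(mean(ests) - exact), 3 * sd(ests) / sqrt(length(ests)) + 0.05)
})

test_that("sorting before resampling leaves the estimator distribution unchanged", {
  cfg <- obs_config()
  phi <- c(baseline = -3, diffusion = -0.8)
  ser <- make_series(phi, times = c(0, 7, 20, 45), seed = 11)
  res <- withr::with_seed(12, {
    sapply(1:200, function(i) {
      aux <- make_aux(100, 4)
      c(sorted = particle_filter_loglik(ser$times, ser$scores, phi, spec_w,
                                        cfg, aux)$loglik,
        plain = pf_loglik_nosort(ser$times, ser$scores, phi, spec_w, cfg, aux))
    })
  })
  d <- res["sorted", ] - res["plain", ]
  se <- sqrt(var(res["sorted", ]) + var(res["plain", ])) / sqrt(ncol(res))
  expect_lt(abs(mean(d)), 3 * se)
})

test_that("dense-grid likelihood validates the filter on a longer series", {
  cfg <- obs_config()
  phi <- c(baseline = -3.5, diffusion = -1.1)
  ser <- make_series(phi, times = c(0, 3, 10, 24, 40, 70), seed = 13)
  exact <- oracle_grid_loglik(ser$times, ser$scores, phi, cfg)
  ests <- withr::with_seed(14, {
    vapply(1:100, function(i) {
      particle_filter_loglik(ser$times, ser$scores, phi, spec_w, cfg,
                             make_aux(400, 6))$loglik
    }, numeric(1))
  })
  lik <- exp(ests - exact)
  expect_lt(abs(mean(lik) - 1), 3 * sd(lik) / sqrt(length(lik)))
})
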