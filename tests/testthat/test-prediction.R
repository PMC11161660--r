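test_that("equal-tailed intervals are the stated empirical quantiles", {
  expect_equal(unname(eti(c(3, 1, 9, 5), 1.0)), c(1, 9))
  expect_equal(unname(eti(rep(4.2, 10), 0.95)), c(4.2, 4.2))
  z <- withr::with_seed(41, rnorm(1e6))
  q <- eti(z, 0.95)
  expect_lt(abs(q[["lower"]] + 1.96), 0.015)
  expect_lt(abs(q[["upper"]] - 1.96), 0.015)
  expect_error(eti(numeric(0)), "draws")
})

test_that("highest-density intervals shorten onto the density peak", {
  z <- withr::with_seed(42, rnorm(1e6))
  h <- hdi(z, 0.95)
  q <- eti(z, 0.95)
  w_h <- h[["upper"]] - h[["lower"]]
  w_q <- q[["upper"]] - q[["lower"]]
  expect_lt(abs(w_h - w_q) / w_q, 0.02)

  e <- withr::with_seed(43, rexp(1e5))
  h <- hdi(e, 0.8)
  expect_lt(h[["lower"]], quantile(e, 0.005))

  expect_equal(unname(hdi(c(5, 5, 5), 0.8)), c(5, 5))
  expect_error(hdi(3, 0.8), "two draws")
})

test_that("IHIP counts paths strictly exceeding the threshold", {
  zeros <- matrix(0L, 5, 10)
  expect_equal(compute_ihip(zeros), 0)
  expect_equal(compute_ihip(matrix(30L, 5, 10)), 1)
  paths <- rbind(rep(3L, 6), rep(10L, 6), c(2L, 21L, 2L, 2L, 2L, 2L),
                 rep(0L, 6))
  expect_equal(compute_ihip(paths), 0.25)
  # touching the threshold exactly does not count
  touch <- rbind(rep(20L, 6), rep(0L, 6))
  expect_equal(compute_ihip(touch), 0)
  # monotone in threshold and horizon on a fixed matrix
  m <- withr::with_seed(44, matrix(sample(0:50, 400, TRUE), 20, 20))
  expect_gte(compute_ihip(m, 10), compute_ihip(m, 30))
  expect_gte(compute_ihip(m[, 1:20]), compute_ihip(m[, 1:5]))
})

test_that("FUT is the first crossing of the interval-range rule, else censored", {
  f <- compute_fut(c(10, 20, 26, 30, 40))
  expect_equal(f$days, 3)
  expect_false(f$censored)
  f <- compute_fut(rep(25, 60))  # never strictly above
  expect_equal(f$days, 60)
  expect_true(f$censored)
})

test_that("V is the mean within-draw interval range with an 80% HDI", {
  # all groups identical: zero-width HDI at v
  day_draws <- rep(c(0, 10), times = 50)
  groups <- rep(1:50, each = 2)
  v <- compute_v(day_draws, groups)
  expect_equal(v$v, 9.5)  # eti(c(0,10), .95) = (0.25, 9.75) per group
  expect_equal(unname(v$v_hdi80), c(9.5, 9.5))
  expect_error(compute_v(1:5, rep(1, 5)), "two parameter-draw groups")

  # streamed vs batch cross-check
  dd <- withr::with_seed(45, rnorm(1000, 20, 5))
  gg <- rep(1:50, each = 20)
  direct <- vapply(split(dd, gg), function(x) diff(unname(quantile(x, c(.025, .975)))),
                   numeric(1))
  expect_equal(compute_v(dd, gg)$v, mean(direct), tolerance = 1e-10)
})

test_that("degenerate dynamics freeze predictive trajectories at the start score", {
  cfg <- obs_config(sigma_y = 1e-9)
  phi <- rbind(c(baseline = 0, diffusion = -40),
               c(baseline = 0, diffusion = -40))  # two identical draws so V is defined
  paths <- simulate_score_paths(phi, 25, obs_cfg = cfg, horizon = 30,
                                paths_per_draw = 25, seed = 46)
  expect_true(all(paths == 25L))
  s <- summarize_paths(paths)
  expect_equal(s$ihip, 1)  # 25 > 20 on every day
  expect_equal(s$v, 0)
  expect_true(s$fut_censored)
})

test_that("latent predictive variance grows linearly for the Wiener model", {
  phi2 <- -0.8
  spec <- model_spec(variant = 2)
  lat <- withr::with_seed(47, {
    t(vapply(1:4000, function(i) {
      simulate_latent_path(c(baseline = 0, diffusion = phi2), spec, 1:40,
                           rnorm(40))
    }, numeric(40)))
  })
  v_day <- apply(lat, 2, var)
  slope <- coef(lm(v_day ~ 0 + seq_len(40)))[[1]]
  expect_lt(abs(slope - exp(2 * phi2)) / exp(2 * phi2), 0.1)
})

test_that("daily bands nest and prediction summaries are well-formed", {
  paths <- simulate_score_paths(c(baseline = -4, diffusion = -1), 5,
                                horizon = 60, paths_per_draw = 300, seed = 48)
  s <- summarize_paths(paths)
  d <- s$daily
  expect_equal(nrow(d), 60)
  expect_true(all(d$eti95_lo <= d$eti68_lo))
  expect_true(all(d$eti68_lo <= d$median))
  expect_true(all(d$median <= d$eti68_hi))
  expect_true(all(d$eti68_hi <= d$eti95_hi))
  expect_true(s$ihip >= 0 && s$ihip <= 1)
  expect_gte(s$fut_days, 1)
  g <- glance(s)
  expect_named(g, c("ihip", "fut_days", "fut_censored", "v", "v_hdi80_lo",
                    "v_hdi80_hi", "horizon", "threshold"))
  expect_identical(tidy(s), d)
})

test_that("greater diffusion shortens the recommended follow-up time", {
  futs <- vapply(1:10, function(s) {
    lo <- summarize_paths(simulate_score_paths(
      c(baseline = -4, diffusion = -1.6), 5, horizon = 60,
      paths_per_draw = 400, seed = 700 + s))
    hi <- summarize_paths(simulate_score_paths(
      c(baseline = -4, diffusion = -0.2), 5, horizon = 60,
      paths_per_draw = 400, seed = 700 + s))
    c(lo = lo$fut_days, hi = hi$fut_days)
  }, numeric(2))
  expect_true(all(futs["hi", ] <= futs["lo", ]))
  expect_lt(mean(futs["hi", ]), mean(futs["lo", ]))
})

test_that("prior predictive baseline draws collapse with the population", {
  spec <- model_spec(variant = 2)
  tight <- population_params(spec,
                             mu = c(baseline = inverse_link(10), diffusion = -1),
                             tau = c(baseline = 1e-9, diffusion = 1e-9),
                             sigma_y = 1e-9)
  pp <- prior_predictive_baseline(tight, n_draws = 500, seed = 49)
  expect_true(all(pp$draws$baseline_score == 10L))
  expect_equal(pp$summary$median[pp$summary$term == "diffusion"], -1,
               tolerance = 1e-6)

  wide <- population_params(spec,
                            mu = c(baseline = -4.39, diffusion = -1.23),
                            tau = c(baseline = 2, diffusion = 0.6),
                            sigma_y = 0.5)
  pp <- prior_predictive_baseline(wide, n_draws = 4000, seed = 50)
  expect_true(all(pp$draws$baseline_score >= 0 & pp$draws$baseline_score <= 50))
  # summaries agree with an independent quantile routine on the same draws
  expect_equal(pp$summary$median[1], median(pp$draws$baseline_score))
})

test_that("fit-based prediction is reproducible and spans the horizon", {
  co <- generate_cohort(cohort_config(n_individuals = 4, zero_fraction = 0,
                                      n_obs_fixed = 6, gap_median_days = 7,
                                      gap_sdlog = 0.5, seed = 51))
  fit <- fit_trajectories(co$data,
                          config = sampler_config(iterations = 80, burnin = 40,
                                                  n_particles = 30, seed = 6))
  p1 <- simulate_predictive(fit, "ind001", horizon = 25, n_draws = 10,
                            paths_per_draw = 3, seed = 52)
  p2 <- simulate_predictive(fit, "ind001", horizon = 25, n_draws = 10,
                            paths_per_draw = 3, seed = 52)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(30, 25))
  expect_true(all(p1 >= 0 & p1 <= 50))
  expect_error(simulate_predictive(fit, "nobody"), "not present")
})

test_that("dynamic updating tightens predictive bands as observations accrue", {
  spec <- model_spec(variant = 2)
  map_pop <- population_params(spec,
                               mu = c(baseline = -4.39, diffusion = -1.23),
                               tau = c(baseline = 2, diffusion = 0.6),
                               sigma_y = 0.5)
  # a stable simulated individual: low diffusion, moderate score
  phi <- c(baseline = inverse_link(8), diffusion = -2)
  ser <- make_series(phi, times = seq(0, 90, by = 10), seed = 53)
  d <- tibble::tibble(time_days = ser$times, sidas_total = ser$scores)
  cfg <- sampler_config(iterations = 400, burnin = 150, n_particles = 50,
                        seed = 7)
  widths <- vapply(1:10, function(rep) {
    res1 <- update_individual(map_pop, d[1, ], spec,
                              config = sampler_config(iterations = 400,
                                                      burnin = 150,
                                                      n_particles = 50,
                                                      seed = 7 + rep),
                              n_draws = 60, paths_per_draw = 4)
    res10 <- update_individual(map_pop, d, spec,
                               config = sampler_config(iterations = 400,
                                                       burnin = 150,
                                                       n_particles = 50,
                                                       seed = 7 + rep),
                               n_draws = 60, paths_per_draw = 4)
    w1 <- with(res1$prediction$daily[30, ], eti95_hi - eti95_lo)
    w10 <- with(res10$prediction$daily[30, ], eti95_hi - eti95_lo)
    c(w1, w10)
  }, numeric(2))
  expect_lt(mean(widths[2, ]), mean(widths[1, ]))
  expect_error(update_individual(map_pop, d[0, ], spec), "empty")
})
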