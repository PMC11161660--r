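# Independent reference implementations used to validate the particle
# filter and the MH kernel. Deliberately written from first principles,
# sharing no code with the package internals.

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen of the Jacobi matrix).
gh_rule <- function(n) {
  b <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- b
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# Exact log-likelihood of a 2-observation Wiener series (first obs at t=0)
# by Gauss-Hermite quadrature over the latent state at the second time.
oracle_gh_loglik_2obs <- function(times, scores, phi, obs_cfg, n_nodes = 800) {
  stopifnot(length(times) == 2, times[1] == 0)
  rule <- gh_rule(n_nodes)
  v <- exp(2 * phi[["diffusion"]]) * (times[2] - times[1])
  x1 <- phi[["baseline"]] + sqrt(2 * v) * rule$x
  lik1 <- sum(rule$w * exp(observation_loglik(scores[2], x1, obs_cfg))) / sqrt(pi)
  observation_loglik(scores[1], phi[["baseline"]], obs_cfg) + log(lik1)
}

# Exact Kalman-filter log-likelihood for the linear-Gaussian test mode
# (random walk latent state, identity link, continuous normal noise).
oracle_kalman_loglik <- function(times, ys, phi, sigma_y) {
  s2 <- exp(2 * phi[["diffusion"]])
  m <- phi[["baseline"]]
  P <- 0
  dts <- diff(c(0, times))
  ll <- 0
  for (i in seq_along(ys)) {
    P <- P + s2 * dts[i]
    S <- P + sigma_y^2
    ll <- ll + dnorm(ys[i], m, sqrt(S), log = TRUE)
    K <- P / S
    m <- m + K * (ys[i] - m)
    P <- (1 - K) * P
  }
  ll
}

# Exact (to discretisation error) log-likelihood of the discretised-score
# state-space model by dense-grid numerical integration (HMM filter on a
# latent grid). Wiener dynamics only.
oracle_grid_loglik <- function(times, scores, phi, obs_cfg, n_grid = 401,
                               width = 6) {
  dts <- diff(c(0, times))
  sd_tot <- sqrt(exp(2 * phi[["diffusion"]]) * sum(dts))
  x0 <- phi[["baseline"]]
  grid <- seq(x0 - width * sd_tot - 1e-6, x0 + width * sd_tot + 1e-6,
              length.out = n_grid)
  ll <- 0
  f <- NULL  # filtering density over the grid (normalised weights)
  for (i in seq_along(scores)) {
    if (dts[i] == 0) {
      if (is.null(f)) {
        pred <- as.numeric(grid == grid[which.min(abs(grid - x0))])
      } else {
        pred <- f
      }
    } else {
      s <- sqrt(exp(2 * phi[["diffusion"]]) * dts[i])
      if (is.null(f)) {
        pred <- dnorm(grid, x0, s)
        pred <- pred / sum(pred)
      } else {
        Tm <- outer(grid, grid, function(from, to) dnorm(to, from, s))
        Tm <- Tm / rowSums(Tm)
        pred <- as.vector(f %*% Tm)
      }
    }
    w <- exp(observation_loglik(scores[i], grid, obs_cfg))
    lik <- sum(pred * w)
    ll <- ll + log(lik)
    f <- pred * w / lik
  }
  ll
}

# Grid posterior over the diffusion parameter for one individual with the
# baseline held fixed: trapezoid-normalised prior x exact likelihood.
oracle_grid_posterior_phi2 <- function(times, scores, phi1, obs_cfg,
                                       prior_mean, prior_sd,
                                       phi2_grid = seq(-3, 0.5, length.out = 201)) {
  logpost <- vapply(phi2_grid, function(p2) {
    oracle_grid_loglik(times, scores,
                       c(baseline = phi1, diffusion = p2), obs_cfg) +
      dnorm(p2, prior_mean, prior_sd, log = TRUE)
  }, numeric(1))
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  list(grid = phi2_grid, weights = w, mean = sum(w * phi2_grid))
}

# Bootstrap filter WITHOUT pre-resampling sorting, used to verify that
# sorting leaves the marginal distribution of the estimator unchanged.
pf_loglik_nosort <- function(times, scores, phi, spec, obs_cfg, aux) {
  pn <- aux$particle_normals
  rn <- aux$resample_normals
  n_p <- nrow(pn)
  dts <- diff(c(0, times))
  s2 <- exp(2 * phi[["diffusion"]])
  x <- rep(phi[["baseline"]], n_p)
  ll <- 0
  for (i in seq_along(scores)) {
    if (dts[i] > 0) x <- x + sqrt(s2 * dts[i]) * pn[, i]
    lw <- observation_loglik(scores[i], x, obs_cfg)
    mx <- max(lw)
    w <- exp(lw - mx)
    ll <- ll + mx + log(mean(w))
    if (i < length(scores)) {
      cw <- cumsum(w) / sum(w)
      pos <- (pnorm(rn[i]) + seq_len(n_p) - 1) / n_p
      x <- x[findInterval(pos, cw, left.open = TRUE) + 1L]
    }
  }
  ll
}

# simulate one individual's irregular score series with known parameters
make_series <- function(phi, times, spec = model_spec(variant = 2),
                        obs_cfg = obs_config(), seed = 1) {
  withr::with_seed(seed, {
    n_steps <- sum(diff(c(0, times)) > 0)
    x <- simulate_latent_path(phi, spec, times, rnorm(n_steps))
    list(times = times, scores = sample_observation(x, obs_cfg,
                                                    runif(length(times))),
         latent = x)
  })
}
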