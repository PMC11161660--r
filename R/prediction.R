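#' Equal-tailed credible interval
#'
#' Empirical `(1 - level) / 2` and `1 - (1 - level) / 2` quantiles.
#'
#' @param draws Numeric draws (at least one).
#' @param level Probability mass in `(0, 1]`.
#' @return Named numeric `c(lower, upper)`.
#' @export
eti <- function(draws, level = 0.95) {
  if (length(draws) == 0L) stop("no draws supplied", call. = FALSE)
  stopifnot(level > 0, level <= 1)
  a <- (1 - level) / 2
  stats::setNames(stats::quantile(draws, c(a, 1 - a), names = FALSE),
                  c("lower", "upper"))
}

#' Highest-density credible interval
#'
#' Shortest contiguous interval containing `level` of the draws
#' (sorted-window algorithm). For symmetric unimodal samples it agrees with
#' the equal-tailed interval; for skewed samples it hugs the density peak.
#'
#' @inheritParams eti
#' @return Named numeric `c(lower, upper)`.
#' @export
hdi <- function(draws, level = 0.8) {
  if (length(draws) < 2L) stop("hdi needs at least two draws", call. = FALSE)
  stopifnot(level > 0, level <= 1)
  x <- sort(draws)
  n <- length(x)
  k <- max(1L, ceiling(level * n))
  if (k >= n) return(stats::setNames(c(x[1], x[n]), c("lower", "upper")))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  stats::setNames(c(x[i], x[i + k]), c("lower", "upper"))
}

# vectorised daily latent stepping + score sampling for a set of paths.
# phi_mat: one row per path; x0: latent start per path; sigma_y per path.
.simulate_daily_scores <- function(x0, phi_mat, sigma_y, spec, obs_cfg, horizon) {
  P <- length(x0)
  out <- matrix(NA_integer_, P, horizon)
  x <- x0
  wiener <- spec$model == "wiener"
  s2 <- exp(2 * phi_mat[, "diffusion"])
  if (!wiener) {
    theta <- exp(phi_mat[, "drift"])
    phi4 <- phi_mat[, "constant"]
    decay <- exp(-theta)
    v <- ifelse(theta < 1e-10, s2, s2 / (2 * theta) * -expm1(-2 * theta))
  }
  for (d in seq_len(horizon)) {
    if (wiener) {
      x <- x + sqrt(s2) * stats::rnorm(P)
    } else {
      x <- phi4 + (x - phi4) * decay + sqrt(v) * stats::rnorm(P)
    }
    mu <- link_mean(x, obs_cfg)
    z <- mu + sigma_y * stats::rnorm(P)
    out[, d] <- as.integer(pmin(pmax(round(z), 0), obs_cfg$score_max))
  }
  out
}

#' Simulate posterior predictive score trajectories for one individual
#'
#' For each selected posterior draw, re-runs the particle filter on the
#' individual's observations to draw the current latent state from the
#' filtering distribution at the last observation, then simulates the
#' latent SDE forward on a daily grid and samples an integer score each day
#' through the observation model. Several paths share each parameter draw so
#' that per-draw summaries (the V statistic) are well defined.
#'
#' @param fit An `ideatraj_fit`.
#' @param id Individual identifier present in the fit.
#' @param horizon Days ahead (default 60).
#' @param n_draws Posterior parameter draws used (evenly thinned).
#' @param paths_per_draw Trajectories simulated per parameter draw.
#' @param seed Optional integer seed.
#' @return Integer matrix `(n_draws * paths_per_draw) x horizon` with
#'   attribute `draw` mapping rows to parameter draws.
#' @export
simulate_predictive <- function(fit, id, horizon = 60, n_draws = 200,
                                paths_per_draw = 5, seed = NULL) {
  stopifnot(n_draws >= 1, paths_per_draw >= 1, horizon >= 1)
  ids <- dimnames(fit$phi_draws)[[2]]
  if (!as.character(id) %in% ids) {
    stop("individual ", id, " not present in the fit", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  d <- fit$obs_index[fit$obs_index$individual_id == id, ]
  S <- nrow(fit$pop_draws)
  sel <- unique(round(seq(1, S, length.out = min(n_draws, S))))
  n_draws <- length(sel)
  P <- n_draws * paths_per_draw
  x0 <- numeric(P)
  phi_mat <- matrix(NA_real_, P, length(fit$spec$slots),
                    dimnames = list(NULL, fit$spec$slots))
  sy <- numeric(P)
  for (k in seq_along(sel)) {
    s <- sel[k]
    phi <- fit$phi_draws[s, as.character(id), ]
    sigma_y_s <- fit$pop_draws[s, "sigma_y"]
    oc <- obs_config(fit$obs_cfg$score_max, sigma_y_s, fit$obs_cfg$link_scale,
                     fit$obs_cfg$family)
    aux <- make_aux(fit$config$n_particles, nrow(d))
    cloud <- .pf_filter_particles(d$time_days, as.integer(d$sidas_total),
                                  phi, fit$spec, oc, aux)
    rows <- (k - 1) * paths_per_draw + seq_len(paths_per_draw)
    x0[rows] <- cloud[sample.int(length(cloud), paths_per_draw, replace = TRUE)]
    phi_mat[rows, ] <- matrix(phi, paths_per_draw, length(phi), byrow = TRUE)
    sy[rows] <- sigma_y_s
  }
  paths <- .simulate_daily_scores(x0, phi_mat, sy, fit$spec, fit$obs_cfg, horizon)
  attr(paths, "draw") <- rep(seq_len(n_draws), each = paths_per_draw)
  paths
}

#' Simulate predictive score trajectories from explicit parameters
#'
#' Forward simulation without a fitted object: the latent state starts at
#' the inverse link of `start_score` and diffuses under the given parameter
#' vector (or one row per draw). This is the computation behind statements
#' like "a trajectory started at score 2 with diffusion -1.23 diffuses to
#' \[1, 4\] within a week".
#'
#' @param phi Parameter vector matching `spec`, or a matrix with one row per
#'   parameter draw.
#' @param start_score Score at the reference observation.
#' @param spec A [model_spec()].
#' @param obs_cfg An [obs_config()].
#' @param horizon Days ahead.
#' @param paths_per_draw Trajectories per parameter draw (rows of `phi`).
#' @param seed Optional integer seed.
#' @return Integer score matrix with attribute `draw`, as
#'   [simulate_predictive()].
#' @export
simulate_score_paths <- function(phi, start_score, spec = model_spec(variant = 2),
                                 obs_cfg = obs_config(), horizon = 60,
                                 paths_per_draw = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(phi))) phi <- matrix(phi, 1, dimnames = list(NULL, spec$slots))
  if (is.null(colnames(phi))) colnames(phi) <- spec$slots
  n_draws <- nrow(phi)
  P <- n_draws * paths_per_draw
  x0 <- rep(inverse_link(start_score, obs_cfg), P)
  phi_mat <- phi[rep(seq_len(n_draws), each = paths_per_draw), , drop = FALSE]
  paths <- .simulate_daily_scores(x0, phi_mat, rep(obs_cfg$sigma_y, P), spec,
                                  obs_cfg, horizon)
  attr(paths, "draw") <- rep(seq_len(n_draws), each = paths_per_draw)
  paths
}

#' Integrated high-ideation probability
#'
#' Fraction of simulated trajectories whose score exceeds the high-ideation
#' threshold (strictly) on at least one day of the horizon.
#'
#' @param paths Score matrix (paths x days).
#' @param threshold High-ideation cut-off; a score must be strictly greater
#'   to count (default 20, the SIDAS high-ideation boundary).
#' @return Probability in `[0, 1]`.
#' @export
compute_ihip <- function(paths, threshold = 20) {
  if (length(paths) == 0L) stop("no trajectories supplied", call. = FALSE)
  mean(apply(paths, 1, max) > threshold)
}

#' Recommended follow-up time from daily interval ranges
#'
#' First day (1-based) on which the 95% equal-tailed interval of predicted
#' scores spans more than half the score range (range `> 25` for SIDAS),
#' read as the point where past observations have lost half their
#' information. If the range never crosses the cut-off the value is censored
#' at the horizon.
#'
#' @param ranges Daily interval ranges (hi - lo), length = horizon.
#' @param cutoff Range cut-off (default 25).
#' @return List with `days` (integer) and `censored` (logical).
#' @export
compute_fut <- function(ranges, cutoff = 25) {
  stopifnot(length(ranges) >= 1, all(ranges >= 0))
  idx <- which(ranges > cutoff)
  if (length(idx) == 0L) {
    list(days = length(ranges), censored = TRUE)
  } else {
    list(days = idx[1], censored = FALSE)
  }
}

#' Future observational variability
#'
#' For each posterior parameter draw, the 95% equal-tailed range of the
#' horizon-day score across that draw's trajectories; V is the mean of those
#' ranges and the uncertainty is their 80% highest-density interval (the
#' range distribution is typically wide-tailed and asymmetric, which is why
#' an HDI rather than a wider equal-tailed summary is reported).
#'
#' @param day_draws Scores at the horizon day, one per trajectory.
#' @param groups Parameter-draw index per trajectory (at least two groups).
#' @param level ETI level for the within-draw range (default 0.95).
#' @param hdi_level HDI level for the across-draw summary (default 0.8).
#' @return List with `v`, `v_hdi80` (named lower/upper), and `ranges`.
#' @export
compute_v <- function(day_draws, groups, level = 0.95, hdi_level = 0.8) {
  stopifnot(length(day_draws) == length(groups))
  if (length(unique(groups)) < 2L) {
    stop("compute_v needs at least two parameter-draw groups", call. = FALSE)
  }
  ranges <- vapply(split(day_draws, groups), function(v) {
    q <- eti(v, level)
    q[["upper"]] - q[["lower"]]
  }, numeric(1))
  list(v = mean(ranges), v_hdi80 = hdi(ranges, hdi_level),
       ranges = unname(ranges))
}

#' Summarise simulated trajectories into daily bands and clinical statistics
#'
#' @param paths Score matrix from [simulate_predictive()] or
#'   [simulate_score_paths()] (attribute `draw` required for V).
#' @param threshold High-ideation threshold for IHIP.
#' @param fut_cutoff Interval-range cut-off for the follow-up time.
#' @return An object of class `ideatraj_prediction` holding the `daily`
#'   band tibble (median, 68% and 95% ETI per day) and the scalars `ihip`,
#'   `fut_days`/`fut_censored`, `v` with `v_hdi80`.
#' @export
summarize_paths <- function(paths, threshold = 20, fut_cutoff = 25) {
  horizon <- ncol(paths)
  q <- apply(paths, 2, stats::quantile,
             probs = c(0.025, 0.16, 0.5, 0.84, 0.975), names = FALSE)
  daily <- tibble::tibble(
    day = seq_len(horizon),
    median = q[3, ],
    eti68_lo = q[2, ], eti68_hi = q[4, ],
    eti95_lo = q[1, ], eti95_hi = q[5, ]
  )
  fut <- compute_fut(daily$eti95_hi - daily$eti95_lo, fut_cutoff)
  groups <- attr(paths, "draw")
  v <- if (!is.null(groups) && length(unique(groups)) >= 2L) {
    compute_v(paths[, horizon], groups)
  } else {
    list(v = NA_real_, v_hdi80 = c(lower = NA_real_, upper = NA_real_))
  }
  structure(
    list(daily = daily, ihip = compute_ihip(paths, threshold),
         fut_days = fut$days, fut_censored = fut$censored,
         v = v$v, v_hdi80 = v$v_hdi80,
         horizon = horizon, threshold = threshold),
    class = "ideatraj_prediction"
  )
}

#' Posterior predictive summary for one individual
#'
#' Convenience wrapper: [simulate_predictive()] followed by
#' [summarize_paths()].
#'
#' @inheritParams simulate_predictive
#' @inheritParams summarize_paths
#' @return An `ideatraj_prediction`.
#' @export
predictive_summary <- function(fit, id, horizon = 60, threshold = 20,
                               n_draws = 200, paths_per_draw = 5,
                               seed = NULL) {
  paths <- simulate_predictive(fit, id, horizon, n_draws, paths_per_draw, seed)
  out <- summarize_paths(paths, threshold)
  out$individual_id <- as.character(id)
  out
}

#' @export
print.ideatraj_prediction <- function(x, ...) {
  cat(sprintf("<ideatraj_prediction> %d-day horizon%s\n", x$horizon,
              if (!is.null(x$individual_id)) paste0(" for ", x$individual_id) else ""))
  cat(sprintf("  IHIP %.3f | FUT %d day(s)%s | V %.1f (80%% HDI %.1f-%.1f)\n",
              x$ihip, x$fut_days, if (x$fut_censored) " (censored)" else "",
              x$v, x$v_hdi80[["lower"]], x$v_hdi80[["upper"]]))
  invisible(x)
}

#' Dynamically update one individual against a frozen population prior
#'
#' Re-estimates a single individual's parameters from an observation prefix
#' with the population-level prior frozen at point estimates (typically
#' [map_population()] of a cohort fit), then produces the forward predictive
#' summary from the prefix's last observation. Iterating this over growing
#' prefixes reproduces the clinical updating loop in which predictive bands
#' tighten as observations accrue. Population-parameter uncertainty is
#' deliberately not propagated.
#'
#' @param map_pop A [population_params()] point estimate.
#' @param data Observation prefix for one individual (columns `time_days`,
#'   `sidas_total`; at least one row).
#' @param spec A [model_spec()].
#' @param obs_cfg An [obs_config()] (its `sigma_y` is overridden by
#'   `map_pop$sigma_y`).
#' @param config A [sampler_config()] for the single-individual chain.
#' @param horizon,threshold,n_draws,paths_per_draw Prediction settings.
#' @return List with `draws` (matrix of retained parameter draws),
#'   `acceptance`, and `prediction` (an `ideatraj_prediction`).
#' @export
update_individual <- function(map_pop, data, spec = map_pop$spec,
                              obs_cfg = obs_config(),
                              config = sampler_config(iterations = 1500,
                                                      burnin = 500),
                              horizon = 60, threshold = 20, n_draws = 200,
                              paths_per_draw = 5) {
  if (nrow(data) == 0L) stop("empty observation prefix", call. = FALSE)
  times <- data$time_days
  scores <- as.integer(data$sidas_total)
  if (is.unsorted(times)) {
    o <- order(times)
    times <- times[o]
    scores <- scores[o]
  }
  oc <- obs_config(obs_cfg$score_max, map_pop$sigma_y, obs_cfg$link_scale,
                   obs_cfg$family)
  set.seed(config$seed)
  r <- which(spec$random)
  f <- which(!spec$random)
  phi <- stats::setNames(numeric(length(spec$slots)), spec$slots)
  phi[r] <- map_pop$mu
  phi[f] <- map_pop$fixed
  aux <- make_aux(config$n_particles, length(times))
  res <- particle_filter_loglik(times, scores, phi, spec, oc, aux)
  state <- list(phi = phi, aux = aux, loglik = res$loglik,
                increments = res$increments)
  n_keep <- config$iterations - config$burnin
  draws <- matrix(NA_real_, n_keep, length(spec$slots),
                  dimnames = list(NULL, spec$slots))
  log_scale <- log(config$proposal_scale)
  acc <- 0
  for (it in seq_len(config$iterations)) {
    state <- cpm_mh_individual_step(state, map_pop, spec, oc, times, scores,
                                    scales = exp(log_scale), rho = config$rho)
    if (config$adapt && it <= config$burnin) {
      log_scale <- log_scale + min(0.25, 2 / sqrt(it)) *
        (state$accepted - config$target_accept)
    }
    if (it > config$burnin) {
      acc <- acc + state$accepted
      draws[it - config$burnin, ] <- state$phi
    }
  }

  sel <- unique(round(seq(1, n_keep, length.out = min(n_draws, n_keep))))
  P <- length(sel) * paths_per_draw
  x0 <- numeric(P)
  phi_mat <- matrix(NA_real_, P, length(spec$slots),
                    dimnames = list(NULL, spec$slots))
  for (k in seq_along(sel)) {
    phi_s <- draws[sel[k], ]
    cloud <- .pf_filter_particles(times, scores, phi_s, spec, oc,
                                  make_aux(config$n_particles, length(times)))
    rows <- (k - 1) * paths_per_draw + seq_len(paths_per_draw)
    x0[rows] <- cloud[sample.int(length(cloud), paths_per_draw, replace = TRUE)]
    phi_mat[rows, ] <- matrix(phi_s, paths_per_draw, length(phi_s), byrow = TRUE)
  }
  paths <- .simulate_daily_scores(x0, phi_mat, rep(oc$sigma_y, P), spec, oc,
                                  horizon)
  attr(paths, "draw") <- rep(seq_along(sel), each = paths_per_draw)
  pred <- summarize_paths(paths, threshold)
  list(draws = draws, acceptance = acc / n_keep, prediction = pred)
}

#' Prior predictive distribution of the baseline score and diffusion
#'
#' Draws individual parameters from the population normals, maps the latent
#' baseline through the observation model to a predicted baseline score, and
#' summarises both margins by median and 95% HDI. This is the reference
#' distribution against which fitted individual medians are usually plotted.
#'
#' @param pop A [population_params()].
#' @param obs_cfg An [obs_config()] (its `sigma_y` is overridden by
#'   `pop$sigma_y`).
#' @param n_draws Number of draws (>= 2).
#' @param seed Optional seed.
#' @return List with `draws` (tibble: `baseline_score`, `diffusion`) and
#'   `summary` (tibble: term, median, hdi95 bounds).
#' @export
prior_predictive_baseline <- function(pop, obs_cfg = obs_config(),
                                      n_draws = 2000, seed = NULL) {
  stopifnot(n_draws >= 2)
  if (!is.null(seed)) set.seed(seed)
  spec <- pop$spec
  oc <- obs_config(obs_cfg$score_max, pop$sigma_y, obs_cfg$link_scale,
                   obs_cfg$family)
  draw_slot <- function(slot) {
    if (spec$random[[slot]]) {
      stats::rnorm(n_draws, pop$mu[[slot]], pop$tau[[slot]])
    } else {
      rep(pop$fixed[[slot]], n_draws)
    }
  }
  phi1 <- draw_slot("baseline")
  phi2 <- draw_slot("diffusion")
  y0 <- sample_observation(phi1, oc, stats::runif(n_draws))
  summ <- function(v) {
    h <- hdi(v, 0.95)
    c(median = stats::median(v), h)
  }
  s1 <- summ(y0)
  s2 <- summ(phi2)
  list(
    draws = tibble::tibble(baseline_score = y0, diffusion = phi2),
    summary = tibble::tibble(
      term = c("baseline_score", "diffusion"),
      median = c(s1[["median"]], s2[["median"]]),
      hdi95_lo = c(s1[["lower"]], s2[["lower"]]),
      hdi95_hi = c(s1[["upper"]], s2[["upper"]])
    )
  )
}
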