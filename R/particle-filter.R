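#' Auxiliary random numbers for the particle filter
#'
#' The correlated pseudo-marginal scheme treats every random number the
#' filter consumes as an explicit auxiliary variable, so the filter is a
#' deterministic function of (data, parameters, auxiliaries). Two Gaussian
#' blocks are held: one standard normal per particle per transition, and one
#' standard normal per observation step that is pushed through the normal CDF
#' to give the systematic-resampling uniform. Keeping the whole block
#' Gaussian lets a single Crank--Nicolson step correlate successive proposals.
#'
#' @param n_particles Number of particles.
#' @param n_obs Number of observations for the individual.
#' @return An object of class `ideatraj_aux`: list with `particle_normals`
#'   (`n_particles x n_obs` matrix) and `resample_normals` (length `n_obs`).
#' @export
make_aux <- function(n_particles, n_obs) {
  stopifnot(n_particles >= 1, n_obs >= 1)
  structure(
    list(
      particle_normals = matrix(stats::rnorm(n_particles * n_obs),
                                n_particles, n_obs),
      resample_normals = stats::rnorm(n_obs)
    ),
    class = "ideatraj_aux"
  )
}

#' Crank--Nicolson refresh of auxiliary variables
#'
#' `u' = rho * u + sqrt(1 - rho^2) * fresh`, elementwise on both Gaussian
#' blocks. The standard-normal marginal is preserved for any `rho` in
#' `[0, 1]`; `rho = 0` replaces the block, `rho = 1` keeps it unchanged.
#' High `rho` makes successive likelihood estimates share most of their
#' Monte-Carlo noise, which is what keeps the pseudo-marginal acceptance
#' rate usable at small particle counts.
#'
#' @param aux An [make_aux()] object.
#' @param rho Correlation in `[0, 1]`.
#' @param fresh An independent [make_aux()] block of identical shape.
#' @return A refreshed `ideatraj_aux`.
#' @export
refresh_aux <- function(aux, rho, fresh) {
  if (!is.finite(rho) || rho < 0 || rho > 1) {
    stop("rho must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(identical(dim(aux$particle_normals), dim(fresh$particle_normals)))
  w <- sqrt(1 - rho^2)
  structure(
    list(
      particle_normals = rho * aux$particle_normals + w * fresh$particle_normals,
      resample_normals = rho * aux$resample_normals + w * fresh$resample_normals
    ),
    class = "ideatraj_aux"
  )
}

#' Bootstrap particle-filter log-likelihood for one individual
#'
#' Estimates the marginal likelihood of an irregularly timed score sequence
#' under the latent SDE + discretised observation model. All particles start
#' at the latent baseline `phi1` at time 0; each observation step propagates
#' them by the exact transition over the elapsed gap using the supplied
#' normal deviates, weights them by the observation likelihood, records the
#' predictive increment `log(mean weight)`, and systematically resamples
#' with the step's single uniform after sorting particles by state value.
#' Sorting keeps the mapping from auxiliary numbers to likelihood smooth in
#' the parameters, which the correlated pseudo-marginal sampler relies on.
#' The estimator of the likelihood (not the log) is unbiased.
#'
#' @param times Increasing observation days, `times[1] >= 0`.
#' @param scores Integer scores, same length as `times`.
#' @param phi Individual parameter vector matching `spec`.
#' @param spec A [model_spec()].
#' @param obs_cfg An [obs_config()].
#' @param aux An [make_aux()] block shaped `(n_particles, length(times))`.
#' @return List with `loglik` (total) and `increments` (per observation,
#'   summing to the total).
#' @export
particle_filter_loglik <- function(times, scores, phi, spec,
                                   obs_cfg = obs_config(), aux) {
  n <- length(times)
  if (n == 0L) stop("no observations supplied", call. = FALSE)
  stopifnot(length(scores) == n, ncol(aux$particle_normals) == n)
  if (is.unsorted(times) || times[1] < 0) {
    stop("observation times must be sorted and non-negative", call. = FALSE)
  }
  check_phi(phi, spec)
  .pf_core(diff(c(0, times)), scores, phi, spec, obs_cfg,
           aux$particle_normals, aux$resample_normals)
}

# hot loop shared by the sampler; dts are gaps from t = 0
.pf_core <- function(dts, scores, phi, spec, obs_cfg, pn, rn) {
  n_p <- nrow(pn)
  n <- length(scores)
  wiener <- spec$model == "wiener"
  if (wiener) {
    s2 <- exp(2 * phi[[2]])
  } else {
    theta <- exp(phi[[3]])
    s2 <- exp(2 * phi[[2]])
    phi4 <- phi[[4]]
  }
  x <- rep.int(phi[[1]], n_p)
  inc <- numeric(n)
  min_ess <- Inf
  for (i in seq_len(n)) {
    dt <- dts[i]
    if (dt > 0) {
      if (wiener) {
        x <- x + sqrt(s2 * dt) * pn[, i]
      } else {
        decay <- exp(-theta * dt)
        v <- if (theta * dt < 1e-10) s2 * dt else s2 / (2 * theta) * -expm1(-2 * theta * dt)
        x <- phi4 + (x - phi4) * decay + sqrt(v) * pn[, i]
      }
    }
    lw <- observation_loglik(scores[i], x, obs_cfg)
    mx <- max(lw)
    if (!is.finite(mx)) {
      stop(sprintf(
        "particle weights degenerate at observation %d (phi = %s)",
        i, paste(signif(phi, 4), collapse = ", ")), call. = FALSE)
    }
    w <- exp(lw - mx)
    sw <- sum(w)
    inc[i] <- mx + log(sw / n_p)
    ess <- sw^2 / sum(w^2)
    if (ess < min_ess) min_ess <- ess
    if (i < n) {
      o <- order(x)
      cw <- cumsum(w[o]) / sw
      pos <- (stats::pnorm(rn[i]) + seq_len(n_p) - 1) / n_p
      idx <- findInterval(pos, cw, left.open = TRUE) + 1L
      x <- x[o][pmin(idx, n_p)]
    }
  }
  # min_ess flags weight degeneracy (effective sample size across steps)
  list(loglik = sum(inc), increments = inc, min_ess = min_ess)
}

# filtering distribution at the last observation: returns the equally
# weighted particle cloud after weighting/resampling at the final step
.pf_filter_particles <- function(times, scores, phi, spec, obs_cfg, aux) {
  dts <- diff(c(0, times))
  pn <- aux$particle_normals
  rn <- aux$resample_normals
  n_p <- nrow(pn)
  n <- length(scores)
  wiener <- spec$model == "wiener"
  s2 <- exp(2 * phi[[2]])
  if (!wiener) {
    theta <- exp(phi[[3]])
    phi4 <- phi[[4]]
  }
  x <- rep.int(phi[[1]], n_p)
  for (i in seq_len(n)) {
    dt <- dts[i]
    if (dt > 0) {
      if (wiener) {
        x <- x + sqrt(s2 * dt) * pn[, i]
      } else {
        decay <- exp(-theta * dt)
        v <- if (theta * dt < 1e-10) s2 * dt else s2 / (2 * theta) * -expm1(-2 * theta * dt)
        x <- phi4 + (x - phi4) * decay + sqrt(v) * pn[, i]
      }
    }
    lw <- observation_loglik(scores[i], x, obs_cfg)
    mx <- max(lw)
    w <- exp(lw - mx)
    o <- order(x)
    cw <- cumsum(w[o]) / sum(w)
    pos <- (stats::pnorm(rn[i]) + seq_len(n_p) - 1) / n_p
    idx <- findInterval(pos, cw, left.open = TRUE) + 1L
    x <- x[o][pmin(idx, n_p)]
  }
  x
}
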