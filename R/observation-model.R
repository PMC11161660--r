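#' Observation model configuration
#'
#' The observation model carries an unbounded latent state onto the bounded,
#' integer 0--`score_max` score scale (SIDAS: five 0--10 items, summed max
#' 50). The latent state is mapped through a scaled logistic link to a mean
#' on the score scale, and the integer score follows a discretised normal
#' distribution around that mean whose boundary bins absorb the tails.
#'
#' The defaults (`link_scale = 0.5`, `sigma_y = 0.5`) are calibrated so that
#' a Wiener trajectory started at score 2 with diffusion parameter -1.23
#' diffuses to a day-7 predictive 95% equal-tailed interval of \[1, 4\]; see
#' the methods vignette for the calibration.
#'
#' `family = "gaussian"` switches to an identity link with a continuous
#' normal observation density. This linear-Gaussian mode exists so the
#' particle-filter likelihood can be validated against an exact Kalman
#' filter; it is not meant for score data.
#'
#' @param score_max Maximum summed score (default 50).
#' @param sigma_y Observation SD on the score scale, `> 0`.
#' @param link_scale Logistic steepness, `> 0`.
#' @param family `"sidas"` (discretised bounded scores) or `"gaussian"`
#'   (identity link, continuous density; validation only).
#' @return An object of class `ideatraj_obs` (a list of the four fields).
#' @export
obs_config <- function(score_max = 50L, sigma_y = 0.5, link_scale = 0.5,
                       family = c("sidas", "gaussian")) {
  family <- match.arg(family)
  stopifnot(length(score_max) == 1L, score_max >= 1, score_max == as.integer(score_max))
  if (!is.finite(sigma_y) || sigma_y <= 0) {
    stop("sigma_y must be a positive number", call. = FALSE)
  }
  if (!is.finite(link_scale) || link_scale <= 0) {
    stop("link_scale must be a positive number", call. = FALSE)
  }
  structure(
    list(score_max = as.integer(score_max), sigma_y = sigma_y,
         link_scale = link_scale, family = family),
    class = "ideatraj_obs"
  )
}

#' Logistic link from latent state to expected score
#'
#' `score_max * plogis(link_scale * x)`: strictly increasing, with latent 0
#' mapping to the score midpoint.
#'
#' @param x Latent state(s).
#' @param cfg An [obs_config()].
#' @return Expected score(s) in `(0, score_max)`.
#' @export
link_mean <- function(x, cfg = obs_config()) {
  if (cfg$family == "gaussian") return(x)
  cfg$score_max * stats::plogis(cfg$link_scale * x)
}

#' Inverse of the logistic link
#'
#' Maps a score back to the latent scale. The boundary scores 0 and
#' `score_max` have no finite preimage and are offset inward by 0.5 before
#' inversion.
#'
#' @param y Score(s) in `[0, score_max]`.
#' @inheritParams link_mean
#' @return Latent value(s).
#' @export
inverse_link <- function(y, cfg = obs_config()) {
  if (any(!is.finite(y)) || any(y < 0) || any(y > cfg$score_max)) {
    stop("scores must lie in [0, ", cfg$score_max, "]", call. = FALSE)
  }
  if (cfg$family == "gaussian") return(y)
  y[y == 0] <- 0.5
  y[y == cfg$score_max] <- cfg$score_max - 0.5
  stats::qlogis(y / cfg$score_max) / cfg$link_scale
}

#' Probability mass function of the discretised normal score distribution
#'
#' Interior scores take the normal probability of the unit-width bin centred
#' on them; the boundary scores absorb the corresponding tail so the pmf
#' sums to one for any mean.
#'
#' @param mu Mean on the score scale.
#' @param sigma_y Observation SD, `> 0`.
#' @param score_max Maximum score.
#' @return Probability vector over scores `0..score_max`.
#' @examples
#' p <- discretized_normal_pmf(10, 2)
#' sum(p)
#' @export
discretized_normal_pmf <- function(mu, sigma_y, score_max = 50L) {
  if (!is.finite(sigma_y) || sigma_y <= 0) {
    stop("sigma_y must be a positive number", call. = FALSE)
  }
  k <- 0:score_max
  hi <- stats::pnorm(k + 0.5, mu, sigma_y)
  lo <- stats::pnorm(k - 0.5, mu, sigma_y)
  p <- hi - lo
  p[1] <- hi[1]
  p[score_max + 1L] <- 1 - lo[score_max + 1L]
  p
}

# log(pnorm(b) - pnorm(a)) for standardised bounds a < b, stable in both
# tails; vectorised. Used so the observation log-likelihood stays finite for
# any finite latent state.
.log_pnorm_diff <- function(a, b) {
  out <- numeric(length(a))
  upper <- (a + b) / 2 > 0
  if (any(upper)) {
    la <- stats::pnorm(a[upper], lower.tail = FALSE, log.p = TRUE)
    lb <- stats::pnorm(b[upper], lower.tail = FALSE, log.p = TRUE)
    out[upper] <- la + log1p(-exp(lb - la))
  }
  if (any(!upper)) {
    la <- stats::pnorm(a[!upper], log.p = TRUE)
    lb <- stats::pnorm(b[!upper], log.p = TRUE)
    out[!upper] <- lb + log1p(-exp(la - lb))
  }
  out
}

#' Observation log-likelihood of a score given a latent state
#'
#' Log of the discretised-normal pmf entry for `y`, with the mean given by
#' the logistic link at `x`. Computed on the log scale throughout, so the
#' result is finite for every finite latent state even when the score sits
#' many observation SDs from the linked mean. Vectorised over `x` (used for
#' particle weights).
#'
#' @param y Integer score in `0..score_max` (scalar).
#' @param x Latent state(s).
#' @inheritParams link_mean
#' @return Log-likelihood value(s).
#' @export
observation_loglik <- function(y, x, cfg = obs_config()) {
  if (cfg$family == "gaussian") {
    return(stats::dnorm(y, x, cfg$sigma_y, log = TRUE))
  }
  if (length(y) != 1L || !is.finite(y) || y < 0 || y > cfg$score_max ||
      y != round(y)) {
    stop("y must be one integer score in 0..", cfg$score_max, call. = FALSE)
  }
  mu <- link_mean(x, cfg)
  s <- cfg$sigma_y
  if (y == 0) {
    stats::pnorm((0.5 - mu) / s, log.p = TRUE)
  } else if (y == cfg$score_max) {
    stats::pnorm((y - 0.5 - mu) / s, lower.tail = FALSE, log.p = TRUE)
  } else {
    .log_pnorm_diff((y - 0.5 - mu) / s, (y + 0.5 - mu) / s)
  }
}

#' Sample a score given a latent state by inverse-CDF
#'
#' Equivalent to rounding a normal draw on the score scale and clamping to
#' the boundaries, which is exactly the discretised-normal pmf with
#' tail-absorbing boundary bins. Deterministic given the uniform deviate(s).
#'
#' @param x Latent state(s).
#' @inheritParams link_mean
#' @param u Uniform deviate(s) in `[0, 1)`, recycled against `x`.
#' @return Integer score(s).
#' @export
sample_observation <- function(x, cfg = obs_config(), u) {
  stopifnot(all(u >= 0), all(u < 1))
  mu <- link_mean(x, cfg)
  z <- mu + cfg$sigma_y * stats::qnorm(u)
  as.integer(pmin(pmax(round(z), 0), cfg$score_max))
}
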