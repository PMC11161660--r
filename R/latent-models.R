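#' Exact transition moments of the latent Wiener process
#'
#' The Wiener (continuous-time random walk) process has Gaussian increments:
#' over an elapsed gap of `dt` days the state stays centred at its current
#' value while the variance grows linearly, `exp(2 * phi2) * dt`, where
#' `exp(phi2)` is the diffusion SD per square-root day.
#'
#' @param x0 Current latent state (vectorised).
#' @param dt Elapsed time in days, `>= 0` (scalar).
#' @param phi2 Log diffusion SD.
#' @return A list with elements `mean` and `variance` (the latter scalar).
#' @examples
#' wiener_transition(0, dt = 4, phi2 = 0)
#' @export
wiener_transition <- function(x0, dt, phi2) {
  stopifnot(is.finite(x0), length(dt) == 1L, is.finite(dt), is.finite(phi2))
  if (dt < 0) stop("elapsed time dt must be non-negative", call. = FALSE)
  list(mean = x0, variance = exp(2 * phi2) * dt)
}

#' Exact transition moments of the latent Ornstein--Uhlenbeck process
#'
#' The OU (continuous-time autoregressive) process adds mean reversion to the
#' Wiener process: the state is pulled towards a long-term constant `phi4` at
#' rate `theta = exp(phi3)` per day. Over a gap `dt`:
#' mean `= phi4 + (x0 - phi4) * exp(-theta * dt)` and variance
#' `= sigma^2 / (2 * theta) * (1 - exp(-2 * theta * dt))` with
#' `sigma = exp(phi2)`. As `theta -> 0` the moments converge to the Wiener
#' ones; the implementation switches to the limit expression for tiny rates
#' so the convergence is numerically exact.
#'
#' @inheritParams wiener_transition
#' @param phi3 Log mean-reversion rate per day.
#' @param phi4 Long-term latent constant.
#' @return A list with elements `mean` and `variance`.
#' @examples
#' ou_transition(0, dt = 50, phi2 = 0, phi3 = 0, phi4 = 3)
#' @export
ou_transition <- function(x0, dt, phi2, phi3, phi4) {
  stopifnot(is.finite(x0), length(dt) == 1L, is.finite(dt),
            is.finite(phi2), is.finite(phi3), is.finite(phi4))
  if (dt < 0) stop("elapsed time dt must be non-negative", call. = FALSE)
  theta <- exp(phi3)
  decay <- exp(-theta * dt)
  s2 <- exp(2 * phi2)
  v <- if (theta * dt < 1e-10) s2 * dt else s2 / (2 * theta) * -expm1(-2 * theta * dt)
  list(mean = phi4 + (x0 - phi4) * decay, variance = v)
}

# dispatch on the spec; phi is the full slot vector
transition_moments <- function(x0, dt, phi, spec) {
  if (spec$model == "wiener") {
    wiener_transition(x0, dt, phi[[2]])
  } else {
    ou_transition(x0, dt, phi[[2]], phi[[3]], phi[[4]])
  }
}

#' Simulate a latent trajectory at given times from supplied noise
#'
#' Steps the exact transition law of the chosen process through an increasing
#' time grid, consuming one standard-normal deviate per stochastic step. The
#' latent state at time 0 is `phi1` exactly; a first time point greater than
#' zero is reached by a transition over that gap (consuming a deviate), and a
#' first time point equal to zero yields `phi1` without consuming noise.
#' The function is deterministic given its inputs, which makes it usable both
#' for data generation and for common-random-number comparisons.
#'
#' @param phi Numeric parameter vector matching `spec` (see [model_spec()]).
#' @param spec An [model_spec()] object.
#' @param times Increasing numeric vector of observation days, `times[1] >= 0`.
#' @param noise Standard-normal deviates, one per stochastic step: length
#'   `length(times) - 1` when `times[1] == 0`, otherwise `length(times)`.
#' @return Numeric latent state vector, one entry per time.
#' @examples
#' simulate_latent_path(c(1, 0), model_spec(variant = 2), times = 0:2,
#'                      noise = c(1, 1))
#' @export
simulate_latent_path <- function(phi, spec, times, noise) {
  check_phi(phi, spec)
  if (length(times) == 0L) return(numeric(0))
  if (is.unsorted(times, strictly = TRUE) || times[1] < 0) {
    stop("times must be strictly increasing and non-negative", call. = FALSE)
  }
  dts <- diff(c(0, times))
  n_steps <- sum(dts > 0)
  if (length(noise) != n_steps) {
    stop("noise must supply one deviate per stochastic step (need ", n_steps, ")",
         call. = FALSE)
  }
  x <- numeric(length(times))
  cur <- phi[[1]]
  k <- 0L
  for (i in seq_along(times)) {
    if (dts[i] > 0) {
      k <- k + 1L
      m <- transition_moments(cur, dts[i], phi, spec)
      cur <- m$mean + sqrt(m$variance) * noise[k]
    }
    x[i] <- cur
  }
  x
}
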