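#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a fitted trajectory model
#'
#' @param x An `ideatraj_fit`.
#' @param pars `"population"` (default) for population-level terms or
#'   `"individual"` for per-individual parameters.
#' @param conf_level ETI level for the interval columns.
#' @param ... Unused.
#' @return A tibble with `term` (and `individual_id` for individual
#'   parameters), `estimate` (posterior mean), `std.error` (posterior SD),
#'   `conf.low`, `conf.high`.
#' @export
tidy.ideatraj_fit <- function(x, pars = c("population", "individual"),
                              conf_level = 0.95, ...) {
  pars <- match.arg(pars)
  summ <- function(v) {
    q <- eti(v, conf_level)
    tibble::tibble(estimate = mean(v), std.error = stats::sd(v),
                   conf.low = q[["lower"]], conf.high = q[["upper"]])
  }
  if (pars == "population") {
    keep <- colnames(x$pop_draws)
    if (!x$config$estimate_sigma_y) keep <- setdiff(keep, "sigma_y")
    purrr::map_dfr(keep, function(nm) {
      dplyr::bind_cols(tibble::tibble(term = nm), summ(x$pop_draws[, nm]))
    })
  } else {
    ids <- dimnames(x$phi_draws)[[2]]
    slots <- dimnames(x$phi_draws)[[3]]
    purrr::map_dfr(ids, function(id) {
      purrr::map_dfr(slots, function(sl) {
        dplyr::bind_cols(
          tibble::tibble(individual_id = id, term = sl),
          summ(x$phi_draws[, id, sl])
        )
      })
    })
  }
}

#' One-row summary of a fitted trajectory model
#'
#' @param x An `ideatraj_fit`.
#' @param ... Unused.
#' @return Tibble with model descriptors, draw counts and acceptance rates.
#' @export
glance.ideatraj_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$model,
    variant = x$spec$variant,
    n_individuals = dim(x$phi_draws)[2],
    n_obs = nrow(x$obs_index),
    iterations = x$config$iterations,
    burnin = x$config$burnin,
    n_draws = nrow(x$pop_draws),
    mean_acceptance = mean(x$acceptance$rate),
    acceptance_fixed = x$acceptance_fixed,
    pf_degeneracy_rate = x$degeneracy_rate,
    n_particles = x$config$n_particles,
    rho = x$config$rho
  )
}

#' Daily predictive bands of a prediction object
#'
#' @param x An `ideatraj_prediction`.
#' @param ... Unused.
#' @return The `daily` tibble: `day`, `median`, `eti68_lo/hi`, `eti95_lo/hi`.
#' @export
tidy.ideatraj_prediction <- function(x, ...) x$daily

#' One-row summary of a prediction object
#'
#' @param x An `ideatraj_prediction`.
#' @param ... Unused.
#' @return Tibble with `ihip`, `fut_days`, `fut_censored`, `v`, `v_hdi80_lo`,
#'   `v_hdi80_hi`, `horizon`, `threshold`.
#' @export
glance.ideatraj_prediction <- function(x, ...) {
  tibble::tibble(
    ihip = x$ihip, fut_days = x$fut_days, fut_censored = x$fut_censored,
    v = x$v, v_hdi80_lo = x$v_hdi80[["lower"]],
    v_hdi80_hi = x$v_hdi80[["upper"]],
    horizon = x$horizon, threshold = x$threshold
  )
}
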