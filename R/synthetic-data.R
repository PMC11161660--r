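#' Configuration for a synthetic measurement-based-care cohort
#'
#' The generator emulates the sampling structure typical of routinely
#' monitored clinical cohorts on digital platforms: hierarchical-normal
#' random effects over individual parameters, a heavily skewed number of
#' observations per individual (most people answer twice, a few dozens of
#' times), log-normal inter-observation gaps spanning days to months, and a
#' structural subgroup reporting zero ideation throughout care.
#'
#' Defaults mirror the observed structure of such cohorts: observation
#' counts with median 2 and mean 4.5 (minimum 2, the usual inclusion rule),
#' gap median 35 days with a log-scale spread targeting an interquartile
#' ratio near 1:108, and a 26% zero-ideation fraction. The default
#' population centres the diffusion parameter at -1.23 and the baseline at
#' the latent preimage of score 5, with SDs chosen to give a realistic
#' spread of baseline scores (roughly 0--20) and of trajectory volatility;
#' see the methods vignette.
#'
#' @param n_individuals Cohort size.
#' @param spec A [model_spec()].
#' @param true_pop A [population_params()] used as ground truth.
#' @param count_p2,count_q Observation-count law: with probability
#'   `count_p2` an individual has exactly 2 observations, otherwise
#'   `2 + 1 + Geom(count_q)`. The defaults give median 2 and mean 4.5.
#' @param n_obs_fixed Optional integer: give every individual exactly this
#'   many observations (overrides the count law; used for designed
#'   simulation studies).
#' @param gap_median_days,gap_sdlog Log-normal gap law (median, log-SD).
#' @param zero_fraction Probability of a structural zero-ideation individual.
#' @param seed Integer seed.
#' @return An object of class `ideatraj_cohort_config`.
#' @export
cohort_config <- function(n_individuals = 100,
                          spec = model_spec(variant = 2),
                          true_pop = population_params(
                            spec,
                            mu = c(baseline = -4.39, diffusion = -1.23),
                            tau = c(baseline = 2, diffusion = 0.6),
                            sigma_y = 0.5
                          ),
                          count_p2 = 0.55, count_q = 0.18,
                          n_obs_fixed = NULL,
                          gap_median_days = 35, gap_sdlog = 3.47,
                          zero_fraction = 0.26, seed = 1) {
  stopifnot(n_individuals >= 1, count_p2 >= 0, count_p2 <= 1,
            count_q > 0, count_q < 1)
  if (!is.finite(gap_median_days) || gap_median_days <= 0 || gap_sdlog <= 0) {
    stop("gap law needs a positive median and log-SD", call. = FALSE)
  }
  if (zero_fraction < 0 || zero_fraction > 1) {
    stop("zero_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_individuals = as.integer(n_individuals), spec = spec,
         true_pop = true_pop, count_p2 = count_p2, count_q = count_q,
         n_obs_fixed = if (!is.null(n_obs_fixed)) as.integer(n_obs_fixed),
         gap_median_days = gap_median_days, gap_sdlog = gap_sdlog,
         zero_fraction = zero_fraction, seed = as.integer(seed)),
    class = "ideatraj_cohort_config"
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Per individual: draws the parameter vector from the population normals
#' (fixed slots copied as-is), draws an observation count and log-normal
#' gaps, simulates the exact latent SDE path at those times, and samples
#' integer scores through the observation model. Individuals flagged as
#' structural zeros emit all-zero scores regardless of their latent
#' dynamics, emulating the never-ideating subgroup that the continuous model
#' deliberately does not capture. Fully reproducible from the config's seed.
#'
#' @param config A [cohort_config()].
#' @return An object of class `ideatraj_cohort`: list with `data` (long
#'   tibble: `individual_id`, `time_days`, `sidas_total`), `truth` (tibble
#'   of per-individual true parameters and the structural-zero flag), and
#'   the `config` echo.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_individuals = 20, seed = 42))
#' cohort_summary(cohort$data)
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  spec <- config$spec
  pop <- config$true_pop
  oc <- obs_config(sigma_y = pop$sigma_y)
  n <- config$n_individuals
  ids <- sprintf("ind%03d", seq_len(n))
  zero <- stats::runif(n) < config$zero_fraction

  rows <- vector("list", n)
  truth_phi <- matrix(NA_real_, n, length(spec$slots),
                      dimnames = list(ids, spec$slots))
  for (m in seq_len(n)) {
    phi <- stats::setNames(numeric(length(spec$slots)), spec$slots)
    for (slot in spec$slots) {
      phi[slot] <- if (spec$random[[slot]]) {
        stats::rnorm(1, pop$mu[[slot]], pop$tau[[slot]])
      } else {
        pop$fixed[[slot]]
      }
    }
    truth_phi[m, ] <- phi
    n_obs <- if (!is.null(config$n_obs_fixed)) config$n_obs_fixed else
      if (stats::runif(1) < config$count_p2) 2L else
        3L + stats::rgeom(1, config$count_q)
    gaps <- stats::rlnorm(n_obs - 1L, log(config$gap_median_days),
                          config$gap_sdlog)
    times <- cumsum(c(0, gaps))
    x <- simulate_latent_path(phi, spec, times, stats::rnorm(n_obs - 1L))
    scores <- sample_observation(x, oc, stats::runif(n_obs))
    if (zero[m]) scores <- rep.int(0L, n_obs)
    rows[[m]] <- tibble::tibble(individual_id = ids[m], time_days = times,
                                sidas_total = scores)
  }
  structure(
    list(
      data = dplyr::bind_rows(rows),
      truth = tibble::as_tibble(cbind(
        tibble::tibble(individual_id = ids, structural_zero = zero),
        tibble::as_tibble(truth_phi)
      )),
      config = config
    ),
    class = "ideatraj_cohort"
  )
}

#' @export
print.ideatraj_cohort <- function(x, ...) {
  cat(sprintf("<ideatraj_cohort> %d individuals, %d observations (seed %d)\n",
              x$config$n_individuals, nrow(x$data), x$config$seed))
  invisible(x)
}

#' Construct baseline covariates with configurable dependence on a parameter
#'
#' Builds a covariate table keyed by individual id for association studies
#' against the true diffusion values: continuous covariates are
#' `effect * phi2 + N(0, 1)` noise; binary covariates apply a median
#' threshold on `phi2` with a label-flip probability. `effect = 0` (or flip
#' probability 0.5) gives null covariates.
#'
#' @param truth The `truth` tibble of an [generate_cohort()] result.
#' @param continuous Named numeric vector of effect sizes for continuous
#'   covariates.
#' @param binary Named numeric vector of label-flip probabilities for binary
#'   covariates.
#' @param seed Optional seed.
#' @return Tibble with `individual_id` and one column per covariate.
#' @export
make_covariates <- function(truth, continuous = c(null_cov = 0),
                            binary = numeric(0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(is.finite(continuous)), all(binary >= 0), all(binary <= 0.5))
  phi2 <- truth$diffusion
  n <- length(phi2)
  out <- tibble::tibble(individual_id = truth$individual_id)
  for (nm in names(continuous)) {
    out[[nm]] <- continuous[[nm]] * phi2 + stats::rnorm(n)
  }
  for (nm in names(binary)) {
    lab <- as.integer(phi2 > stats::median(phi2))
    flip <- stats::runif(n) < binary[[nm]]
    out[[nm]] <- ifelse(flip, 1L - lab, lab)
  }
  out
}

#' Descriptive summary of a long observation table
#'
#' The statistics routinely reported for monitored cohorts: size,
#' observation-count distribution, inter-observation gap quartiles, and the
#' fraction of individuals who never report a non-zero score.
#'
#' @param data Long observation table (`individual_id`, `time_days`,
#'   `sidas_total`).
#' @return One-row tibble.
#' @export
cohort_summary <- function(data) {
  if (nrow(data) == 0L) {
    return(tibble::tibble(
      n_individuals = 0L, n_obs = 0L, obs_mean = NA_real_, obs_median = NA_real_,
      pct_ge5 = NA_real_, pct_ge10 = NA_real_, gap_median = NA_real_,
      gap_q1 = NA_real_, gap_q3 = NA_real_, zero_fraction = NA_real_
    ))
  }
  per <- data |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      all_zero = all(.data$sidas_total == 0),
      .groups = "drop"
    )
  gaps <- data |>
    dplyr::arrange(.data$individual_id, .data$time_days) |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::reframe(gap = diff(.data$time_days)) |>
    dplyr::pull("gap")
  gq <- if (length(gaps)) stats::quantile(gaps, c(0.25, 0.5, 0.75), names = FALSE)
        else rep(NA_real_, 3)
  tibble::tibble(
    n_individuals = nrow(per),
    n_obs = nrow(data),
    obs_mean = mean(per$n),
    obs_median = stats::median(per$n),
    pct_ge5 = 100 * mean(per$n >= 5),
    pct_ge10 = 100 * mean(per$n >= 10),
    gap_median = gq[2], gap_q1 = gq[1], gap_q3 = gq[3],
    zero_fraction = mean(per$all_zero)
  )
}
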