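#' Validate and normalise a long observation table
#'
#' Checks column presence and types, rejects out-of-range or non-integer
#' scores and negative times (naming offending rows), resolves duplicate
#' (individual, time) records by keeping the last (re-entry interpretation,
#' with a warning), offsets residual same-day entries by 1e-3 days to keep
#' strict ordering, and sorts per individual by time.
#'
#' @param data Data frame with `individual_id`, `time_days`, `sidas_total`.
#' @param score_max Maximum valid score.
#' @return A sorted, validated tibble.
#' @export
validate_dataset <- function(data, score_max = 50L) {
  need <- c("individual_id", "time_days", "sidas_total")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  data$individual_id <- as.character(data$individual_id)
  bad_time <- which(!is.finite(data$time_days) | data$time_days < 0)
  if (length(bad_time)) {
    stop("negative or missing time_days on row(s): ",
         paste(utils::head(bad_time, 5), collapse = ", "), call. = FALSE)
  }
  s <- data$sidas_total
  bad_score <- which(!is.finite(s) | s < 0 | s > score_max | s != round(s))
  if (length(bad_score)) {
    stop("scores outside 0..", score_max, " or non-integer on row(s): ",
         paste(utils::head(bad_score, 5), collapse = ", "), call. = FALSE)
  }
  data$sidas_total <- as.integer(s)
  dup <- duplicated(data[, c("individual_id", "time_days")], fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate (individual, time) record(s) dropped, ",
            "keeping the last entry", call. = FALSE)
    data <- data[!dup, ]
  }
  data <- dplyr::arrange(data, .data$individual_id, .data$time_days)
  # same-day repeated entries at distinct recorded times are already distinct;
  # guard against exact float ties sneaking through grouped arithmetic
  data <- data |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::mutate(time_days = .data$time_days +
                    1e-3 * (seq_along(.data$time_days) - 1) *
                    (duplicated(.data$time_days))) |>
    dplyr::ungroup()
  data
}

#' Read a long-format observation CSV
#'
#' Loads, validates (see [validate_dataset()]) and filters a long SIDAS
#' observation table, dropping individuals with fewer than `min_obs`
#' observations (the usual inclusion rule requires at least two completed
#' assessments).
#'
#' @param path CSV with columns `individual_id`, `time_days`, `sidas_total`.
#' @param min_obs Minimum observations per retained individual.
#' @param score_max Maximum valid score.
#' @return A validated tibble; the number of dropped individuals is
#'   messaged.
#' @export
read_sidas_data <- function(path, min_obs = 2, score_max = 50L) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  data <- validate_dataset(raw, score_max)
  counts <- table(data$individual_id)
  keep <- names(counts)[counts >= min_obs]
  dropped <- length(counts) - length(keep)
  if (dropped > 0) {
    message(dropped, " individual(s) dropped with fewer than ", min_obs,
            " observations")
  }
  data[data$individual_id %in% keep, ]
}

#' Write posterior samples to columnar CSV files
#'
#' Individual-level draws go to `<stem>_individual.csv` (long:
#' `draw, individual_id, parameter, value`) and population-level draws to
#' `<stem>_population.csv` (long: `draw, parameter, value`).
#'
#' @param fit An `ideatraj_fit`.
#' @param stem Output path stem.
#' @return Invisibly, the two file paths.
#' @export
write_fit_csv <- function(fit, stem) {
  phi <- fit$phi_draws
  # array storage order: draw fastest, then individual, then parameter
  ind <- tibble::tibble(
    draw = rep(seq_len(dim(phi)[1]), times = dim(phi)[2] * dim(phi)[3]),
    individual_id = rep(rep(dimnames(phi)[[2]], each = dim(phi)[1]),
                        times = dim(phi)[3]),
    parameter = rep(dimnames(phi)[[3]], each = dim(phi)[1] * dim(phi)[2]),
    value = as.vector(phi)
  )
  pop <- tibble::tibble(
    draw = rep(seq_len(nrow(fit$pop_draws)), times = ncol(fit$pop_draws)),
    parameter = rep(colnames(fit$pop_draws), each = nrow(fit$pop_draws)),
    value = as.vector(fit$pop_draws)
  )
  p1 <- paste0(stem, "_individual.csv")
  p2 <- paste0(stem, "_population.csv")
  readr::write_csv(ind, p1)
  readr::write_csv(pop, p2)
  invisible(c(p1, p2))
}

#' Serialise a predictive summary as JSON
#'
#' One record per individual per prediction time: horizon, daily band
#' arrays, IHIP, FUT (days + censoring flag), V with its 80% HDI, and the
#' seed used.
#'
#' @param pred An `ideatraj_prediction`.
#' @param path Output path.
#' @param seed Seed to echo into the record.
#' @return Invisibly, `path`.
#' @export
write_prediction_json <- function(pred, path, seed = NA_integer_) {
  rec <- list(
    individual_id = pred$individual_id,
    horizon = pred$horizon,
    threshold = pred$threshold,
    day = pred$daily$day,
    median = pred$daily$median,
    eti68_lo = pred$daily$eti68_lo, eti68_hi = pred$daily$eti68_hi,
    eti95_lo = pred$daily$eti95_lo, eti95_hi = pred$daily$eti95_hi,
    ihip = pred$ihip,
    fut_days = pred$fut_days, fut_censored = pred$fut_censored,
    v = pred$v,
    v_hdi80 = unname(pred$v_hdi80),
    seed = seed
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a synthetic cohort to CSV (+ JSON truth sidecar)
#'
#' @param cohort An [generate_cohort()] result.
#' @param stem Output path stem; writes `<stem>_observations.csv`,
#'   `<stem>_truth.json`, and `<stem>_covariates.csv` when covariates are
#'   supplied.
#' @param covariates Optional covariate tibble.
#' @return Invisibly, the written paths.
#' @export
write_cohort <- function(cohort, stem, covariates = NULL) {
  p_obs <- paste0(stem, "_observations.csv")
  readr::write_csv(cohort$data, p_obs)
  p_truth <- paste0(stem, "_truth.json")
  truth <- list(
    seed = cohort$config$seed,
    zero_fraction = cohort$config$zero_fraction,
    individuals = cohort$truth
  )
  jsonlite::write_json(truth, p_truth, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  paths <- c(p_obs, p_truth)
  if (!is.null(covariates)) {
    p_cov <- paste0(stem, "_covariates.csv")
    readr::write_csv(covariates, p_cov)
    paths <- c(paths, p_cov)
  }
  invisible(paths)
}
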