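#' Compare model variants by WAIC
#'
#' Fits each requested variant to the same data with the same sampler
#' settings and tabulates WAIC (deviance scale; lower is better) computed on
#' the observations of individuals with at least `waic_min_obs`
#' observations. The best (minimum-WAIC) variant is flagged.
#'
#' @param data Long observation table.
#' @param variants Integer vector of variant ids (see [model_spec()]).
#' @param obs_cfg An [obs_config()].
#' @param config A [sampler_config()]; each variant runs from the same seed.
#' @param waic_min_obs Subset rule for the WAIC computation.
#' @return Tibble with one row per variant: `variant`, `model`, `effects`,
#'   `waic`, `p_waic`, `best`.
#' @export
compare_variants <- function(data, variants = 1:4, obs_cfg = obs_config(),
                             config = sampler_config(), waic_min_obs = 10) {
  rows <- purrr::map(variants, function(v) {
    spec <- model_spec(variant = v)
    fit <- fit_trajectories(data, spec, obs_cfg, config, hyperpriors(spec))
    w <- waic(fit, min_obs = waic_min_obs)
    tibble::tibble(
      variant = v,
      model = spec$model,
      effects = paste(ifelse(spec$random, "random", "fixed"), collapse = "/"),
      waic = w$waic, p_waic = w$p_waic
    )
  })
  out <- dplyr::bind_rows(rows)
  out$best <- seq_len(nrow(out)) == which.min(out$waic)
  out
}

#' File-based pipeline stages
#'
#' Thin wrappers tying the package functions into a simulate / fit /
#' compare / predict / associate workflow over CSV and JSON artefacts; these
#' are what the command-line script dispatches to. Each returns its output
#' paths invisibly and echoes the seed into outputs where the format allows.
#'
#' @param out_stem Output path stem.
#' @param config A [cohort_config()] (`cmd_simulate`) or [sampler_config()]
#'   (others).
#' @param data_path Observations CSV path.
#' @param variant Model variant id.
#' @param obs_cfg An [obs_config()].
#' @param min_obs Inclusion rule for [read_sidas_data()].
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmd_simulate <- function(config = cohort_config(), out_stem) {
  cohort <- generate_cohort(config)
  write_cohort(cohort, out_stem)
}

#' @rdname pipeline
#' @export
cmd_fit <- function(data_path, out_stem, variant = 2,
                    obs_cfg = obs_config(), config = sampler_config(),
                    min_obs = 2) {
  data <- read_sidas_data(data_path, min_obs = min_obs,
                          score_max = obs_cfg$score_max)
  spec <- model_spec(variant = variant)
  fit <- fit_trajectories(data, spec, obs_cfg, config, hyperpriors(spec))
  paths <- write_fit_csv(fit, out_stem)
  saveRDS(fit, paste0(out_stem, "_fit.rds"))
  invisible(c(paths, paste0(out_stem, "_fit.rds")))
}

#' @rdname pipeline
#' @param variants Variant ids to compare.
#' @param waic_min_obs WAIC subset rule.
#' @export
cmd_compare <- function(data_path, out_stem, variants = 1:4,
                        obs_cfg = obs_config(), config = sampler_config(),
                        min_obs = 2, waic_min_obs = 10) {
  data <- read_sidas_data(data_path, min_obs = min_obs,
                          score_max = obs_cfg$score_max)
  tab <- compare_variants(data, variants, obs_cfg, config, waic_min_obs)
  p <- paste0(out_stem, "_waic.csv")
  readr::write_csv(tab, p)
  invisible(p)
}

#' @rdname pipeline
#' @param fit_path Path to a saved fit (`*_fit.rds` from [cmd_fit()]).
#' @param horizon,threshold Prediction settings.
#' @export
cmd_predict <- function(fit_path, out_stem, horizon = 60, threshold = 20) {
  fit <- readRDS(fit_path)
  ids <- dimnames(fit$phi_draws)[[2]]
  paths <- vapply(ids, function(id) {
    pred <- predictive_summary(fit, id, horizon = horizon,
                               threshold = threshold,
                               seed = fit$config$seed)
    write_prediction_json(pred, paste0(out_stem, "_", id, ".json"),
                          seed = fit$config$seed)
  }, character(1))
  invisible(unname(paths))
}

#' @rdname pipeline
#' @param covariates_path Covariates CSV (`individual_id` + columns).
#' @export
cmd_associate <- function(fit_path, covariates_path, out_stem) {
  fit <- readRDS(fit_path)
  cov <- readr::read_csv(covariates_path, show_col_types = FALSE)
  tab <- covariate_association(fit, cov)
  p <- paste0(out_stem, "_associations.csv")
  readr::write_csv(tab, p)
  invisible(p)
}
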