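#' Posterior association between baseline covariates and a model parameter
#'
#' For each covariate and each retained posterior draw, computes an
#' association statistic across individuals between that draw's parameter
#' values (default: the diffusion parameter) and the covariate, then
#' summarises the posterior of the statistic by its mean and 95%
#' equal-tailed interval. Continuous covariates use the Pearson correlation;
#' binary (0/1) covariates use the difference of group means (group 1 minus
#' group 0). Propagating every draw keeps the parameter uncertainty in the
#' reported interval.
#'
#' @param fit An `ideatraj_fit`.
#' @param covariates Data frame with `individual_id` plus one column per
#'   covariate; ids must match the fit, covariates must be non-constant, and
#'   binary columns may contain only 0/1.
#' @param slot Parameter slot to associate (default `"diffusion"`).
#' @return Tibble with one row per covariate: `covariate`, `type`,
#'   `estimate` (posterior mean), `conf.low`, `conf.high` (95% ETI).
#' @export
covariate_association <- function(fit, covariates, slot = "diffusion") {
  stopifnot(slot %in% fit$spec$slots)
  ids <- dimnames(fit$phi_draws)[[2]]
  if (length(ids) < 3L) {
    stop("need at least three individuals", call. = FALSE)
  }
  if (!"individual_id" %in% names(covariates)) {
    stop("covariates must carry an individual_id column", call. = FALSE)
  }
  cov_df <- as.data.frame(covariates)
  rownames(cov_df) <- as.character(cov_df$individual_id)
  missing_ids <- setdiff(ids, rownames(cov_df))
  if (length(missing_ids)) {
    stop("covariates missing for: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  cov_df <- cov_df[ids, setdiff(names(cov_df), "individual_id"), drop = FALSE]
  phi <- fit$phi_draws[, , slot, drop = FALSE][, , 1]  # draws x individuals
  purrr::map_dfr(names(cov_df), function(nm) {
    v <- cov_df[[nm]]
    if (length(unique(v)) < 2L) {
      stop("covariate '", nm, "' is constant; association undefined",
           call. = FALSE)
    }
    binary <- all(v %in% c(0, 1))
    stat <- if (binary) {
      apply(phi, 1, function(p) mean(p[v == 1]) - mean(p[v == 0]))
    } else {
      apply(phi, 1, function(p) stats::cor(p, v))
    }
    q <- eti(stat, 0.95)
    tibble::tibble(
      covariate = nm,
      type = if (binary) "binary" else "continuous",
      estimate = mean(stat),
      conf.low = q[["lower"]], conf.high = q[["upper"]]
    )
  })
}
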