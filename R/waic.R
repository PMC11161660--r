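#' Widely applicable information criterion from pointwise log-likelihoods
#'
#' Computes WAIC on the deviance scale from a draws-by-observations matrix
#' of log-likelihood increments: `lppd` is the sum over observations of the
#' log of the posterior-mean likelihood (log-sum-exp over draws), the
#' effective number of parameters `p_waic` is the sum of the per-observation
#' posterior variances of the log-likelihood, and
#' `WAIC = -2 * (lppd - p_waic)`. Lower is better.
#'
#' @param x A numeric matrix (draws x observations) of log-likelihood
#'   increments, or an `ideatraj_fit`.
#' @param ... Passed to methods.
#' @return A one-row tibble with `waic`, `p_waic`, `lppd`, `n_obs`.
#' @export
waic <- function(x, ...) UseMethod("waic")

#' @rdname waic
#' @export
waic.matrix <- function(x, ...) {
  if (nrow(x) < 2L) {
    stop("WAIC needs at least two posterior draws (variance undefined)",
         call. = FALSE)
  }
  S <- nrow(x)
  mx <- apply(x, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(x, 2, mx)))))
  p_waic <- sum(apply(x, 2, stats::var))
  tibble::tibble(waic = -2 * (lppd - p_waic), p_waic = p_waic, lppd = lppd,
                 n_obs = ncol(x))
}

#' @rdname waic
#' @param min_obs Only observations belonging to individuals with at least
#'   this many observations enter the computation (default 10, the usual
#'   subset rule for predictive comparison on sparsely observed cohorts).
#'   Use `min_obs = 0` for all observations.
#' @export
waic.ideatraj_fit <- function(x, min_obs = 10, ...) {
  counts <- table(x$obs_index$individual_id)
  keep_ids <- names(counts)[counts >= min_obs]
  keep <- x$obs_index$individual_id %in% keep_ids
  if (!any(keep)) {
    stop("no individuals with at least ", min_obs, " observations", call. = FALSE)
  }
  out <- waic.matrix(x$increments[, keep, drop = FALSE])
  out$n_individuals <- length(keep_ids)
  out
}
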