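#' Specify a latent trajectory model variant
#'
#' A model specification names the latent stochastic process (Wiener or
#' Ornstein--Uhlenbeck) and, for each individual-level parameter, whether it
#' is a *random* effect (drawn per individual from a population normal) or a
#' *fixed* effect (one value shared across the cohort).
#'
#' The four numbered variants mirror the standard model-comparison ladder for
#' this family, ordered by the number of free parameters:
#'
#' | variant | process | baseline | diffusion | drift | constant |
#' |--------:|---------|----------|-----------|-------|----------|
#' | 1 | Wiener | random | fixed  | --     | --     |
#' | 2 | Wiener | random | random | --     | --     |
#' | 3 | OU     | random | random | fixed  | random |
#' | 4 | OU     | random | random | random | random |
#'
#' Parameter slots are, in order: `baseline` (`phi1`, the latent initial
#' state), `diffusion` (`phi2`, log of the diffusion SD per sqrt(day)),
#' and for the OU process additionally `drift` (`phi3`, log mean-reversion
#' rate per day) and `constant` (`phi4`, the long-term latent level).
#'
#' @param model `"wiener"` or `"ou"`. Ignored when `variant` is given.
#' @param random Character vector naming the slots treated as random effects.
#'   Defaults to all slots. Ignored when `variant` is given.
#' @param variant Optional integer 1--4 selecting a standard variant.
#' @return An object of class `ideatraj_spec`: a list with elements `model`,
#'   `slots` (slot names), `random` (named logical), and `variant`.
#' @examples
#' model_spec(variant = 2)
#' model_spec("ou", random = c("baseline", "diffusion", "constant"))
#' @export
model_spec <- function(model = c("wiener", "ou"), random = NULL, variant = NULL) {
  if (!is.null(variant)) {
    stopifnot(length(variant) == 1L, variant %in% 1:4)
    variant <- as.integer(variant)
    model <- if (variant <= 2L) "wiener" else "ou"
    random <- switch(variant,
      c("baseline"),
      c("baseline", "diffusion"),
      c("baseline", "diffusion", "constant"),
      c("baseline", "diffusion", "drift", "constant")
    )
  } else {
    model <- match.arg(model)
  }
  slots <- if (model == "wiener") c("baseline", "diffusion") else
    c("baseline", "diffusion", "drift", "constant")
  if (is.null(random)) random <- slots
  if (!all(random %in% slots)) {
    stop("unknown parameter slot(s): ", paste(setdiff(random, slots), collapse = ", "),
         call. = FALSE)
  }
  is_random <- stats::setNames(slots %in% random, slots)
  if (is.null(variant)) variant <- .match_variant(model, is_random)
  structure(
    list(model = model, slots = slots, random = is_random, variant = variant),
    class = "ideatraj_spec"
  )
}

# reverse lookup of the variant table; NA for non-standard combinations
.match_variant <- function(model, is_random) {
  for (v in 1:4) {
    s <- model_spec(variant = v)
    if (s$model == model && identical(s$random, is_random)) return(v)
  }
  NA_integer_
}

#' @export
print.ideatraj_spec <- function(x, ...) {
  eff <- ifelse(x$random, "random", "fixed")
  cat(sprintf("<ideatraj_spec> %s process (variant %s)\n",
              if (x$model == "wiener") "Wiener" else "Ornstein-Uhlenbeck",
              ifelse(is.na(x$variant), "custom", x$variant)))
  cat(paste0("  ", format(x$slots, width = 9), eff, collapse = "\n"), "\n")
  invisible(x)
}

n_slots <- function(spec) length(spec$slots)

# validate an individual parameter vector against a spec
check_phi <- function(phi, spec) {
  if (length(phi) != n_slots(spec) || !all(is.finite(phi))) {
    stop("individual parameter vector must hold ", n_slots(spec),
         " finite values (", paste(spec$slots, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(phi)
}
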