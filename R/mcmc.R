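#' Hyperpriors for the population-level parameters
#'
#' Each random-effect slot `j` gets a semi-conjugate pair: a normal
#' hyperprior `mu_j ~ N(mu0_j, kappa0_j^2)` on the population mean and an
#' inverse-gamma hyperprior `tau_j^2 ~ IG(a0_j, b0_j)` on the population
#' variance. Fixed-effect slots use the normal component as the prior on the
#' shared value. Defaults are weakly informative on the latent scale:
#' `N(0, 5^2)` and `IG(2, 1)`.
#'
#' @param spec A [model_spec()].
#' @param mu0,kappa0,a0,b0 Scalars or named vectors over the spec's slots.
#' @return An object of class `ideatraj_hyper` with per-slot vectors.
#' @export
hyperpriors <- function(spec, mu0 = 0, kappa0 = 5, a0 = 2, b0 = 1) {
  expand <- function(v, what, positive = FALSE) {
    out <- stats::setNames(rep_len(v, n_slots(spec)), spec$slots)
    if (!is.null(names(v))) out[names(v)] <- v
    if (any(!is.finite(out)) || (positive && any(out <= 0))) {
      stop(what, " must be finite", if (positive) " and positive", call. = FALSE)
    }
    out
  }
  structure(
    list(mu0 = expand(mu0, "mu0"), kappa0 = expand(kappa0, "kappa0", TRUE),
         a0 = expand(a0, "a0", TRUE), b0 = expand(b0, "b0", TRUE)),
    class = "ideatraj_hyper"
  )
}

#' Population-level parameter set
#'
#' Bundles the population normal means/SDs for random-effect slots, the
#' shared values for fixed-effect slots, and the observation SD.
#'
#' @param spec A [model_spec()].
#' @param mu,tau Named vectors over the random-effect slots.
#' @param fixed Named vector over the fixed-effect slots (may be empty).
#' @param sigma_y Observation SD on the score scale.
#' @return An object of class `ideatraj_pop`.
#' @export
population_params <- function(spec, mu, tau, fixed = numeric(0), sigma_y = 0.5) {
  r <- spec$slots[spec$random]
  f <- spec$slots[!spec$random]
  if (!setequal(names(mu), r) || !setequal(names(tau), r)) {
    stop("mu and tau must be named over the random slots: ",
         paste(r, collapse = ", "), call. = FALSE)
  }
  if (!setequal(names(fixed), f)) {
    stop("fixed must be named over the fixed slots: ",
         paste(f, collapse = ", "), call. = FALSE)
  }
  if (any(tau <= 0)) stop("population SDs tau must be positive", call. = FALSE)
  structure(
    list(mu = mu[r], tau = tau[r], fixed = fixed[f], sigma_y = sigma_y,
         spec = spec),
    class = "ideatraj_pop"
  )
}

#' Sampler configuration
#'
#' @param n_particles Particles per filter evaluation.
#' @param rho Auxiliary-variable correlation in `[0, 1]` for the
#'   Crank--Nicolson refresh; `0.99` follows standard correlated
#'   pseudo-marginal practice.
#' @param proposal_scale Initial random-walk SD for the individual-parameter
#'   proposals (one multiplier per individual, adapted during burn-in toward
#'   `target_accept` and frozen afterwards).
#' @param iterations,burnin Total MCMC iterations and burn-in length.
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param estimate_sigma_y Also sample the observation SD (log-normal prior
#'   `log sigma_y ~ N(0, 1)`) via a pseudo-marginal MH step.
#' @param adapt Adapt proposal scales during burn-in.
#' @param target_accept Acceptance-rate target for adaptation.
#' @return An object of class `ideatraj_config`.
#' @export
sampler_config <- function(n_particles = 100, rho = 0.99, proposal_scale = 0.4,
                           iterations = 2000, burnin = 1000, seed = 1,
                           estimate_sigma_y = FALSE, adapt = TRUE,
                           target_accept = 0.3) {
  stopifnot(n_particles >= 1, rho >= 0, rho <= 1, proposal_scale > 0,
            burnin < iterations, burnin >= 0)
  structure(
    list(n_particles = as.integer(n_particles), rho = rho,
         proposal_scale = proposal_scale, iterations = as.integer(iterations),
         burnin = as.integer(burnin), seed = as.integer(seed),
         estimate_sigma_y = isTRUE(estimate_sigma_y), adapt = isTRUE(adapt),
         target_accept = target_accept),
    class = "ideatraj_config"
  )
}

#' One correlated pseudo-marginal MH update of an individual's parameters
#'
#' Proposes new values for the random-effect slots from a normal random walk
#' and a correlated refresh of the auxiliary variables, then accepts with
#' the pseudo-marginal ratio combining the particle-filter likelihood
#' estimate and the population random-effect prior (fixed slots carry no
#' prior term; they are updated at the population level).
#'
#' Exposed mainly for validation: `loglik_fun` can replace the particle
#' filter by an exact likelihood, in which case the kernel is a plain MH
#' sampler whose stationary distribution can be checked against numerical
#' integration.
#'
#' @param state List with `phi` (parameter vector), `aux`, `loglik`,
#'   `increments`.
#' @param pop A [population_params()] for the prior.
#' @param spec,obs_cfg Model and observation configuration.
#' @param times,scores The individual's data.
#' @param scales Proposal SD per random slot.
#' @param rho Auxiliary correlation.
#' @param loglik_fun Function `(phi, aux) -> list(loglik, increments)`;
#'   defaults to the particle filter on this individual's data.
#' @return Updated state list with an `accepted` flag.
#' @export
cpm_mh_individual_step <- function(state, pop, spec, obs_cfg, times, scores,
                                   scales, rho, loglik_fun = NULL) {
  r <- which(spec$random)
  if (is.null(loglik_fun)) {
    loglik_fun <- function(phi, aux) {
      particle_filter_loglik(times, scores, phi, spec, obs_cfg, aux)
    }
  }
  phi_new <- state$phi
  phi_new[r] <- phi_new[r] + scales * stats::rnorm(length(r))
  aux_new <- refresh_aux(state$aux, rho,
                         make_aux(nrow(state$aux$particle_normals),
                                  ncol(state$aux$particle_normals)))
  cand <- loglik_fun(phi_new, aux_new)
  logr <- cand$loglik - state$loglik +
    sum(stats::dnorm(phi_new[r], pop$mu, pop$tau, log = TRUE)) -
    sum(stats::dnorm(state$phi[r], pop$mu, pop$tau, log = TRUE))
  if (is.finite(logr) && log(stats::runif(1)) < logr) {
    list(phi = phi_new, aux = aux_new, loglik = cand$loglik,
         increments = cand$increments, min_ess = cand$min_ess,
         accepted = TRUE)
  } else {
    c(state[c("phi", "aux", "loglik", "increments")],
      state["min_ess"], list(accepted = FALSE))
  }
}

#' Semi-conjugate Gibbs update of the population parameters
#'
#' For every random-effect slot, draws the population mean from its normal
#' full conditional given the current individual values and population SD,
#' then the population variance from its inverse-gamma full conditional
#' given the freshly drawn mean.
#'
#' @param phi_mat Matrix of current individual parameters
#'   (individuals x slots, columns named by slot).
#' @param spec A [model_spec()].
#' @param hyper A [hyperpriors()].
#' @param tau Named vector of current population SDs (random slots).
#' @return List with updated `mu` and `tau` named vectors.
#' @export
gibbs_update_population <- function(phi_mat, spec, hyper, tau) {
  r <- spec$slots[spec$random]
  M <- nrow(phi_mat)
  mu <- stats::setNames(numeric(length(r)), r)
  tau_new <- stats::setNames(numeric(length(r)), r)
  for (j in r) {
    v <- phi_mat[, j]
    prec <- 1 / hyper$kappa0[[j]]^2 + M / tau[[j]]^2
    mean_j <- (hyper$mu0[[j]] / hyper$kappa0[[j]]^2 + sum(v) / tau[[j]]^2) / prec
    mu[[j]] <- stats::rnorm(1, mean_j, sqrt(1 / prec))
    a_n <- hyper$a0[[j]] + M / 2
    b_n <- hyper$b0[[j]] + 0.5 * sum((v - mu[[j]])^2)
    tau_new[[j]] <- sqrt(1 / stats::rgamma(1, a_n, rate = b_n))
  }
  list(mu = mu, tau = tau_new)
}

# split a long observation table into per-individual time/score lists
.split_individuals <- function(data) {
  data <- dplyr::arrange(data, .data$individual_id, .data$time_days)
  ids <- unique(data$individual_id)
  lapply(ids, function(id) {
    d <- data[data$individual_id == id, ]
    list(id = id, times = d$time_days, scores = as.integer(d$sidas_total),
         n = nrow(d))
  })
}

#' Fit the hierarchical trajectory model by particle MCMC
#'
#' Runs the correlated pseudo-marginal Metropolis--Hastings-within-Gibbs
#' sampler: per iteration, one CPM-MH update of each individual's
#' random-effect parameters, a semi-conjugate Gibbs update of the population
#' means and SDs, a joint pseudo-marginal MH update of any fixed-effect
#' slots (summing all individuals' filter log-likelihoods), and optionally a
#' pseudo-marginal update of the observation SD. Per-observation predictive
#' log-likelihood increments are stored for every retained draw so WAIC can
#' be computed afterwards. The run is bit-reproducible from
#' `config$seed`.
#'
#' @param data Long observation table with columns `individual_id`,
#'   `time_days`, `sidas_total`. Every individual needs at least two
#'   observations.
#' @param spec A [model_spec()]; default is the Wiener process with random
#'   baseline and diffusion (variant 2).
#' @param obs_cfg An [obs_config()].
#' @param config A [sampler_config()].
#' @param hyper A [hyperpriors()] for `spec`.
#' @return An object of class `ideatraj_fit`; see [tidy.ideatraj_fit()] and
#'   [glance.ideatraj_fit()] for tabular summaries.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n_individuals = 8, seed = 1))
#' fit <- fit_trajectories(cohort$data,
#'                         config = sampler_config(iterations = 200,
#'                                                 burnin = 100,
#'                                                 n_particles = 50))
#' tidy(fit)
#' }
#' @export
fit_trajectories <- function(data, spec = model_spec(variant = 2),
                             obs_cfg = obs_config(),
                             config = sampler_config(),
                             hyper = hyperpriors(spec)) {
  data <- validate_dataset(data, score_max = obs_cfg$score_max)
  inds <- .split_individuals(data)
  few <- vapply(inds, function(z) z$n < 2L, logical(1))
  if (any(few)) {
    stop("individuals with fewer than two observations: ",
         paste(vapply(inds[few], `[[`, "", "id"), collapse = ", "),
         call. = FALSE)
  }
  M <- length(inds)
  set.seed(config$seed)

  r <- which(spec$random)
  f <- which(!spec$random)
  slots <- spec$slots
  ids <- vapply(inds, `[[`, character(1), "id")

  mu <- hyper$mu0[slots[r]]
  tau <- stats::setNames(rep(1, length(r)), slots[r])
  fixed <- hyper$mu0[slots[f]]
  sigma_y <- obs_cfg$sigma_y

  phi0 <- stats::setNames(numeric(length(slots)), slots)
  phi0[r] <- mu
  phi0[f] <- fixed

  cfg_now <- function() {
    if (config$estimate_sigma_y) {
      obs_config(obs_cfg$score_max, sigma_y, obs_cfg$link_scale, obs_cfg$family)
    } else obs_cfg
  }

  states <- lapply(inds, function(z) {
    aux <- make_aux(config$n_particles, z$n)
    res <- particle_filter_loglik(z$times, z$scores, phi0, spec, cfg_now(), aux)
    list(phi = phi0, aux = aux, loglik = res$loglik,
         increments = res$increments)
  })

  degen <- 0L
  degen_total <- 0L
  log_scale <- rep(log(config$proposal_scale), M)
  log_scale_fixed <- log(config$proposal_scale / 2)
  log_scale_sigma <- log(0.2)
  acc <- numeric(M)
  acc_fixed <- 0
  acc_sigma <- 0
  n_keep <- config$iterations - config$burnin
  total_obs <- sum(vapply(inds, `[[`, integer(1), "n"))
  phi_draws <- array(NA_real_, c(n_keep, M, length(slots)),
                     dimnames = list(NULL, ids, slots))
  pop_names <- c(paste0("mu_", slots[r]), paste0("tau_", slots[r]),
                 if (length(f)) paste0("fixed_", slots[f]), "sigma_y")
  pop_draws <- matrix(NA_real_, n_keep, length(pop_names),
                      dimnames = list(NULL, pop_names))
  inc_draws <- matrix(NA_real_, n_keep, total_obs)
  obs_index <- dplyr::arrange(data, .data$individual_id, .data$time_days)

  for (it in seq_len(config$iterations)) {
    oc <- cfg_now()
    gamma <- if (config$adapt && it <= config$burnin) min(0.25, 2 / sqrt(it)) else 0
    for (m in seq_len(M)) {
      z <- inds[[m]]
      states[[m]] <- cpm_mh_individual_step(
        states[[m]], list(mu = mu, tau = tau), spec, oc, z$times, z$scores,
        scales = exp(log_scale[m]), rho = config$rho
      )
      a <- states[[m]]$accepted
      if (it > config$burnin) acc[m] <- acc[m] + a
      log_scale[m] <- log_scale[m] + gamma * (a - config$target_accept)
    }

    phi_mat <- do.call(rbind, lapply(states, `[[`, "phi"))
    colnames(phi_mat) <- slots
    upd <- gibbs_update_population(phi_mat, spec, hyper, tau)
    mu <- upd$mu
    tau <- upd$tau

    if (length(f)) {
      fixed_new <- fixed + exp(log_scale_fixed) * stats::rnorm(length(f))
      cands <- vector("list", M)
      ll_new <- 0
      ll_old <- 0
      for (m in seq_len(M)) {
        z <- inds[[m]]
        phi_new <- states[[m]]$phi
        phi_new[f] <- fixed_new
        aux_new <- refresh_aux(states[[m]]$aux, config$rho,
                               make_aux(config$n_particles, z$n))
        cand <- particle_filter_loglik(z$times, z$scores, phi_new, spec, oc,
                                       aux_new)
        cands[[m]] <- list(phi = phi_new, aux = aux_new, loglik = cand$loglik,
                           increments = cand$increments)
        ll_new <- ll_new + cand$loglik
        ll_old <- ll_old + states[[m]]$loglik
      }
      logr <- ll_new - ll_old +
        sum(stats::dnorm(fixed_new, hyper$mu0[slots[f]], hyper$kappa0[slots[f]],
                         log = TRUE)) -
        sum(stats::dnorm(fixed, hyper$mu0[slots[f]], hyper$kappa0[slots[f]],
                         log = TRUE))
      a <- is.finite(logr) && log(stats::runif(1)) < logr
      if (a) {
        fixed <- fixed_new
        for (m in seq_len(M)) states[[m]][c("phi", "aux", "loglik", "increments")] <- cands[[m]]
      }
      if (it > config$burnin) acc_fixed <- acc_fixed + a
      log_scale_fixed <- log_scale_fixed + gamma * (a - config$target_accept)
    }

    if (config$estimate_sigma_y) {
      lsy_new <- log(sigma_y) + exp(log_scale_sigma) * stats::rnorm(1)
      oc_new <- obs_config(obs_cfg$score_max, exp(lsy_new), obs_cfg$link_scale,
                           obs_cfg$family)
      ll_new <- 0
      ll_old <- 0
      cands <- vector("list", M)
      for (m in seq_len(M)) {
        z <- inds[[m]]
        cand <- particle_filter_loglik(z$times, z$scores, states[[m]]$phi,
                                       spec, oc_new, states[[m]]$aux)
        cands[[m]] <- cand
        ll_new <- ll_new + cand$loglik
        ll_old <- ll_old + states[[m]]$loglik
      }
      logr <- ll_new - ll_old +
        stats::dnorm(lsy_new, 0, 1, log = TRUE) -
        stats::dnorm(log(sigma_y), 0, 1, log = TRUE)
      a <- is.finite(logr) && log(stats::runif(1)) < logr
      if (a) {
        sigma_y <- exp(lsy_new)
        for (m in seq_len(M)) {
          states[[m]]$loglik <- cands[[m]]$loglik
          states[[m]]$increments <- cands[[m]]$increments
        }
      }
      if (it > config$burnin) acc_sigma <- acc_sigma + a
      log_scale_sigma <- log_scale_sigma + gamma * (a - config$target_accept)
    }

    if (it > config$burnin) {
      k <- it - config$burnin
      for (m in seq_len(M)) {
        me <- states[[m]]$min_ess
        if (!is.null(me)) {
          degen_total <- degen_total + 1L
          if (me < 0.1 * config$n_particles) degen <- degen + 1L
        }
      }
      for (m in seq_len(M)) phi_draws[k, m, ] <- states[[m]]$phi
      pop_draws[k, ] <- c(mu, tau, if (length(f)) fixed, sigma_y)
      inc_draws[k, ] <- unlist(lapply(states, `[[`, "increments"),
                               use.names = FALSE)
    }
  }

  structure(
    list(
      phi_draws = phi_draws,
      pop_draws = pop_draws,
      increments = inc_draws,
      obs_index = obs_index,
      acceptance = tibble::tibble(
        individual_id = ids, rate = acc / n_keep,
        proposal_scale = exp(log_scale)
      ),
      degeneracy_rate = if (degen_total > 0) degen / degen_total else NA_real_,
      acceptance_fixed = if (length(f)) acc_fixed / n_keep else NA_real_,
      acceptance_sigma_y = if (config$estimate_sigma_y) acc_sigma / n_keep else NA_real_,
      spec = spec, obs_cfg = obs_cfg, config = config, hyper = hyper
    ),
    class = "ideatraj_fit"
  )
}

#' @export
print.ideatraj_fit <- function(x, ...) {
  cat(sprintf(
    "<ideatraj_fit> %s (variant %s): %d individuals, %d observations, %d draws\n",
    x$spec$model, ifelse(is.na(x$spec$variant), "custom", x$spec$variant),
    dim(x$phi_draws)[2], nrow(x$obs_index), nrow(x$pop_draws)))
  cat(sprintf("  mean individual acceptance rate %.2f\n",
              mean(x$acceptance$rate)))
  if (!is.na(x$degeneracy_rate) && x$degeneracy_rate > 0.05) {
    cat(sprintf(
      "  warning: particle-filter ESS fell below 10%% of particles in %.0f%% of updates\n",
      100 * x$degeneracy_rate))
  }
  invisible(x)
}

#' Maximum a posteriori population-level estimates
#'
#' Marginal posterior modes of the population parameters, taken as the peak
#' of a kernel density estimate over the retained draws (the SD and
#' observation-noise components are kept on their natural positive scale).
#' Used to freeze the population prior when dynamically updating a single
#' individual.
#'
#' @param fit An `ideatraj_fit`.
#' @return A [population_params()] object.
#' @export
map_population <- function(fit) {
  mode1 <- function(v) {
    if (stats::sd(v) < 1e-12) return(v[1])
    d <- stats::density(v)
    d$x[which.max(d$y)]
  }
  est <- apply(fit$pop_draws, 2, mode1)
  spec <- fit$spec
  r <- spec$slots[spec$random]
  f <- spec$slots[!spec$random]
  population_params(
    spec,
    mu = stats::setNames(est[paste0("mu_", r)], r),
    tau = stats::setNames(pmax(est[paste0("tau_", r)], 1e-8), r),
    fixed = stats::setNames(est[paste0("fixed_", f)], f),
    sigma_y = unname(est["sigma_y"])
  )
}
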