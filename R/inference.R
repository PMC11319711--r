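# Bayesian recalibration of the formulation shift delta2 (the multiplicative
# test/reference difference in the slow-depot maximum release rate) jointly
# with all subject-level parameters, by blocked random-walk
# Metropolis-Hastings on the latent log scale.  Population locations,
# variances and the residual variance stay fixed at their configured central
# values; the other five delta components stay at 1.

#' MCMC configuration
#'
#' @param n_chains number of chains (>= 2; convergence diagnostics need at
#'   least two).
#' @param n_iter iterations per chain.
#' @param n_burnin discarded initial iterations (< `n_iter`). Proposal
#'   scales adapt toward 20-40% acceptance during burn-in and are frozen
#'   afterwards.
#' @param scale_subj initial random-walk SD for the 9-dimensional
#'   per-subject blocks (latent log scale).
#' @param scale_delta2 initial random-walk SD for log delta2.
#' @param prior_delta2_gm,prior_delta2_gsd lognormal prior for delta2
#'   (default: geometric mean 1, geometric SD 2, a vague prior spanning
#'   roughly a factor of 8).
#' @param seed optional seed for the whole run.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4, n_iter = 10000, n_burnin = 2500,
                        scale_subj = 0.08, scale_delta2 = 0.1,
                        prior_delta2_gm = 1, prior_delta2_gsd = 2,
                        seed = NULL) {
  if (n_chains < 2) stop("n_chains must be >= 2 (diagnostics require it)")
  if (n_burnin >= n_iter) stop("n_burnin must be smaller than n_iter")
  if (scale_subj <= 0 || scale_delta2 <= 0) {
    stop("proposal scales must be positive")
  }
  assert_scalar_pos(prior_delta2_gm, "prior_delta2_gm")
  if (prior_delta2_gsd <= 1) stop("prior_delta2_gsd must be > 1")
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin),
                 scale_subj = scale_subj, scale_delta2 = scale_delta2,
                 prior_delta2_gm = prior_delta2_gm,
                 prior_delta2_gsd = prior_delta2_gsd, seed = seed),
            class = "mcmc_config")
}

# Per-subject observation lists and arm codes, in sorted subject order.
mcmc_data <- function(dataset) {
  ids <- sort(unique(dataset$subject))
  obs_t <- obs_logc <- vector("list", length(ids))
  arm <- integer(length(ids))
  for (i in seq_along(ids)) {
    idx <- which(dataset$subject == ids[i])
    o <- order(dataset$time[idx])
    obs_t[[i]] <- dataset$time[idx][o]
    obs_logc[[i]] <- log(dataset$conc[idx][o])
    a <- unique(dataset$arm[idx])
    if (length(a) != 1) stop("subject assigned to more than one arm")
    arm[i] <- if (a == "test") 1L else 0L
  }
  list(ids = ids, obs_t = obs_t, obs_logc = obs_logc, arm = arm)
}

# Reference-arm latent locations with all delta fixed at 1 (inference
# estimates delta2 only; the other components stay at 1 by construction).
inference_locations <- function(pop) {
  pop_null <- pop
  pop_null$delta <- setNames(rep(1, 6), DELTA_NAMES)
  shifted_locations(pop_null, "reference")
}

#' Joint log-posterior of delta2 and the subject parameters
#'
#' Sum of (i) lognormal measurement log-densities of the observed
#' concentrations around the model-predicted profiles (log-variance
#' `pop$sigma2_resid`, fixed), (ii) the population log-densities of the
#' subject latent parameters around the fixed locations (the test-arm
#' kas3_max location shifted by delta2), and (iii) the lognormal delta2
#' prior.  Returns `-Inf` for out-of-domain states.
#'
#' @param delta2 positive shift on the slow-depot maximum release rate.
#' @param subject_latents matrix (subjects x 9) of latent log-scale values,
#'   columns `kappa_f1`, `kappa_f3`, `ka1`, `kar3_50`, `kas3_max`,
#'   `kas3_50`, `CL`, `V`, `Qc0`; rows in sorted subject-id order.
#' @param dataset a `concentration_dataset`.
#' @param pop a [population_params()].
#' @param regimen dosing regimen (defaults to the dataset design's).
#' @param prior_delta2_gm,prior_delta2_gsd delta2 prior.
#' @param components if `TRUE` return the likelihood/prior decomposition.
#' @param rtol,atol solver tolerances used inside the likelihood (the
#'   sampler's defaults trade a ~1e-5 relative solution error, negligible
#'   against the residual SD, for speed).
#' @return The scalar log-posterior, or a list of components.
#' @export
log_posterior <- function(delta2, subject_latents, dataset, pop,
                          regimen = NULL, prior_delta2_gm = 1,
                          prior_delta2_gsd = 2, components = FALSE,
                          rtol = 1e-5, atol = 1e-7) {
  regimen <- regimen %||% attr(dataset, "design")$regimen %||% pp_regimen()
  md <- mcmc_data(dataset)
  if (nrow(subject_latents) != length(md$ids)) {
    stop("subject_latents must have one row per subject in the dataset")
  }
  loc <- inference_locations(pop)
  res <- .log_posterior_cpp(
    delta2, as.matrix(subject_latents[, LATENT_NAMES, drop = FALSE]),
    md$arm, md$obs_t, md$obs_logc, regimen_events_matrix(regimen),
    loc$tl1, loc$kar3_max, loc$gamma,
    if (pop$transform == "paper_logistic") 0L else 1L,
    unname(loc$meanlog), unname(loc$sdlog), sqrt(pop$sigma2_resid),
    log(prior_delta2_gm), log(prior_delta2_gsd), rtol, atol)
  if (components) res else res$total
}

#' Recalibrate delta2 from abbreviated-trial data by MCMC
#'
#' Blocked random-walk Metropolis-Hastings: each subject's nine latent
#' parameters are proposed jointly (one ODE solve per proposal); delta2 has
#' its own block, which touches only the test-arm population terms and the
#' prior.  Proposal scales adapt during burn-in and are then frozen, so the
#' retained draws target the exact posterior.
#'
#' @param config an [mcmc_config()].
#' @param dataset a `concentration_dataset` from an abbreviated trial.
#' @param pop a [population_params()]; its locations, variances and
#'   residual variance are held fixed.
#' @param regimen dosing regimen (defaults to the dataset design's).
#' @param sample_subjects if `FALSE`, hold the subject latent parameters
#'   fixed at `init_latents` and sample only delta2 (used for reduced
#'   conjugate checks and sensitivity runs).
#' @param init_latents optional matrix (subjects x 9) of latent log-scale
#'   starting values; defaults to the population locations.
#' @param rtol,atol solver tolerances for likelihood evaluations.
#' @return An object of class `mcmc_result`: per-chain draw matrices
#'   (column 1 = `delta2` on the natural scale, remaining columns latent
#'   log-scale subject parameters), acceptance rates, Gelman-Rubin `rhat`
#'   per parameter, and the delta2 posterior summary.
#' @export
run_mcmc <- function(config, dataset, pop, regimen = NULL,
                     sample_subjects = TRUE, init_latents = NULL,
                     rtol = 1e-5, atol = 1e-7) {
  stopifnot(inherits(config, "mcmc_config"),
            inherits(pop, "population_params"))
  regimen <- regimen %||% attr(dataset, "design")$regimen %||% pp_regimen()
  md <- mcmc_data(dataset)
  loc <- inference_locations(pop)
  n_subj <- length(md$ids)
  if (is.null(init_latents)) {
    init_latents <- matrix(rep(unname(loc$meanlog), each = n_subj),
                           nrow = n_subj,
                           dimnames = list(NULL, LATENT_NAMES))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  raw <- .run_mcmc_cpp(
    md$obs_t, md$obs_logc, md$arm, regimen_events_matrix(regimen),
    loc$tl1, loc$kar3_max, loc$gamma,
    if (pop$transform == "paper_logistic") 0L else 1L,
    unname(loc$meanlog), unname(loc$sdlog), sqrt(pop$sigma2_resid),
    log(config$prior_delta2_gm), log(config$prior_delta2_gsd),
    config$n_chains, config$n_iter, config$n_burnin, sample_subjects,
    as.matrix(init_latents[, LATENT_NAMES, drop = FALSE]),
    config$scale_subj, config$scale_delta2, rtol, atol)
  par_names <- c("delta2",
                 as.vector(t(outer(md$ids, LATENT_NAMES, paste, sep = "."))))
  chains <- lapply(raw$chains, function(m) {
    colnames(m) <- par_names
    m
  })
  rhat <- if (sample_subjects) gelman_rubin(chains) else
    gelman_rubin(lapply(chains, function(m) m[, 1, drop = FALSE]))
  res <- list(chains = chains,
              accept_delta2 = as.numeric(raw$accept_delta2),
              accept_subjects = as.numeric(raw$accept_subjects),
              rhat = rhat,
              delta2 = NULL,
              config = config, subjects = md$ids)
  d2 <- unlist(lapply(chains, function(m) m[, "delta2"]))
  if (length(d2) >= 100) res$delta2 <- posterior_summary(d2)
  class(res) <- "mcmc_result"
  res
}

#' @export
print.mcmc_result <- function(x, ...) {
  nk <- nrow(x$chains[[1]])
  cat(sprintf("MCMC result: %d chains x %d retained draws, %d parameters\n",
              length(x$chains), nk, ncol(x$chains[[1]])))
  cat(sprintf("  delta2: GM %.3f, GSD %.3f, 95%% CrI [%.3f, %.3f]\n",
              x$delta2$gm, x$delta2$gsd, x$delta2$cri[1], x$delta2$cri[2]))
  cat(sprintf("  acceptance: delta2 %.2f, subject blocks %.2f\n",
              mean(x$accept_delta2), mean(x$accept_subjects)))
  cat(sprintf("  max Rhat: %.4f\n", max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Pooled delta2 draws of an MCMC result
#'
#' @param result an `mcmc_result`.
#' @return All post-burn-in delta2 draws across chains.
#' @export
delta2_draws <- function(result) {
  unlist(lapply(result$chains, function(m) m[, "delta2"]))
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Between/within-chain variance diagnostic; values near 1 indicate
#' convergence.
#'
#' @param chains list of draw matrices (equal dimensions, one per chain) or
#'   of numeric vectors.
#' @return Named vector of R-hat values; `NA` where the within-chain
#'   variance is zero (flagged undefined).
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2) {
    stop("Gelman-Rubin diagnostics require >= 2 chains")
  }
  chains <- lapply(chains, function(x) {
    if (is.null(dim(x))) matrix(x, ncol = 1) else as.matrix(x)
  })
  n <- unique(vapply(chains, nrow, integer(1)))
  if (length(n) != 1) stop("chains must have equal lengths")
  if (n < 10) stop("chains must have length >= 10")
  m <- length(chains)
  p <- ncol(chains[[1]])
  out <- numeric(p)
  for (j in seq_len(p)) {
    draws <- vapply(chains, function(ch) ch[, j], numeric(n))
    means <- colMeans(draws)
    W <- mean(apply(draws, 2, var))
    B <- n * var(means)
    if (W == 0) {
      out[j] <- NA_real_
    } else {
      vhat <- (n - 1) / n * W + B / n
      out[j] <- sqrt(vhat / W)
    }
  }
  names(out) <- colnames(chains[[1]])
  out
}

#' Posterior summary on the geometric scale
#'
#' @param draws positive posterior draws (>= 100).
#' @return List with `gm` (geometric mean), `gsd` (geometric SD), and
#'   `cri`, the equal-tailed 95% credibility interval from the empirical
#'   2.5% and 97.5% quantiles (default quantile interpolation, type 7).
#' @export
posterior_summary <- function(draws) {
  if (length(draws) < 100) stop("posterior summary requires >= 100 draws")
  if (any(draws <= 0)) stop("draws must be positive")
  ld <- log(draws)
  list(gm = exp(mean(ld)), gsd = exp(sd(ld)),
       cri = unname(quantile(draws, c(0.025, 0.975))))
}
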