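# Bioequivalence decision machinery.
#
# Workflow A is data-based: NCA metrics from one simulated trial, assessed
# by two one-sided tests (TOST) on the log scale; BE is declared only if
# both Cmax and AUC pass.  Workflow B is model-integrated: the posterior
# predictive distribution of the Cmax and AUC geometric-mean ratios over
# many large noise-free trials, with a probabilistic decision rule
# P(both ratios in limits) >= threshold.

#' Two one-sided tests (TOST) for average bioequivalence
#'
#' Parallel-design TOST on log-scale metrics: the equivalence claim is
#' accepted when the two-sided 100(1 - 2 alpha)% confidence interval for
#' the test/reference ratio of geometric means lies inside the limits.
#' Pooled-variance two-sample t by default; Welch optional.
#'
#' @param log_test,log_ref log exposure metrics per subject in each arm.
#' @param alpha one-sided level (default 0.05, i.e. a 90% CI).
#' @param limits equivalence limits on the ratio scale.
#' @param var_equal pooled variance (classical parallel BE) if `TRUE`,
#'   Welch otherwise.
#' @return List of class `tost_result`: `gmr`, `ci` (ratio scale), `pass`,
#'   `alpha`, `limits`, `df`, `se_log`.
#' @export
tost <- function(log_test, log_ref, alpha = 0.05, limits = c(0.8, 1.25),
                 var_equal = TRUE) {
  n1 <- length(log_test); n2 <- length(log_ref)
  if (n1 < 2 || n2 < 2) stop("each arm needs at least 2 subjects")
  if (any(!is.finite(log_test)) || any(!is.finite(log_ref))) {
    stop("log metrics must be finite")
  }
  v1 <- var(log_test); v2 <- var(log_ref)
  if (v1 == 0 && v2 == 0) stop("degenerate variance: both arms constant")
  diff <- mean(log_test) - mean(log_ref)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  half <- qt(1 - alpha, df) * se
  ci <- exp(c(diff - half, diff + half))
  res <- list(gmr = exp(diff), ci = ci,
              pass = ci[1] >= limits[1] && ci[2] <= limits[2],
              alpha = alpha, limits = limits, df = df, se_log = se)
  class(res) <- "tost_result"
  res
}

#' @export
print.tost_result <- function(x, ...) {
  cat(sprintf("TOST: GMR %.4f, %d%% CI [%.4f, %.4f], limits [%g, %g] -> %s\n",
              x$gmr, round(100 * (1 - 2 * x$alpha)), x$ci[1], x$ci[2],
              x$limits[1], x$limits[2], if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Workflow A: data-based BE decision on a simulated trial
#'
#' NCA Cmax and partial AUC per subject over the analysis interval,
#' followed by a TOST on each metric; overall BE requires both to pass.
#'
#' @param dataset a `concentration_dataset` with both arms.
#' @param interval analysis interval (defaults to the design's).
#' @param alpha,limits,var_equal passed to [tost()].
#' @return List of class `be_decision_A` with elements `cmax` and `auc`
#'   ([tost()] results), `pass`, and the trial summary.
#' @export
be_workflow_A <- function(dataset, interval = NULL, alpha = 0.05,
                          limits = c(0.8, 1.25), var_equal = TRUE) {
  metrics <- nca_by_subject(dataset, interval)
  arms <- split(metrics, metrics$arm)
  if (!all(c("reference", "test") %in% names(arms))) {
    stop("workflow A needs both a reference and a test arm")
  }
  res <- lapply(c(cmax = "cmax", auc = "auc"), function(m) {
    tost(log(arms$test[[m]]), log(arms$reference[[m]]), alpha = alpha,
         limits = limits, var_equal = var_equal)
  })
  out <- list(cmax = res$cmax, auc = res$auc,
              pass = res$cmax$pass && res$auc$pass,
              summary = summarize_trial(metrics), workflow = "A")
  class(out) <- "be_decision_A"
  out
}

#' @export
print.be_decision_A <- function(x, ...) {
  cat("Workflow A (data-based TOST) BE decision\n")
  cat("  Cmax: "); print(x$cmax)
  cat("  AUC : "); print(x$auc)
  cat(sprintf("  overall: %s\n", if (x$pass) "bioequivalent"
              else "not bioequivalent"))
  invisible(x)
}

# Noise-free model-integrated exposures of n sampled subjects.
population_exposures <- function(pop, n, arm, regimen, interval,
                                 n_grid = 100) {
  subj <- sample_subjects(pop, n, arm)
  grid <- seq(interval[1], interval[2], length.out = n_grid)
  ex <- .pk_exposure_batch_cpp(as.matrix(subj),
                               regimen_events_matrix(regimen), grid)
  data.frame(cmax = ex[, 1], auc = ex[, 2])
}

#' Workflow B: posterior predictive distribution of exposure ratios
#'
#' For each simulated trial a delta2 value is drawn from the posterior
#' (either a sample of draws or a lognormal geometric-mean/geometric-SD
#' summary), both arms are simulated without measurement noise, and the
#' test/reference ratios of the arm geometric means of model-integrated
#' Cmax and partial AUC are recorded.
#'
#' @param delta2_posterior numeric vector of posterior draws, a
#'   `list(gm =, gsd =)` lognormal summary, or a single number (point
#'   mass).
#' @param pop a [population_params()]; its other delta components are kept.
#' @param n_trials number of simulated trials.
#' @param n_per_arm subjects per arm per trial (>= 2).
#' @param regimen dosing regimen (default [pp_regimen()]).
#' @param interval model-integrated analysis interval; defaults to the
#'   last dosing period of the regimen.
#' @param n_grid Cmax search grid size.
#' @return Data frame of class `ratio_samples` with columns `delta2`,
#'   `d_cmax`, `d_auc`, one row per trial.
#' @export
posterior_predictive_ratios <- function(delta2_posterior, pop,
                                        n_trials = 1000, n_per_arm = 1000,
                                        regimen = pp_regimen(),
                                        interval = NULL, n_grid = 100) {
  if (n_trials < 1 || n_per_arm < 2) {
    stop("need n_trials >= 1 and n_per_arm >= 2")
  }
  interval <- interval %||% last_dosing_period(regimen)
  draw_delta2 <- if (is.numeric(delta2_posterior)) {
    if (any(delta2_posterior <= 0)) stop("invalid posterior: delta2 <= 0")
    if (length(delta2_posterior) == 1) {
      function() delta2_posterior
    } else {
      function() sample(delta2_posterior, 1)
    }
  } else if (is.list(delta2_posterior) &&
             all(c("gm", "gsd") %in% names(delta2_posterior))) {
    if (delta2_posterior$gm <= 0 || delta2_posterior$gsd < 1) {
      stop("invalid posterior summary")
    }
    function() rlnorm(1, log(delta2_posterior$gm),
                      log(delta2_posterior$gsd))
  } else {
    stop("delta2_posterior must be draws, a point value, or list(gm, gsd)")
  }
  d2 <- d_cmax <- d_auc <- numeric(n_trials)
  for (k in seq_len(n_trials)) {
    d2[k] <- draw_delta2()
    pop_k <- pop
    pop_k$delta["kas3_max"] <- d2[k]
    ref <- population_exposures(pop_k, n_per_arm, "reference", regimen,
                                interval, n_grid)
    tst <- population_exposures(pop_k, n_per_arm, "test", regimen,
                                interval, n_grid)
    d_cmax[k] <- geomean(tst$cmax) / geomean(ref$cmax)
    d_auc[k] <- geomean(tst$auc) / geomean(ref$auc)
  }
  out <- data.frame(delta2 = d2, d_cmax = d_cmax, d_auc = d_auc)
  class(out) <- c("ratio_samples", "data.frame")
  attr(out, "provenance") <- list(n_trials = n_trials,
                                  n_per_arm = n_per_arm)
  out
}

#' Workflow B: probabilistic BE decision
#'
#' @param ratios a `ratio_samples` data frame (>= 100 rows).
#' @param threshold declare BE when P(both ratios in limits) is at least
#'   this value (default 0.95).
#' @param limits equivalence limits.
#' @return List of class `be_decision_B`: `p_be`, per-tail exceedance
#'   probabilities, `pass`, `threshold`, `limits`.
#' @export
be_workflow_B <- function(ratios, threshold = 0.95, limits = c(0.8, 1.25)) {
  if (nrow(ratios) < 100) stop("workflow B needs >= 100 ratio draws")
  inside <- ratios$d_cmax >= limits[1] & ratios$d_cmax <= limits[2] &
    ratios$d_auc >= limits[1] & ratios$d_auc <= limits[2]
  out <- list(p_be = mean(inside),
              p_cmax_above = mean(ratios$d_cmax > limits[2]),
              p_cmax_below = mean(ratios$d_cmax < limits[1]),
              p_auc_above = mean(ratios$d_auc > limits[2]),
              p_auc_below = mean(ratios$d_auc < limits[1]),
              pass = mean(inside) >= threshold,
              threshold = threshold, limits = limits, workflow = "B")
  class(out) <- "be_decision_B"
  out
}

#' @export
print.be_decision_B <- function(x, ...) {
  cat("Workflow B (posterior predictive) BE decision\n")
  cat(sprintf("  P(both ratios in [%g, %g]) = %.3f (threshold %.2f)\n",
              x$limits[1], x$limits[2], x$p_be, x$threshold))
  cat(sprintf("  P(dCmax > %g) = %.3f, P(dAUC > %g) = %.3f\n",
              x$limits[2], x$p_cmax_above, x$limits[2], x$p_auc_above))
  cat(sprintf("  overall: %s\n", if (x$pass) "bioequivalent"
              else "not bioequivalent"))
  invisible(x)
}

#' Power and type-I error of the data-based workflow
#'
#' Repeats trial simulation plus the workflow-A TOST decision and reports
#' the fraction of trials declaring BE with its binomial Monte-Carlo SE.
#' Boundary placements multiply the test-arm concentrations by the limit so
#' the true geometric-mean ratio of every exposure metric sits exactly on
#' it (a pure multiplicative shift; the null delta is used otherwise).
#'
#' @param design a [trial_design()].
#' @param pop a [population_params()].
#' @param placement `"null"` (delta = 1), `"boundary_upper"` (true GMR =
#'   upper limit), `"boundary_lower"`, `"gmr"` (true GMR = `true_gmr`), or
#'   `"custom"` (use `delta`).
#' @param delta custom shift vector for `placement = "custom"`.
#' @param true_gmr target true geometric-mean ratio for `placement = "gmr"`.
#' @param n_reps number of simulated trials (>= 20).
#' @param alpha,limits,var_equal passed to [tost()].
#' @return List: `pass_fraction`, `mc_se`, `n_reps`, `placement`, and the
#'   per-trial verdicts.
#' @export
power_type1 <- function(design, pop,
                        placement = c("null", "boundary_upper",
                                      "boundary_lower", "gmr", "custom"),
                        delta = NULL, true_gmr = NULL, n_reps = 100,
                        alpha = 0.05, limits = c(0.8, 1.25),
                        var_equal = TRUE) {
  placement <- match.arg(placement)
  if (n_reps < 20) stop("n_reps must be >= 20")
  pop_run <- pop
  mult <- 1
  if (placement == "custom") {
    if (is.null(delta)) stop("placement = 'custom' requires delta")
    pop_run$delta <- setNames(rep_len(delta, 6), DELTA_NAMES)
  } else {
    pop_run$delta <- setNames(rep(1, 6), DELTA_NAMES)
    mult <- switch(placement, null = 1, boundary_upper = limits[2],
                   boundary_lower = limits[1],
                   gmr = true_gmr %||% stop("placement = 'gmr' requires true_gmr"))
  }
  if (!is.null(design$seed)) set.seed(design$seed)
  inner <- design
  inner$seed <- NULL
  pass <- logical(n_reps)
  for (k in seq_len(n_reps)) {
    ds <- simulate_trial(inner, pop_run)
    if (mult != 1) ds$conc[ds$arm == "test"] <- ds$conc[ds$arm == "test"] * mult
    pass[k] <- be_workflow_A(ds, alpha = alpha, limits = limits,
                             var_equal = var_equal)$pass
  }
  pf <- mean(pass)
  list(pass_fraction = pf, mc_se = sqrt(pf * (1 - pf) / n_reps),
       n_reps = n_reps, placement = placement, pass = pass)
}

#' Local sensitivity ranking of the drug-release parameters
#'
#' Perturbs each component of the shift vector delta (order: f3, kas3_max,
#' kar3_max, kas3_50, kar3_50, gamma) by a small relative amount on the
#' reference population mean subject and reports the relative change in
#' model-integrated Cmax and partial AUC, ranked by impact.
#'
#' @param pop a [population_params()].
#' @param regimen dosing regimen.
#' @param interval analysis interval; defaults to the last dosing period.
#' @param perturbation relative perturbation (default 0.05 = 5%).
#' @return Data frame (one row per delta component, ranked): `parameter`,
#'   `pct_cmax`, `pct_auc`, `rank`.
#' @export
sensitivity_ranking <- function(pop, regimen = pp_regimen(),
                                interval = NULL, perturbation = 0.05) {
  if (perturbation <= 0) stop("perturbation must be positive")
  interval <- interval %||% last_dosing_period(regimen)
  mean_subject <- function(pop_x) {
    loc <- shifted_locations(pop_x, "test")
    latent_to_subject(loc$meanlog, loc, pop_x$transform)
  }
  pop0 <- pop
  pop0$delta <- setNames(rep(1, 6), DELTA_NAMES)
  base <- exposure_model_integrated(mean_subject(pop0), regimen, interval)
  rows <- lapply(seq_along(DELTA_NAMES), function(i) {
    pop_i <- pop0
    pop_i$delta[i] <- 1 + perturbation
    m <- exposure_model_integrated(mean_subject(pop_i), regimen, interval)
    data.frame(parameter = DELTA_NAMES[i],
               pct_cmax = 100 * (m$cmax / base$cmax - 1),
               pct_auc = 100 * (m$auc / base$auc - 1))
  })
  out <- do.call(rbind, rows)
  impact <- pmax(abs(out$pct_cmax), abs(out$pct_auc))
  out <- out[order(-impact), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Workflow A safe space: fuzzy map under random formulation shifts
#'
#' Samples every component of delta uniformly, simulates a full trial per
#' draw, and records the workflow-A TOST verdict and realized GMRs.
#'
#' @param pop a [population_params()].
#' @param design a [trial_design()] (130 subjects/arm by default in the
#'   published setting; configurable).
#' @param n_trials number of sampled delta points (>= 10).
#' @param delta_low,delta_high uniform sampling bounds for each component.
#' @param alpha,limits passed to [tost()].
#' @return Data frame of class `safe_space_map` (mode `"A_fuzzy"`): the six
#'   delta components, `gmr_cmax`, `gmr_auc`, `pass`.
#' @export
safe_space_A <- function(pop, design, n_trials = 1000, delta_low = 0.5,
                         delta_high = 2, alpha = 0.05,
                         limits = c(0.8, 1.25)) {
  if (n_trials < 10) stop("n_trials must be >= 10")
  if (!is.null(design$seed)) set.seed(design$seed)
  inner <- design
  inner$seed <- NULL
  rows <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    delta <- runif(6, delta_low, delta_high)
    pop_k <- pop
    pop_k$delta <- setNames(delta, DELTA_NAMES)
    row <- tryCatch({
      ds <- simulate_trial(inner, pop_k)
      dec <- be_workflow_A(ds, alpha = alpha, limits = limits)
      data.frame(t(setNames(delta, paste0("delta_", DELTA_NAMES))),
                 gmr_cmax = dec$cmax$gmr, gmr_auc = dec$auc$gmr,
                 pass = dec$pass)
    }, error = function(e) {
      warning(sprintf("safe-space point %d failed: %s", k,
                      conditionMessage(e)))
      NULL
    })
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("safe_space_map", "data.frame")
  attr(out, "mode") <- "A_fuzzy"
  out
}

#' Workflow B safe space: crisp map on a (delta1, delta2) grid
#'
#' At each grid point delta is fixed (no posterior uncertainty); the Cmax
#' and AUC ratios are averaged over `n_trials` noise-free trials and the
#' point is in the safe space when both averaged ratios lie inside the
#' limits.  A probabilistic rule (P(both in limits) >= threshold across
#' trials) is available for boundary-uncertainty studies.
#'
#' @param pop a [population_params()].
#' @param delta1,delta2 grid values for the f3 and kas3_max shifts.
#' @param n_trials trials per grid point.
#' @param n_per_arm subjects per arm per trial.
#' @param regimen,interval,n_grid as in [posterior_predictive_ratios()].
#' @param rule `"mean"` (average ratio in limits) or `"probability"`.
#' @param threshold probability threshold for `rule = "probability"`.
#' @param limits equivalence limits.
#' @return Data frame of class `safe_space_map` (mode `"B_crisp"`):
#'   `delta1`, `delta2`, mean ratios `d_cmax`, `d_auc`, `pass`.
#' @export
safe_space_B <- function(pop, delta1, delta2, n_trials = 50,
                         n_per_arm = 200, regimen = pp_regimen(),
                         interval = NULL, n_grid = 100,
                         rule = c("mean", "probability"), threshold = 0.95,
                         limits = c(0.8, 1.25)) {
  rule <- match.arg(rule)
  grid <- expand.grid(delta1 = delta1, delta2 = delta2)
  if (nrow(grid) == 0) stop("empty grid")
  interval <- interval %||% last_dosing_period(regimen)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pop_g <- pop
    pop_g$delta <- setNames(c(grid$delta1[g], 1, 1, 1, 1, 1), DELTA_NAMES)
    rows[[g]] <- tryCatch({
      # the grid's delta2 enters as a point-mass posterior draw
      ratios <- posterior_predictive_ratios(grid$delta2[g], pop_g,
                                            n_trials = n_trials,
                                            n_per_arm = n_per_arm,
                                            regimen = regimen,
                                            interval = interval,
                                            n_grid = n_grid)
      mc <- geomean(ratios$d_cmax); ma <- geomean(ratios$d_auc)
      pass <- if (rule == "mean") {
        mc >= limits[1] && mc <= limits[2] &&
          ma >= limits[1] && ma <= limits[2]
      } else {
        inside <- ratios$d_cmax >= limits[1] & ratios$d_cmax <= limits[2] &
          ratios$d_auc >= limits[1] & ratios$d_auc <= limits[2]
        mean(inside) >= threshold
      }
      data.frame(delta1 = grid$delta1[g], delta2 = grid$delta2[g],
                 d_cmax = mc, d_auc = ma, pass = pass)
    }, error = function(e) {
      warning(sprintf("grid point (%g, %g) failed: %s", grid$delta1[g],
                      grid$delta2[g], conditionMessage(e)))
      NULL
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("safe_space_map", "data.frame")
  attr(out, "mode") <- "B_crisp"
  out
}

#' Bisection refinement of the crisp safe-space boundary in delta2
#'
#' At a fixed delta1, brackets the delta2 value where the workflow-B mean
#' ratios leave the limits and refines it by bisection.
#'
#' @param pop a [population_params()].
#' @param delta1 fixed f3 shift.
#' @param lower,upper delta2 bracket; the decision must differ at the ends.
#' @param tol bisection tolerance in delta space.
#' @param ... passed to [safe_space_B()].
#' @return The boundary delta2 estimate.
#' @export
safe_space_boundary_B <- function(pop, delta1, lower, upper, tol = 0.01,
                                  ...) {
  eval_pass <- function(d2) {
    safe_space_B(pop, delta1 = delta1, delta2 = d2, ...)$pass[1]
  }
  lo <- lower; hi <- upper
  p_lo <- eval_pass(lo); p_hi <- eval_pass(hi)
  if (p_lo == p_hi) stop("bracket does not straddle the boundary")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (eval_pass(mid) == p_lo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
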