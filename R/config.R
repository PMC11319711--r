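# Configuration and command-layer orchestration: YAML run configurations,
# deterministic seeding, provenance manifests, and the vbe_cmd_* stage
# functions that the inst/cli/vbe.R front-end dispatches to.

#' Default run configuration
#'
#' A complete configuration for the paliperidone palmitate case study:
#' population profile, trial design blocks (abbreviated, large,
#' safe-space), MCMC block, decision block, and master seed.  The
#' population values are the documented placeholder profile of
#' [default_population()].
#'
#' @param seed master seed.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 1) {
  pop <- default_population()
  cfg <- list(
    profile = "paliperidone_pp3m_placeholder",
    population = list(
      mu = as.list(pop$mu),
      sigma2 = as.list(pop$sigma2),
      shared = pop$shared,
      qc0_gm = pop$qc0_gm, qc0_gsd = pop$qc0_gsd,
      sigma2_resid = pop$sigma2_resid,
      delta = as.list(pop$delta),
      transform = pop$transform),
    designs = list(
      abbreviated = list(n_per_arm = 25, schedule = "weeks_54_63"),
      large = list(n_per_arm = 130, schedule = "weeks_54_63"),
      safe_space = list(n_per_arm = 130, n_trials = 1000,
                        delta_low = 0.5, delta_high = 2)),
    mcmc = list(n_chains = 4, n_iter = 10000, n_burnin = 2500,
                scale_subj = 0.08, scale_delta2 = 0.1,
                prior_delta2_gm = 1, prior_delta2_gsd = 2),
    decision = list(limits = c(0.8, 1.25), threshold = 0.95, alpha = 0.05),
    seed = as.integer(seed))
  class(cfg) <- c("run_config", "list")
  cfg
}

validate_run_config <- function(cfg) {
  lim <- unlist(cfg$decision$limits)
  if (length(lim) != 2 || !(lim[1] < 1 && 1 < lim[2])) {
    stop("configuration error: decision.limits must straddle 1")
  }
  thr <- cfg$decision$threshold
  if (is.null(thr) || thr <= 0 || thr >= 1) {
    stop("configuration error: decision.threshold must lie in (0, 1)")
  }
  if (is.null(cfg$seed)) stop("configuration error: missing key 'seed'")
  invisible(cfg)
}

#' Read and write run configurations (YAML)
#'
#' @param path YAML file path.
#' @param config a `run_config` list.
#' @return `read_run_config()` returns a validated `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- c("run_config", "list")
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build the population from a configuration
#'
#' @param config a `run_config`.
#' @return A [population_params()].
#' @export
config_population <- function(config) {
  p <- config$population
  if (is.null(p)) stop("configuration error: missing key 'population'")
  population_params(mu = p$mu, sigma2 = unlist(p$sigma2), shared = p$shared,
                    qc0_gm = p$qc0_gm, qc0_gsd = p$qc0_gsd,
                    sigma2_resid = p$sigma2_resid,
                    delta = unlist(p$delta),
                    transform = p$transform %||% "odds_ratio")
}

#' Build a trial design from a configuration block
#'
#' @param config a `run_config`.
#' @param name design block name (`"abbreviated"`, `"large"`, ...).
#' @return A [trial_design()] seeded deterministically from the master
#'   seed and the block name.
#' @export
config_design <- function(config, name) {
  blk <- config$designs[[name]]
  if (is.null(blk)) {
    stop(sprintf("configuration error: missing design profile '%s'", name))
  }
  sched <- sampling_schedule(blk$schedule %||% "weeks_54_63")
  trial_design(n_per_arm = blk$n_per_arm %||% 25,
               regimen = pp_regimen(),
               sampling_times = sched,
               seed = derive_seed(config$seed, nchar(name),
                                  utf8ToInt(substr(name, 1, 1))))
}

# FNV-1a hash of the YAML serialization; provenance fingerprint only.
config_hash <- function(config) {
  bytes <- utf8ToInt(yaml::as.yaml(unclass(config)))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

write_manifest <- function(config, stage, out_dir, files) {
  manifest <- list(stage = stage, seed = config$seed,
                   config_hash = config_hash(config),
                   package_version = as.character(
                     utils::packageVersion("vbesim")),
                   files = files)
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

say <- function(quiet, ...) if (!quiet) message(sprintf(...))

#' Stage commands
#'
#' Thin orchestration layer over the package's functions, used by the
#' command-line front-end (`inst/cli/vbe.R`): each command runs one stage,
#' writes CSV/JSON results into `out_dir`, and drops a provenance manifest
#' (seed, configuration hash).
#'
#' @param config a `run_config`.
#' @param design name of the design block to simulate.
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return Invisibly, the paths of the written files.
#' @export
vbe_cmd_simulate <- function(config, design = "abbreviated",
                             out_dir = ".", quiet = FALSE) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- config_population(config)
  des <- config_design(config, design)
  say(quiet, "simulating '%s' trial: %d subjects/arm", design, des$n_per_arm)
  ds <- simulate_trial(des, pop)
  data_path <- file.path(out_dir, paste0(design, "_trial.csv"))
  params_path <- file.path(out_dir, paste0(design, "_true_params.csv"))
  write_concentration_dataset(ds, data_path, params_path)
  man <- write_manifest(config, paste0("simulate_", design), out_dir,
                        c(data_path, params_path))
  invisible(c(data_path, params_path, man))
}

#' @rdname vbe_cmd_simulate
#' @param dataset_path CSV written by [vbe_cmd_simulate()].
#' @export
vbe_cmd_recalibrate <- function(config, dataset_path, out_dir = ".",
                                quiet = FALSE) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- read_concentration_dataset(dataset_path)
  m <- config$mcmc
  cfg <- mcmc_config(n_chains = m$n_chains, n_iter = m$n_iter,
                     n_burnin = m$n_burnin,
                     scale_subj = m$scale_subj %||% 0.08,
                     scale_delta2 = m$scale_delta2 %||% 0.1,
                     prior_delta2_gm = m$prior_delta2_gm %||% 1,
                     prior_delta2_gsd = m$prior_delta2_gsd %||% 2,
                     seed = derive_seed(config$seed, 2))
  say(quiet, "recalibrating delta2: %d chains x %d iterations",
      cfg$n_chains, cfg$n_iter)
  pop <- config_population(config)
  fit <- run_mcmc(cfg, ds, pop)
  chain_paths <- character(length(fit$chains))
  for (c in seq_along(fit$chains)) {
    chain_paths[c] <- file.path(out_dir, sprintf("chain_%d.csv", c))
    write.csv(as.data.frame(fit$chains[[c]]), chain_paths[c],
              row.names = FALSE)
  }
  summary_path <- file.path(out_dir, "recalibration_summary.json")
  jsonlite::write_json(
    list(delta2 = list(gm = fit$delta2$gm, gsd = fit$delta2$gsd,
                       cri = fit$delta2$cri),
         rhat_max = max(fit$rhat, na.rm = TRUE),
         rhat_delta2 = unname(fit$rhat["delta2"]),
         converged = max(fit$rhat, na.rm = TRUE) < 1.1,
         accept_delta2 = fit$accept_delta2,
         accept_subjects = fit$accept_subjects),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  man <- write_manifest(config, "recalibrate", out_dir,
                        c(chain_paths, summary_path))
  invisible(c(chain_paths, summary_path, man))
}

#' @rdname vbe_cmd_simulate
#' @param mode `"A"` (data-based TOST on a dataset) or `"B"` (posterior
#'   predictive decision from a recalibration summary).
#' @param input for mode A a dataset CSV; for mode B a recalibration
#'   summary JSON (or chain CSVs' directory).
#' @param n_trials,n_per_arm workflow-B Monte-Carlo size.
#' @export
vbe_cmd_assess <- function(config, mode = c("A", "B"), input, out_dir = ".",
                           n_trials = 200, n_per_arm = 200, quiet = FALSE) {
  mode <- match.arg(mode)
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lim <- unlist(config$decision$limits)
  alpha <- config$decision$alpha %||% 0.05
  pop <- config_population(config)
  if (mode == "A") {
    if (missing(input) || !file.exists(input)) {
      stop("mode A requires a dataset CSV")
    }
    ds <- read_concentration_dataset(input)
    dec <- be_workflow_A(ds, alpha = alpha, limits = lim)
    out <- list(workflow = "A", pass = dec$pass,
                limits = lim, alpha = alpha,
                cmax = list(gmr = dec$cmax$gmr, ci = dec$cmax$ci,
                            pass = dec$cmax$pass),
                auc = list(gmr = dec$auc$gmr, ci = dec$auc$ci,
                           pass = dec$auc$pass))
  } else {
    if (missing(input)) stop("mode B requires a posterior input")
    post <- if (is.character(input) && file.exists(input)) {
      s <- jsonlite::read_json(input, simplifyVector = TRUE)
      list(gm = s$delta2$gm, gsd = s$delta2$gsd)
    } else if (is.numeric(input)) {
      input
    } else {
      stop("mode B requires a posterior input (recalibration summary JSON or delta2 draws)")
    }
    set.seed(derive_seed(config$seed, 3))
    ratios <- posterior_predictive_ratios(post, pop, n_trials = n_trials,
                                          n_per_arm = n_per_arm)
    dec <- be_workflow_B(ratios, threshold = config$decision$threshold,
                         limits = lim)
    out <- list(workflow = "B", pass = dec$pass, limits = lim,
                threshold = dec$threshold, p_be = dec$p_be,
                p_cmax_above = dec$p_cmax_above,
                p_cmax_below = dec$p_cmax_below,
                p_auc_above = dec$p_auc_above,
                p_auc_below = dec$p_auc_below)
  }
  path <- file.path(out_dir, sprintf("decision_%s.json", mode))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  man <- write_manifest(config, paste0("assess_", mode), out_dir, path)
  say(quiet, "workflow %s verdict: %s", mode,
      if (out$pass) "bioequivalent" else "not bioequivalent")
  invisible(c(path, man))
}

#' @rdname vbe_cmd_simulate
#' @param placement passed to [power_type1()].
#' @param n_reps number of trials for the power command.
#' @export
vbe_cmd_power <- function(config, placement = "null", n_reps = 100,
                          out_dir = ".", quiet = FALSE) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- config_population(config)
  des <- config_design(config, "large")
  res <- power_type1(des, pop, placement = placement, n_reps = n_reps,
                     alpha = config$decision$alpha %||% 0.05,
                     limits = unlist(config$decision$limits))
  path <- file.path(out_dir, sprintf("power_%s.json", placement))
  jsonlite::write_json(list(placement = placement,
                            pass_fraction = res$pass_fraction,
                            mc_se = res$mc_se, n_reps = res$n_reps),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  man <- write_manifest(config, paste0("power_", placement), out_dir, path)
  say(quiet, "%s placement: pass fraction %.3f (SE %.3f)", placement,
      res$pass_fraction, res$mc_se)
  invisible(c(path, man))
}

#' @rdname vbe_cmd_simulate
#' @export
vbe_cmd_sensitivity <- function(config, out_dir = ".", quiet = FALSE) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- config_population(config)
  rk <- sensitivity_ranking(pop)
  path <- file.path(out_dir, "sensitivity_ranking.csv")
  write.csv(rk, path, row.names = FALSE)
  man <- write_manifest(config, "sensitivity", out_dir, path)
  say(quiet, "most influential release parameter: %s", rk$parameter[1])
  invisible(c(path, man))
}

#' @rdname vbe_cmd_simulate
#' @export
vbe_cmd_safe_space <- function(config, mode = c("A", "B"), out_dir = ".",
                               quiet = FALSE) {
  mode <- match.arg(mode)
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- config_population(config)
  blk <- config$designs$safe_space %||% list()
  if (mode == "A") {
    des <- trial_design(n_per_arm = blk$n_per_arm %||% 130,
                        seed = derive_seed(config$seed, 4))
    map <- safe_space_A(pop, des, n_trials = blk$n_trials %||% 1000,
                        delta_low = blk$delta_low %||% 0.5,
                        delta_high = blk$delta_high %||% 2,
                        limits = unlist(config$decision$limits))
  } else {
    set.seed(derive_seed(config$seed, 5))
    d1 <- blk$grid_delta1 %||% seq(0.5, 2, length.out = 5)
    d2 <- blk$grid_delta2 %||% seq(0.5, 2, length.out = 5)
    map <- safe_space_B(pop, unlist(d1), unlist(d2),
                        n_trials = blk$b_trials %||% 50,
                        n_per_arm = blk$b_per_arm %||% 200,
                        limits = unlist(config$decision$limits))
  }
  path <- file.path(out_dir, sprintf("safe_space_%s.csv", mode))
  write.csv(map, path, row.names = FALSE)
  man <- write_manifest(config, paste0("safe_space_", mode), out_dir, path)
  say(quiet, "safe-space %s: %d points, %d in safe space", mode,
      nrow(map), sum(map$pass))
  invisible(c(path, man))
}

#' @rdname vbe_cmd_simulate
#' @param n_check_trials predictive-check trial count.
#' @export
vbe_cmd_predictive_check <- function(config, n_check_trials = 100,
                                     out_dir = ".", quiet = FALSE) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- config_population(config)
  des <- config_design(config, "large")
  bands <- predictive_check_bands(pop, des, n_trials = n_check_trials)
  df <- data.frame(time_days = bands$times,
                   median_lower = bands$bands[, "median", "lower"],
                   median_upper = bands$bands[, "median", "upper"],
                   p5_lower = bands$bands[, "p5", "lower"],
                   p5_upper = bands$bands[, "p5", "upper"],
                   p95_lower = bands$bands[, "p95", "lower"],
                   p95_upper = bands$bands[, "p95", "upper"])
  path <- file.path(out_dir, "predictive_check_bands.csv")
  write.csv(df, path, row.names = FALSE)
  man <- write_manifest(config, "predictive_check", out_dir, path)
  invisible(c(path, man))
}
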