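# Virtual parallel-trial generation: subject sampling, noise-free profiles,
# lognormal residual error, sparse-sampling NCA, trial summaries, and
# predictive-check percentile bands.  Also serves as the package's synthetic
# data generator: the defaults emulate an abbreviated (25/arm) or large
# (130/arm) paliperidone palmitate parallel BE trial.

#' Sampling schedules
#'
#' Two published sparse sampling schedules for the last dosing period:
#' `"weeks_54_63"` (54, 55, 57, 59, 63 weeks; the default) and
#' `"weeks_54_65"` (54, 55, 57, 61, 65 weeks, spanning 11 weeks).
#'
#' @param name schedule name.
#' @return Sampling times in days.
#' @export
sampling_schedule <- function(name = c("weeks_54_63", "weeks_54_65")) {
  name <- match.arg(name)
  weeks <- switch(name,
                  weeks_54_63 = c(54, 55, 57, 59, 63),
                  weeks_54_65 = c(54, 55, 57, 61, 65))
  weeks * 7
}

#' Parallel BE trial design
#'
#' @param n_per_arm subjects per arm (>= 2).
#' @param regimen a [dosing_regimen()] applied to every subject (both arms
#'   receive the same schedule; formulation differences act through the
#'   population shift vector `delta`).
#' @param sampling_times measurement times (days).
#' @param analysis_interval `c(t_start, t_end)` used for NCA metrics;
#'   defaults to the span of `sampling_times`.
#' @param arms trial arms to simulate.
#' @param seed optional integer seed making the simulated trial
#'   reproducible.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_per_arm = 25, regimen = pp_regimen(),
                         sampling_times = sampling_schedule(),
                         analysis_interval = range(sampling_times),
                         arms = c("reference", "test"), seed = NULL) {
  if (n_per_arm < 2) stop("n_per_arm must be >= 2")
  if (length(sampling_times) < 1) stop("sampling_times must be non-empty")
  if (analysis_interval[2] <= analysis_interval[1]) {
    stop("analysis_interval must be non-empty")
  }
  arms <- match.arg(arms, several.ok = TRUE)
  structure(list(n_per_arm = as.integer(n_per_arm), regimen = regimen,
                 sampling_times = sort(as.numeric(sampling_times)),
                 analysis_interval = as.numeric(analysis_interval),
                 arms = arms, seed = seed),
            class = "trial_design")
}

#' Abbreviated and large trial designs
#'
#' `abbreviated_trial_design()` is the 25-subjects-per-arm parallel design
#' used for model recalibration (250 measurements from 50 subjects under
#' the default 5-point schedule); `large_trial_design()` is the
#' 130-subjects-per-arm design used for data-based BE assessment.
#'
#' @param n_per_arm subjects per arm.
#' @param ... passed to [trial_design()].
#' @return A [trial_design()].
#' @export
abbreviated_trial_design <- function(n_per_arm = 25, ...) {
  trial_design(n_per_arm = n_per_arm, ...)
}

#' @rdname abbreviated_trial_design
#' @export
large_trial_design <- function(n_per_arm = 130, ...) {
  trial_design(n_per_arm = n_per_arm, ...)
}

#' Simulate a parallel BE trial
#'
#' Samples virtual subjects per arm (the test arm from the delta-shifted
#' population), computes noise-free model profiles at the sampling times,
#' and draws measured concentrations lognormally around the predictions
#' with log-variance `pop$sigma2_resid`.
#'
#' @param design a [trial_design()].
#' @param pop a [population_params()].
#' @return A `concentration_dataset`: data frame with columns `subject`,
#'   `arm`, `time`, `conc` (ng/mL) and attributes `true_params` (the
#'   sampled subject parameters) and `design`.
#' @examples
#' ds <- simulate_trial(abbreviated_trial_design(seed = 1),
#'                      default_population(delta = c(1, 1.05, 1, 1, 1, 1)))
#' nrow(ds)  # 2 arms x 25 subjects x 5 samples = 250
#' @export
simulate_trial <- function(design, pop) {
  stopifnot(inherits(design, "trial_design"),
            inherits(pop, "population_params"))
  if (!is.null(design$seed)) set.seed(design$seed)
  sigma <- sqrt(pop$sigma2_resid)
  records <- list()
  true_params <- list()
  for (arm in design$arms) {
    subj <- sample_subjects(pop, design$n_per_arm, arm)
    prefix <- if (arm == "reference") "R" else "T"
    ids <- sprintf("%s%03d", prefix, seq_len(design$n_per_arm))
    preds <- tryCatch(
      .pk_conc_batch_cpp(as.matrix(subj), regimen_events_matrix(design$regimen),
                         design$sampling_times),
      error = function(e) {
        stop(sprintf("trial simulation (%s arm): %s", arm,
                     conditionMessage(e)))
      })
    noise <- if (sigma > 0) {
      matrix(rlnorm(length(preds), meanlog = 0, sdlog = sigma),
             nrow = nrow(preds))
    } else 1
    conc <- preds * noise
    records[[arm]] <- data.frame(
      subject = rep(ids, times = length(design$sampling_times)),
      arm = arm,
      time = rep(design$sampling_times, each = design$n_per_arm),
      conc = as.vector(conc))
    true_params[[arm]] <- cbind(subject = ids, arm = arm, subj)
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out <- out[order(out$arm, out$subject, out$time), ]
  rownames(out) <- NULL
  attr(out, "true_params") <- do.call(rbind, true_params)
  attr(out, "design") <- design
  class(out) <- c("concentration_dataset", "data.frame")
  out
}

#' Sparse-sampling NCA exposure metrics
#'
#' Cmax is the maximum observed concentration in the interval; the partial
#' AUC is the linear trapezoidal rule over the observed points.
#'
#' @param times,conc observation times and concentrations for one subject.
#' @param interval `c(t_start, t_end)`; only observations inside are used.
#' @return An `exposure_metrics` list with `method = "nca"`.
#' @export
nca_metrics <- function(times, conc, interval = range(times)) {
  keep <- times >= interval[1] & times <= interval[2]
  times <- times[keep]; conc <- conc[keep]
  if (length(times) < 2) {
    stop("insufficient data: NCA needs at least 2 observations in interval")
  }
  o <- order(times)
  times <- times[o]; conc <- conc[o]
  auc <- sum(diff(times) * (head_(conc) + tail_(conc)) / 2)
  metrics <- list(cmax = max(conc), auc = auc,
                  interval = as.numeric(interval), method = "nca")
  class(metrics) <- "exposure_metrics"
  metrics
}

head_ <- function(x) x[-length(x)]
tail_ <- function(x) x[-1]

#' Per-subject NCA metrics for a trial dataset
#'
#' @param dataset a `concentration_dataset`.
#' @param interval analysis interval; defaults to the design's.
#' @return Data frame with columns `subject`, `arm`, `cmax`, `auc`.
#' @export
nca_by_subject <- function(dataset, interval = NULL) {
  interval <- interval %||% attr(dataset, "design")$analysis_interval %||%
    range(dataset$time)
  split_idx <- split(seq_len(nrow(dataset)), dataset$subject)
  rows <- lapply(names(split_idx), function(id) {
    idx <- split_idx[[id]]
    m <- nca_metrics(dataset$time[idx], dataset$conc[idx], interval)
    data.frame(subject = id, arm = dataset$arm[idx[1]],
               cmax = m$cmax, auc = m$auc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize exposure metrics of a two-arm trial
#'
#' Geometric means per arm, test/reference geometric-mean ratios, and
#' natural-space CVs (`sqrt(exp(s^2) - 1)` with `s` the log-SD) for Cmax
#' and AUC.
#'
#' @param metrics data frame with columns `arm`, `cmax`, `auc` (e.g. from
#'   [nca_by_subject()]).
#' @return A list with one element per metric carrying `gm_ref`, `gm_test`,
#'   `gmr`, `cv_ref`, `cv_test`.
#' @export
summarize_trial <- function(metrics) {
  for (m in c("cmax", "auc")) {
    if (any(metrics[[m]] <= 0)) stop("exposure metrics must be positive")
  }
  arms <- split(metrics, metrics$arm)
  if (!all(c("reference", "test") %in% names(arms))) {
    stop("both arms must be non-empty")
  }
  out <- lapply(c(cmax = "cmax", auc = "auc"), function(m) {
    lr <- log(arms$reference[[m]]); lt <- log(arms$test[[m]])
    list(gm_ref = exp(mean(lr)), gm_test = exp(mean(lt)),
         gmr = exp(mean(lt) - mean(lr)),
         cv_ref = lognormal_cv(sd(lr)), cv_test = lognormal_cv(sd(lt)))
  })
  out
}

#' Predictive-check percentile bands
#'
#' Simulates `n_trials` trials; within each trial computes the median and
#' the 5th and 95th percentile concentration across subjects at every
#' sampling time, then reports the 5th-95th percentile envelope of each of
#' those three summaries across trials.
#'
#' @param pop a [population_params()].
#' @param design a [trial_design()]; its seed, when set, seeds the whole
#'   band computation.
#' @param n_trials number of simulated trials (>= 2).
#' @return A list with `times` and `bands`, an array of dimension
#'   (times x 3 summaries x 2 bounds).
#' @export
predictive_check_bands <- function(pop, design, n_trials = 100) {
  if (n_trials < 2) stop("n_trials must be >= 2")
  if (!is.null(design$seed)) set.seed(design$seed)
  inner <- design
  inner$seed <- NULL
  times <- design$sampling_times
  qs <- array(NA_real_, c(n_trials, length(times), 3))
  for (k in seq_len(n_trials)) {
    ds <- simulate_trial(inner, pop)
    for (j in seq_along(times)) {
      x <- ds$conc[ds$time == times[j]]
      qs[k, j, ] <- quantile(x, c(0.5, 0.05, 0.95), names = FALSE)
    }
  }
  bands <- array(NA_real_, c(length(times), 3, 2),
                 dimnames = list(NULL, c("median", "p5", "p95"),
                                 c("lower", "upper")))
  for (j in seq_along(times)) {
    for (s in 1:3) {
      bands[j, s, ] <- quantile(qs[, j, s], c(0.05, 0.95), names = FALSE)
    }
  }
  list(times = times, bands = bands)
}

#' Read and write concentration datasets
#'
#' Long-format CSV with columns `subject`, `arm`, `time_days`,
#' `conc_ng_per_ml`; numeric columns are written with 17 significant
#' digits so the round trip is lossless.  The true-parameter sidecar, when
#' present, is written alongside.
#'
#' @param dataset a `concentration_dataset`.
#' @param path CSV path.
#' @param params_path optional sidecar CSV for the true subject parameters.
#' @return `read_concentration_dataset()` returns a
#'   `concentration_dataset`.
#' @export
write_concentration_dataset <- function(dataset, path, params_path = NULL) {
  df <- data.frame(subject = dataset$subject, arm = dataset$arm,
                   time_days = sprintf("%.17g", dataset$time),
                   conc_ng_per_ml = sprintf("%.17g", dataset$conc))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  tp <- attr(dataset, "true_params")
  if (!is.null(params_path) && !is.null(tp)) {
    num <- vapply(tp, is.numeric, logical(1))
    tp[num] <- lapply(tp[num], function(x) sprintf("%.17g", x))
    write.csv(tp, params_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_concentration_dataset
#' @export
read_concentration_dataset <- function(path, params_path = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "arm", "time_days", "conc_ng_per_ml")
  if (!all(need %in% names(df))) {
    stop("malformed dataset CSV: expected columns ",
         paste(need, collapse = ", "))
  }
  out <- data.frame(subject = df$subject, arm = df$arm,
                    time = as.numeric(df$time_days),
                    conc = as.numeric(df$conc_ng_per_ml))
  if (any(!is.finite(out$conc)) || any(out$conc <= 0)) {
    bad <- which(!is.finite(out$conc) | out$conc <= 0)[1]
    stop(sprintf("parse error at data line %d: non-positive concentration",
                 bad))
  }
  if (!is.null(params_path)) {
    tp <- read.csv(params_path, stringsAsFactors = FALSE)
    attr(out, "true_params") <- tp
  }
  class(out) <- c("concentration_dataset", "data.frame")
  out
}
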