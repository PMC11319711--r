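# Hierarchical population layer: lognormal inter-subject variability on the
# structural parameters, latent logit/odds-scale fractions, and the
# multiplicative test/reference formulation-shift vector delta.

DELTA_NAMES <- c("f3", "kas3_max", "kar3_max", "kas3_50", "kar3_50", "gamma")
VARYING_NAMES <- c("f1", "f3", "ka1", "kar3_50", "kas3_max", "kas3_50",
                   "CL", "V")
LATENT_NAMES <- c("kappa_f1", "kappa_f3", "ka1", "kar3_50", "kas3_max",
                  "kas3_50", "CL", "V", "Qc0")

#' Population PK parameters
#'
#' Hierarchical model specification: geometric means (fraction-scale
#' locations for `f1` and `f3`), log-space variances, shared structural
#' constants, the initial-body-burden distribution, residual error variance,
#' and the six-component formulation-shift vector `delta` in the order
#' (f3, kas3_max, kar3_max, kas3_50, kar3_50, gamma).
#'
#' @param mu named list/vector of geometric means for `ka1`, `kar3_50`,
#'   `kas3_max`, `kas3_50`, `CL`, `V` and fraction-scale locations in (0,1)
#'   for `f1`, `f3`.
#' @param sigma2 named vector of log-space variances for the eight
#'   subject-varying parameters (for `f1`, `f3` the variance applies to the
#'   latent kappa).
#' @param shared named list with `kar3_max`, `gamma`, `tl1`: structural
#'   values common to all subjects.
#' @param qc0_gm,qc0_gsd geometric mean (mg eq.) and geometric SD of the
#'   initial central-compartment amount.
#' @param sigma2_resid residual log-space variance of measured
#'   concentrations.
#' @param delta six positive multiplicative test/reference shifts, in the
#'   order given above.
#' @param transform latent-fraction back-transform: `"odds_ratio"`
#'   (`theta = kappa / (1 + kappa)`; the location is the median fraction;
#'   the default) or `"paper_logistic"` (logistic applied to the lognormal
#'   odds-scale latent, which restricts fractions to (0.5, 1)).
#' @return An object of class `population_params`.
#' @seealso [default_population()] for the documented default profile.
#' @export
population_params <- function(mu, sigma2, shared, qc0_gm, qc0_gsd,
                              sigma2_resid, delta = rep(1, 6),
                              transform = c("odds_ratio", "paper_logistic")) {
  transform <- match.arg(transform)
  mu <- as.list(mu)
  need <- VARYING_NAMES
  if (!all(need %in% names(mu))) {
    stop("mu must name all of: ", paste(need, collapse = ", "))
  }
  sigma2 <- unlist(sigma2)[need]
  if (any(is.na(sigma2)) || any(sigma2 < 0)) {
    stop("sigma2 must provide a non-negative variance for each of: ",
         paste(need, collapse = ", "))
  }
  for (nm in c("ka1", "kar3_50", "kas3_max", "kas3_50", "CL", "V")) {
    assert_scalar_pos(mu[[nm]], paste0("mu$", nm))
  }
  for (nm in c("f1", "f3")) {
    if (mu[[nm]] <= 0 || mu[[nm]] >= 1) {
      stop(sprintf("mu$%s must lie strictly in (0, 1)", nm))
    }
  }
  shared <- as.list(shared)
  for (nm in c("kar3_max", "gamma", "tl1")) {
    assert_scalar_pos(shared[[nm]] %||% stop("shared$", nm, " missing"),
                      paste0("shared$", nm))
  }
  assert_scalar_pos(qc0_gm, "qc0_gm")
  if (qc0_gsd < 1) stop("qc0_gsd must be >= 1")
  if (sigma2_resid < 0) stop("sigma2_resid must be non-negative")
  delta <- unname(unlist(delta))
  if (length(delta) != 6 || any(delta <= 0)) {
    stop("delta must be a vector of 6 positive shifts")
  }
  pop <- list(mu = mu, sigma2 = sigma2, shared = shared, qc0_gm = qc0_gm,
              qc0_gsd = qc0_gsd, sigma2_resid = sigma2_resid,
              delta = setNames(delta, DELTA_NAMES), transform = transform)
  class(pop) <- "population_params"
  # the shifted test-arm f3 location must stay a valid fraction
  invisible(shifted_locations(pop, "test"))
  pop
}

#' @export
print.population_params <- function(x, ...) {
  cat("Population PK parameters\n")
  cat("  geometric means / fraction locations:\n")
  print(unlist(x$mu))
  cat("  log-space variances:\n")
  print(x$sigma2)
  cat(sprintf("  shared: kar3_max = %g, gamma = %g, tl1 = %g\n",
              x$shared$kar3_max, x$shared$gamma, x$shared$tl1))
  cat(sprintf("  Qc0 ~ LN(GM %g, GSD %g); residual sigma2 = %g\n",
              x$qc0_gm, x$qc0_gsd, x$sigma2_resid))
  cat("  delta (f3, kas3_max, kar3_max, kas3_50, kar3_50, gamma):\n")
  print(x$delta)
  cat(sprintf("  fraction transform: %s\n", x$transform))
  invisible(x)
}

#' Default population profile
#'
#' The package's documented configuration profile for paliperidone palmitate
#' long-acting injectables.  The structural values are placeholders chosen
#' to reproduce the qualitative regime of the published model: average
#' steady-state concentrations near 40-50 ng/mL under 525 mg eq. every
#' 13 weeks, release spanning months, and exposure coefficients of
#' variation of about 50-55% across subjects.
#'
#' @param delta optional six-vector overriding the null shift.
#' @param transform fraction back-transform, see [population_params()].
#' @return A [population_params()] object.
#' @export
default_population <- function(delta = rep(1, 6),
                               transform = "odds_ratio") {
  population_params(
    mu = list(f1 = 0.15, f3 = 0.15, ka1 = 0.02, kar3_50 = 100,
              kas3_max = 5, kas3_50 = 300, CL = 120, V = 400),
    sigma2 = c(f1 = 0.30^2, f3 = 0.30^2, ka1 = 0.30^2, kar3_50 = 0.30^2,
               kas3_max = 0.25^2, kas3_50 = 0.30^2, CL = 0.50^2,
               V = 0.30^2),
    shared = list(kar3_max = 8, gamma = 1.3, tl1 = 7),
    qc0_gm = 30, qc0_gsd = 1.5,
    sigma2_resid = 0.2^2,
    delta = delta,
    transform = transform
  )
}

#' Latent fraction transform and its inverse
#'
#' Maps the positive lognormal latent `kappa` to a fraction in (0, 1).
#' `"paper_logistic"` composes the odds-scale latent with the logistic
#' inverse (restricting fractions to (0.5, 1) for `kappa > 0`);
#' `"odds_ratio"` is the internally consistent odds-to-probability mapping.
#'
#' @param kappa positive latent value(s).
#' @param method `"paper_logistic"` or `"odds_ratio"`.
#' @return Fractions strictly in (0, 1).
#' @export
fraction_transform <- function(kappa, method = c("paper_logistic",
                                                 "odds_ratio")) {
  method <- match.arg(method)
  if (any(kappa <= 0)) stop("kappa must be positive (lognormal latent)")
  if (method == "paper_logistic") 1 / (1 + exp(-kappa)) else kappa / (1 + kappa)
}

#' @rdname fraction_transform
#' @param theta fraction(s) strictly in (0, 1); for `"paper_logistic"` the
#'   inverse additionally requires theta > 0.5 (the transform's range).
#' @export
fraction_inverse <- function(theta, method = c("paper_logistic",
                                               "odds_ratio")) {
  method <- match.arg(method)
  if (any(theta <= 0) || any(theta >= 1)) {
    stop("fractions must lie strictly in (0, 1)")
  }
  if (method == "paper_logistic") {
    if (any(theta <= 0.5)) {
      stop("paper_logistic range is (0.5, 1); fraction not invertible")
    }
    log(theta / (1 - theta))
  } else {
    theta / (1 - theta)
  }
}

#' Apply the formulation shift to reference locations
#'
#' Multiplies the six drug-release location parameters by the components of
#' `delta` (order: f3, kas3_max, kar3_max, kas3_50, kar3_50, gamma).  For
#' `f3` the shift acts on the geometric mean of the latent kappa.
#'
#' @param mu_ref named list of reference locations as in
#'   [population_params()] plus `kar3_max` and `gamma` entries.
#' @param delta positive six-vector.
#' @return The shifted location list.
#' @export
apply_formulation_shift <- function(mu_ref, delta) {
  if (length(delta) != 6 || any(delta <= 0)) {
    stop("delta must be a vector of 6 positive shifts")
  }
  mu <- as.list(mu_ref)
  mu$kas3_max <- mu$kas3_max * delta[2]
  mu$kar3_max <- mu$kar3_max * delta[3]
  mu$kas3_50 <- mu$kas3_50 * delta[4]
  mu$kar3_50 <- mu$kar3_50 * delta[5]
  mu$gamma <- mu$gamma * delta[6]
  # f3: multiplicative on the latent kappa geometric mean
  mu$kappa_f3 <- (mu$kappa_f3 %||% (mu$f3 / (1 - mu$f3))) * delta[1]
  mu$f3 <- NULL
  mu
}

# Latent-scale (meanlog) locations and SDs for the nine subject-varying
# parameters, with the arm's delta shift applied.  Order = LATENT_NAMES.
shifted_locations <- function(pop, arm = c("reference", "test")) {
  arm <- match.arg(arm)
  d <- if (arm == "test") pop$delta else setNames(rep(1, 6), DELTA_NAMES)
  kappa_f1 <- pop$mu$f1 / (1 - pop$mu$f1)
  kappa_f3 <- pop$mu$f3 / (1 - pop$mu$f3) * d["f3"]
  if (!is.finite(kappa_f3) || kappa_f3 <= 0 ||
      fraction_transform(kappa_f3, pop$transform) >= 1) {
    stop("shifted f3 location implies a fraction outside (0, 1)")
  }
  meanlog <- c(log(kappa_f1), log(kappa_f3), log(pop$mu$ka1),
               log(pop$mu$kar3_50 * d["kar3_50"]),
               log(pop$mu$kas3_max * d["kas3_max"]),
               log(pop$mu$kas3_50 * d["kas3_50"]),
               log(pop$mu$CL), log(pop$mu$V), log(pop$qc0_gm))
  sdlog <- c(sqrt(pop$sigma2[c("f1", "f3", "ka1", "kar3_50", "kas3_max",
                               "kas3_50", "CL", "V")]),
             log(pop$qc0_gsd))
  list(meanlog = setNames(meanlog, LATENT_NAMES),
       sdlog = setNames(unname(sdlog), LATENT_NAMES),
       kar3_max = pop$shared$kar3_max * unname(d["kar3_max"]),
       gamma = pop$shared$gamma * unname(d["gamma"]),
       tl1 = pop$shared$tl1)
}

latent_to_subject <- function(z, loc, transform) {
  subject_params(
    f1 = fraction_transform(exp(z[["kappa_f1"]]), transform),
    tl1 = loc$tl1,
    ka1 = exp(z[["ka1"]]),
    f3 = fraction_transform(exp(z[["kappa_f3"]]), transform),
    kar3_max = loc$kar3_max,
    kar3_50 = exp(z[["kar3_50"]]),
    kas3_max = exp(z[["kas3_max"]]),
    kas3_50 = exp(z[["kas3_50"]]),
    gamma = loc$gamma,
    CL = exp(z[["CL"]]),
    V = exp(z[["V"]]),
    Qc0 = exp(z[["Qc0"]]))
}

#' Sample virtual subjects from the population
#'
#' Draws subject-level parameters: lognormal around the (possibly
#' delta-shifted) geometric means for the six continuous parameters and the
#' initial body burden, and latent-kappa draws back-transformed to fractions
#' for `f1` and `f3`.  `kar3_max` and `gamma` are shared across subjects.
#'
#' @param pop a [population_params()] object.
#' @param n number of subjects.
#' @param arm `"reference"` or `"test"`; the test arm uses the
#'   delta-shifted locations.
#' @return A data frame with one row per subject holding the twelve
#'   structural parameters (class `subject_sample`).
#' @export
sample_subjects <- function(pop, n, arm = c("reference", "test")) {
  arm <- match.arg(arm)
  stopifnot(inherits(pop, "population_params"), n >= 1)
  loc <- shifted_locations(pop, arm)
  z <- matrix(rnorm(n * 9, mean = rep(loc$meanlog, each = n),
                    sd = rep(loc$sdlog, each = n)),
              nrow = n, dimnames = list(NULL, LATENT_NAMES))
  out <- data.frame(
    f1 = fraction_transform(exp(z[, "kappa_f1"]), pop$transform),
    tl1 = loc$tl1,
    ka1 = exp(z[, "ka1"]),
    f3 = fraction_transform(exp(z[, "kappa_f3"]), pop$transform),
    kar3_max = loc$kar3_max,
    kar3_50 = exp(z[, "kar3_50"]),
    kas3_max = exp(z[, "kas3_max"]),
    kas3_50 = exp(z[, "kas3_50"]),
    gamma = loc$gamma,
    CL = exp(z[, "CL"]),
    V = exp(z[, "V"]),
    Qc0 = exp(z[, "Qc0"]))
  class(out) <- c("subject_sample", "data.frame")
  out
}

#' @rdname sample_subjects
#' @return `sample_subject()` returns a single [subject_params()] object.
#' @export
sample_subject <- function(pop, arm = c("reference", "test")) {
  row <- sample_subjects(pop, 1, arm)
  do.call(subject_params, as.list(row[1, , drop = FALSE]))
}

subject_params_from_row <- function(row) {
  subject_params(f1 = row$f1, tl1 = row$tl1, ka1 = row$ka1, f3 = row$f3,
                 kar3_max = row$kar3_max, kar3_50 = row$kar3_50,
                 kas3_max = row$kas3_max, kas3_50 = row$kas3_50,
                 gamma = row$gamma, CL = row$CL, V = row$V, Qc0 = row$Qc0)
}
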