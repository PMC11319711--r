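# Bayesian recalibration: log-posterior decomposition, diagnostics,
# posterior summaries, and sampler correctness against closed forms.

make_latents <- function(dataset, pop) {
  tp <- attr(dataset, "true_params")
  tp <- tp[order(tp$subject), ]
  z <- cbind(kappa_f1 = log(fraction_inverse(tp$f1, pop$transform)),
             kappa_f3 = log(fraction_inverse(tp$f3, pop$transform)),
             ka1 = log(tp$ka1), kar3_50 = log(tp$kar3_50),
             kas3_max = log(tp$kas3_max), kas3_50 = log(tp$kas3_50),
             CL = log(tp$CL), V = log(tp$V), Qc0 = log(tp$Qc0))
  z
}

empty_dataset <- function() {
  ds <- data.frame(subject = character(), arm = character(),
                   time = numeric(), conc = numeric())
  class(ds) <- c("concentration_dataset", "data.frame")
  ds
}

test_that("with no observations the log-posterior reduces to the priors", {
  pop <- default_population()
  z <- matrix(numeric(), 0, 9,
              dimnames = list(NULL, vbesim:::LATENT_NAMES))
  lp <- log_posterior(1.3, z, empty_dataset(), pop, regimen = pp_regimen(),
                      components = TRUE)
  expect_equal(lp$loglik, 0)
  expect_equal(lp$logprior_subj, 0)
  expect_equal(lp$logprior_delta2, dnorm(log(1.3), 0, log(2), log = TRUE))
  expect_equal(lp$total, lp$logprior_delta2)
})

test_that("the measurement term equals the lognormal density at the mode", {
  pop <- default_population()
  loc <- vbesim:::inference_locations(pop)
  z <- matrix(loc$meanlog, 1, 9,
              dimnames = list(NULL, vbesim:::LATENT_NAMES))
  subj <- vbesim:::latent_to_subject(loc$meanlog, loc, pop$transform)
  pred <- simulate_profile(subj, pp_regimen(), 399, rtol = 1e-5,
                           atol = 1e-7)$conc
  ds <- data.frame(subject = "R001", arm = "reference", time = 399,
                   conc = pred)
  class(ds) <- c("concentration_dataset", "data.frame")
  lp <- log_posterior(1, z, ds, pop, regimen = pp_regimen(),
                      components = TRUE)
  sigma <- sqrt(pop$sigma2_resid)
  expect_equal(lp$loglik, dlnorm(pred, log(pred), sigma, log = TRUE),
               tolerance = 1e-7)
})

test_that("duplicating every record exactly doubles the likelihood term", {
  pop <- default_population()
  ds <- simulate_trial(small_design(n = 3, seed = 31), pop)
  z <- make_latents(ds, pop)
  lp1 <- log_posterior(1.1, z, ds, pop, components = TRUE)
  ds2 <- rbind(ds, ds)
  class(ds2) <- class(ds)
  attr(ds2, "design") <- attr(ds, "design")
  lp2 <- log_posterior(1.1, z, ds2, pop, components = TRUE)
  expect_equal(lp2$loglik, 2 * lp1$loglik, tolerance = 1e-10)
  expect_equal(lp2$logprior_subj, lp1$logprior_subj)
})

test_that("Gelman-Rubin matches a direct evaluation of the B/W formula", {
  set.seed(432)
  ch1 <- rnorm(100, 0, 1); ch2 <- rnorm(100, 10, 1)
  rhat <- gelman_rubin(list(ch1, ch2))
  # independent spreadsheet-style evaluation
  n <- 100; means <- c(mean(ch1), mean(ch2))
  W <- mean(c(var(ch1), var(ch2)))
  B <- n * var(means)
  expected <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(unname(rhat), expected, tolerance = 1e-10)

  same <- lapply(1:4, function(i) rnorm(1e4))
  expect_lt(gelman_rubin(same), 1.01)

  expect_error(gelman_rubin(list(ch1)), ">= 2 chains")
  expect_true(is.na(gelman_rubin(list(rep(1, 50), rep(1, 50)))))
})

test_that("posterior summaries follow the geometric-scale conventions", {
  s <- posterior_summary(rep(2, 200))
  expect_equal(s$gm, 2)
  expect_equal(s$gsd, 1)
  expect_equal(s$cri, c(2, 2))

  set.seed(433)
  s2 <- posterior_summary(exp(rnorm(1e5)))
  expect_equal(s2$gm, 1, tolerance = 0.02)
  expect_equal(s2$gsd, exp(1), tolerance = 0.02)

  s3 <- posterior_summary(as.numeric(1:1000))
  expect_equal(s3$cri, quantile(1:1000, c(0.025, 0.975), names = FALSE))
  expect_equal(s3$cri[1], 25.975)

  expect_error(posterior_summary(rep(1, 50)), ">= 100")
  expect_error(posterior_summary(c(rep(1, 200), -1)), "positive")
})

test_that("the delta2 block reproduces the conjugate normal-normal posterior", {
  pop <- default_population()
  ds <- simulate_trial(small_design(n = 10, seed = 34), pop)
  z <- make_latents(ds, pop)
  cfg <- mcmc_config(n_chains = 2, n_iter = 6000, n_burnin = 1000,
                     seed = 35)
  fit <- run_mcmc(cfg, ds, pop, sample_subjects = FALSE, init_latents = z)
  draws <- log(delta2_draws(fit))

  # closed form: z_kas3 of test subjects ~ N(m + log d2, sd^2),
  # prior log d2 ~ N(0, log(2)^2)
  loc <- vbesim:::inference_locations(pop)
  md <- vbesim:::mcmc_data(ds)
  zt <- z[md$arm == 1, "kas3_max"]
  sd2 <- loc$sdlog[["kas3_max"]]^2
  prec <- length(zt) / sd2 + 1 / log(2)^2
  post_mean <- sum(zt - loc$meanlog[["kas3_max"]]) / sd2 / prec
  post_sd <- sqrt(1 / prec)
  expect_lt(abs(mean(draws) - post_mean), 0.02)
  expect_equal(sd(draws), post_sd, tolerance = 0.05)
})

test_that("an almost noise-free likelihood recovers subject clearances", {
  pop <- default_population()
  pop$sigma2_resid <- 1e-4
  des <- trial_design(n_per_arm = 4,
                      sampling_times = seq(14, 441, by = 21), seed = 36)
  ds <- simulate_trial(des, pop)
  cfg <- mcmc_config(n_chains = 2, n_iter = 1200, n_burnin = 600,
                     scale_subj = 0.02, seed = 37)
  fit <- run_mcmc(cfg, ds, pop, init_latents = make_latents(ds, pop))
  tp <- attr(ds, "true_params")
  tp <- tp[order(tp$subject), ]
  for (i in seq_len(nrow(tp))) {
    col <- paste0(tp$subject[i], ".CL")
    med <- median(exp(unlist(lapply(fit$chains, function(m) m[, col]))))
    expect_lt(abs(med / tp$CL[i] - 1), 0.05)
  }
})

test_that("identical seeds give identical chains", {
  pop <- default_population()
  ds <- simulate_trial(small_design(n = 2, seed = 38), pop)
  cfg <- mcmc_config(n_chains = 2, n_iter = 120, n_burnin = 60, seed = 39)
  f1 <- run_mcmc(cfg, ds, pop)
  f2 <- run_mcmc(cfg, ds, pop)
  expect_identical(f1$chains, f2$chains)
  cfg$seed <- 40
  f3 <- run_mcmc(cfg, ds, pop)
  expect_false(identical(f1$chains[[1]][, 1], f3$chains[[1]][, 1]))
})

test_that("a larger abbreviated trial contracts the delta2 posterior", {
  pop_true <- default_population(delta = c(1, 1.3, 1, 1, 1, 1))
  pop <- default_population()
  gsd_for <- function(n, seed) {
    ds <- simulate_trial(trial_design(n_per_arm = n, seed = seed), pop_true)
    cfg <- mcmc_config(n_chains = 2, n_iter = 500, n_burnin = 250,
                       seed = seed + 1)
    run_mcmc(cfg, ds, pop)$delta2$gsd
  }
  seeds <- c(501, 502, 503)
  g25 <- mean(vapply(seeds, function(s) gsd_for(25, s), numeric(1)))
  g100 <- mean(vapply(seeds, function(s) gsd_for(100, s + 10), numeric(1)))
  expect_lt(g100, g25)
})

test_that("configuration invariants are enforced", {
  expect_error(mcmc_config(n_chains = 1), "n_chains")
  expect_error(mcmc_config(n_iter = 100, n_burnin = 100), "n_burnin")
  expect_error(mcmc_config(scale_subj = 0), "positive")
})
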