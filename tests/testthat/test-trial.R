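# Trial simulator: dataset contracts, residual error, NCA, summaries,
# predictive-check bands, file round-trips.

test_that("the abbreviated design yields 250 records from 50 subjects", {
  ds <- simulate_trial(abbreviated_trial_design(seed = 1),
                       default_population())
  expect_equal(nrow(ds), 250)
  expect_equal(length(unique(ds$subject)), 50)
  expect_true(all(ds$conc > 0))
  expect_false(any(duplicated(ds[c("subject", "time")])))
  expect_s3_class(ds, "concentration_dataset")
  expect_equal(nrow(attr(ds, "true_params")), 50)
})

test_that("zero residual variance reproduces the model predictions exactly", {
  pop <- default_population()
  pop$sigma2_resid <- 0
  des <- small_design(n = 3, seed = 2)
  ds <- simulate_trial(des, pop)
  tp <- attr(ds, "true_params")
  id <- ds$subject[1]
  row <- tp[tp$subject == id, ]
  p <- subject_params(f1 = row$f1, tl1 = row$tl1, ka1 = row$ka1,
                      f3 = row$f3, kar3_max = row$kar3_max,
                      kar3_50 = row$kar3_50, kas3_max = row$kas3_max,
                      kas3_50 = row$kas3_50, gamma = row$gamma,
                      CL = row$CL, V = row$V, Qc0 = row$Qc0)
  pred <- simulate_profile(p, des$regimen, des$sampling_times)$conc
  expect_equal(ds$conc[ds$subject == id], pred, tolerance = 1e-10)
})

test_that("trial simulation is deterministic given the seed", {
  pop <- default_population()
  a <- simulate_trial(small_design(n = 3, seed = 7), pop)
  b <- simulate_trial(small_design(n = 3, seed = 7), pop)
  c <- simulate_trial(small_design(n = 3, seed = 8), pop)
  expect_identical(a$conc, b$conc)
  expect_false(identical(a$conc, c$conc))
})

test_that("NCA metrics match hand-computed trapezoids", {
  m <- nca_metrics(c(0, 1, 2, 4, 8), c(1, 2, 4, 2, 1))
  expect_equal(m$auc, 16.5)
  expect_equal(m$cmax, 4)
  flat <- nca_metrics(c(0, 5), c(3, 3))
  expect_equal(flat$auc, 15)
  expect_equal(flat$cmax, 3)
  expect_error(nca_metrics(3, 1), "insufficient")
})

test_that("sparse NCA converges to the model-integrated AUC on a dense grid", {
  s <- test_subject()
  iv <- last_dosing_period(pp_regimen())
  grid <- seq(iv[1], iv[2], length.out = 10000)
  conc <- simulate_profile(s, pp_regimen(), grid)$conc
  nca <- nca_metrics(grid, conc, iv)
  mi <- exposure_model_integrated(s, pp_regimen(), iv)
  expect_equal(nca$auc, mi$auc, tolerance = 1e-3)
  # sparse five-point schedule must differ (and not crash)
  sparse_t <- sampling_schedule()
  sparse <- nca_metrics(sparse_t,
                        simulate_profile(s, pp_regimen(), sparse_t)$conc)
  expect_false(isTRUE(all.equal(sparse$auc, mi$auc, tolerance = 1e-3)))
})

test_that("trial summaries compute GMRs and lognormal CVs correctly", {
  met <- data.frame(arm = rep(c("reference", "test"), each = 4),
                    cmax = c(1, 2, 3, 4, 2, 4, 6, 8),
                    auc = c(10, 20, 30, 40, 20, 40, 60, 80))
  s <- summarize_trial(met)
  expect_equal(s$cmax$gmr, 2)
  expect_equal(s$auc$gmr, 2)

  # identical arms
  met2 <- met; met2$cmax[5:8] <- met2$cmax[1:4]; met2$auc[5:8] <- met2$auc[1:4]
  expect_equal(summarize_trial(met2)$cmax$gmr, 1)

  # CV formula: log-SD 0.4724 -> CV 49.9%
  x <- exp(as.numeric(scale(rnorm(30))) * 0.4724)
  met3 <- data.frame(arm = rep(c("reference", "test"), each = 30),
                     cmax = c(x, x), auc = c(x, x))
  expect_equal(summarize_trial(met3)$cmax$cv_ref,
               sqrt(exp(0.4724^2) - 1), tolerance = 1e-10)
  expect_equal(summarize_trial(met3)$cmax$cv_ref, 0.500, tolerance = 1e-3)

  expect_error(summarize_trial(transform(met, cmax = -cmax)), "positive")
})

test_that("with delta = 1 the trial GMR distribution is centred at 1", {
  set.seed(421)
  pop <- default_population()
  des <- small_design(n = 10)
  lg <- replicate(200, {
    ds <- simulate_trial(des, pop)
    log(summarize_trial(nca_by_subject(ds))$auc$gmr)
  })
  se <- sd(lg) / sqrt(length(lg))
  expect_lt(abs(mean(lg)), 2 * se + 1e-12)
})

test_that("simulated large-trial exposure CVs sit in the configured regime", {
  set.seed(422)
  pop <- default_population()
  cvs <- unlist(lapply(1:3, function(i) {
    ds <- simulate_trial(trial_design(n_per_arm = 65), pop)
    s <- summarize_trial(nca_by_subject(ds))
    c(s$cmax$cv_ref, s$cmax$cv_test, s$auc$cv_ref, s$auc$cv_test)
  }))
  expect_gt(mean(cvs), 0.4)
  expect_lt(mean(cvs), 0.7)
})

test_that("predictive-check bands collapse, widen and keep their shape", {
  pop0 <- default_population()
  pop0$sigma2 <- setNames(rep(0, 8), vbesim:::VARYING_NAMES)
  pop0$sigma2_resid <- 0
  pop0$qc0_gsd <- 1
  des <- small_design(n = 4, seed = 5)
  b0 <- predictive_check_bands(pop0, des, n_trials = 3)
  expect_equal(b0$bands[, , "lower"], b0$bands[, , "upper"],
               tolerance = 1e-10)

  widths <- vapply(c(0.05, 0.2, 0.5), function(sig) {
    pop <- pop0
    pop$sigma2_resid <- sig^2
    des$seed <- 6
    b <- predictive_check_bands(pop, des, n_trials = 20)
    mean(b$bands[, "p95", "upper"] - b$bands[, "p95", "lower"])
  }, numeric(1))
  expect_true(all(diff(widths) > 0))

  expect_equal(dim(b0$bands), c(length(des$sampling_times), 3, 2))
})

test_that("concentration datasets round-trip losslessly through CSV", {
  ds <- simulate_trial(small_design(n = 3, seed = 9), default_population())
  d <- withr::local_tempdir()
  f <- file.path(d, "trial.csv"); fp <- file.path(d, "params.csv")
  write_concentration_dataset(ds, f, fp)
  back <- read_concentration_dataset(f, fp)
  expect_identical(back$conc, ds$conc)
  expect_identical(back$time, ds$time)
  expect_identical(back$subject, ds$subject)
  tp <- attr(back, "true_params")
  expect_equal(tp$CL, attr(ds, "true_params")$CL)

  writeLines(c("a,b", "1,2"), f)
  expect_error(read_concentration_dataset(f), "malformed")
})
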