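# Bioequivalence machinery: TOST against its closed form, both decision
# workflows, power behaviour, sensitivity ranking and safe-space maps.

test_that("TOST matches the closed-form pooled-variance interval", {
  # arms with exact sample moments: mean log difference 0, pooled SD 0.5
  base <- as.numeric(scale(rnorm(25))) * 0.5
  res <- tost(base + 1, base + 1)
  half <- qt(0.95, 48) * 0.5 * sqrt(2 / 25)
  expect_equal(log(res$ci[2]), half, tolerance = 1e-12)
  expect_equal(res$gmr, 1)
  expect_gt(half, log(1.25))   # the low-power regime
  expect_false(res$pass)       # fails despite a GMR of exactly 1

  # a 38% difference at 25/arm with ~48% CV cannot conclude BE
  ref <- as.numeric(scale(rnorm(25))) * 0.48 + 3
  res2 <- tost(ref + log(1.38), ref)
  expect_equal(res2$gmr, 1.38, tolerance = 1e-12)
  expect_false(res2$pass)

  # near-identical formulations with large n pass
  set.seed(441)
  a <- rnorm(50, 0, 1e-6)
  res3 <- tost(a, rnorm(50, 0, 1e-6))
  expect_true(res3$pass)
  expect_equal(res3$gmr, 1, tolerance = 1e-5)

  expect_error(tost(rep(1, 10), rep(1, 10)), "degenerate")
  expect_error(tost(1, rnorm(5)), "at least 2")
})

test_that("TOST pass/fail equals the CI-inclusion oracle on random data", {
  set.seed(442)
  for (i in 1:30) {
    n1 <- sample(10:60, 1); n2 <- sample(10:60, 1)
    lt <- rnorm(n1, runif(1, -0.4, 0.4), runif(1, 0.2, 0.8))
    lr <- rnorm(n2, 0, runif(1, 0.2, 0.8))
    res <- tost(lt, lr)
    # independent oracle: standard two-sample pooled CI via t.test
    ci <- stats::t.test(lt, lr, var.equal = TRUE,
                        conf.level = 0.90)$conf.int
    oracle_pass <- exp(ci[1]) >= 0.8 && exp(ci[2]) <= 1.25
    expect_identical(res$pass, oracle_pass)
    expect_equal(res$ci, exp(as.numeric(ci)), tolerance = 1e-12)
  }
})

test_that("workflow A passes duplicated arms and fails a 1.5-fold shift", {
  pop <- default_population()
  pop$sigma2_resid <- 1e-6
  ds <- simulate_trial(trial_design(n_per_arm = 40, seed = 43,
                                    arms = "reference"), pop)
  dup <- ds[ds$arm == "reference", ]
  dup$arm <- "test"
  dup$subject <- sub("^R", "T", dup$subject)
  both <- rbind(ds, dup)
  class(both) <- class(ds)
  attr(both, "design") <- attr(ds, "design")
  expect_true(be_workflow_A(both)$pass)

  shifted <- both
  shifted$conc[shifted$arm == "test"] <-
    1.5 * shifted$conc[shifted$arm == "test"]
  dec <- be_workflow_A(shifted)
  expect_false(dec$pass)
  expect_equal(dec$cmax$gmr, 1.5, tolerance = 1e-6)
})

test_that("a large trial under the recalibrated shift yields a coherent verdict", {
  pop <- default_population(delta = c(1, 1.42, 1, 1, 1, 1))
  ds <- simulate_trial(trial_design(n_per_arm = 130, seed = 44), pop)
  dec <- be_workflow_A(ds)
  for (m in list(dec$cmax, dec$auc)) {
    expect_true(m$ci[1] <= m$gmr && m$gmr <= m$ci[2])
    expect_identical(m$pass,
                     m$ci[1] >= 0.8 && m$ci[2] <= 1.25)
  }
  expect_identical(dec$pass, dec$cmax$pass && dec$auc$pass)
})

test_that("posterior-predictive ratios concentrate near 1 under a null shift", {
  set.seed(445)
  pop <- default_population()
  ratios <- posterior_predictive_ratios(1, pop, n_trials = 10,
                                        n_per_arm = 1000)
  expect_equal(nrow(ratios), 10)
  expect_gte(mean(abs(log(ratios$d_cmax)) < 0.05), 0.9)
  expect_gte(mean(abs(log(ratios$d_auc)) < 0.05), 0.9)
  expect_error(posterior_predictive_ratios(-1, pop), "invalid")
  expect_error(posterior_predictive_ratios(list(gm = 1, gsd = 0.5), pop),
               "invalid")
})

test_that("the workflow-B decision rule is a simple empirical probability", {
  mix <- data.frame(delta2 = 1,
                    d_cmax = c(rep(1.3, 100), rep(1.0, 100)),
                    d_auc = c(rep(1.3, 100), rep(1.0, 100)))
  class(mix) <- c("ratio_samples", "data.frame")
  dec <- be_workflow_B(mix)
  expect_equal(dec$p_be, 0.5)
  expect_false(dec$pass)
  expect_equal(dec$p_cmax_above, 0.5)

  ones <- data.frame(delta2 = 1, d_cmax = rep(1, 150), d_auc = rep(1, 150))
  class(ones) <- c("ratio_samples", "data.frame")
  expect_true(be_workflow_B(ones)$pass)
  expect_equal(be_workflow_B(ones)$p_be, 1)

  # invariance to draw order
  perm <- mix[sample(nrow(mix)), ]
  expect_equal(be_workflow_B(perm)$p_be, dec$p_be)

  expect_error(be_workflow_B(ones[1:50, ]), ">= 100")
})

test_that("power declines monotonically from the null toward a limit", {
  pop <- default_population()
  des <- trial_design(n_per_arm = 90)
  pf <- vapply(c(1.0, 1.1, 1.25), function(g) {
    des$seed <- 446
    power_type1(des, pop, placement = "gmr", true_gmr = g,
                n_reps = 60)$pass_fraction
  }, numeric(1))
  se <- sqrt(pmax(pf * (1 - pf), 0.25 / 60) / 60)
  expect_gte(pf[1] + 2 * se[1], pf[2])
  expect_gte(pf[2] + 2 * se[2], pf[3])
  expect_gt(pf[1], 0.4)
  expect_lt(pf[3], 0.2)
})

test_that("a grossly inequivalent formulation never passes", {
  pop <- default_population()
  res <- power_type1(trial_design(n_per_arm = 25, seed = 447), pop,
                     placement = "gmr", true_gmr = 2, n_reps = 20)
  expect_equal(res$pass_fraction, 0)
})

test_that("sensitivity ranking isolates the active release pathways", {
  pop <- default_population()
  # PP3M parameters have no pathway under a PP1M-only regimen
  reg1 <- dosing_regimen(c(0, 28, 56), 150, "PP1M")
  rk1 <- sensitivity_ranking(pop, reg1, interval = c(56, 84))
  expect_equal(rk1$pct_cmax, rep(0, 6), tolerance = 1e-8)
  expect_equal(rk1$pct_auc, rep(0, 6), tolerance = 1e-8)

  # under the default regimen the slow-depot maximum rate dominates
  rk <- sensitivity_ranking(pop)
  expect_equal(nrow(rk), 6)
  expect_equal(rk$parameter[1], "kas3_max")
  # a 5% shift moves exposures by a few percent, nowhere near 38%
  d2 <- rk[rk$parameter == "kas3_max", ]
  expect_gt(abs(d2$pct_cmax), 0.5)
  expect_lt(abs(d2$pct_cmax), 10)
})

test_that("the fuzzy safe-space map reduces to power at a frozen delta", {
  pop <- default_population()
  des <- trial_design(n_per_arm = 30, seed = 448)
  map <- safe_space_A(pop, des, n_trials = 12, delta_low = 1,
                      delta_high = 1)
  expect_equal(nrow(map), 12)
  expect_true(all(map$delta_f3 == 1))
  des$seed <- 448
  pw <- power_type1(des, pop, placement = "null", n_reps = 20)
  expect_equal(mean(map$pass), pw$pass_fraction, tolerance = 0.35)

  set.seed(449)
  des$seed <- NULL
  wide <- safe_space_A(pop, des, n_trials = 25)
  far <- wide$gmr_cmax > 1.6 | wide$gmr_auc > 1.6 |
    wide$gmr_cmax < 1 / 1.6 | wide$gmr_auc < 1 / 1.6
  expect_true(all(!wide$pass[far]))
})

test_that("the crisp safe space contains the identity point", {
  set.seed(450)
  pop <- default_population()
  map <- safe_space_B(pop, delta1 = 1, delta2 = 1, n_trials = 4,
                      n_per_arm = 60)
  expect_true(map$pass[1])
  expect_equal(map$d_cmax[1], 1, tolerance = 0.15)
})
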