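# Shared fixtures and the independent deSolve oracle used to cross-check
# the package's compiled integrator.

test_subject <- function(...) {
  args <- modifyList(list(f1 = 0.15, tl1 = 7, ka1 = 0.02, f3 = 0.15,
                          kar3_max = 8, kar3_50 = 100, kas3_max = 5,
                          kas3_50 = 300, gamma = 1.3, CL = 120, V = 400,
                          Qc0 = 30), list(...))
  do.call(subject_params, args)
}

single_pp3m <- function(dose = 525) dosing_regimen(0, dose, "PP3M")
single_pp1m <- function(dose = 150) dosing_regimen(0, dose, "PP1M")

# small fast trial design for unit tests (short horizon would change the
# science; instead keep the standard regimen but few subjects)
small_design <- function(n = 5, seed = NULL) {
  trial_design(n_per_arm = n, seed = seed)
}

# Independent reference solution via deSolve: same model equations written
# as an R right-hand side, integrated segment-by-segment with lsoda at
# tight tolerance.  Depot bookkeeping mirrors the package's convention
# (full PP1M dose enters the fast depot, the (1 - f1) share transfers to
# the first-order depot when the zero-order window closes).
desolve_profile <- function(params, regimen, times, rtol = 1e-10,
                            atol = 1e-12) {
  p <- params
  acts <- list()
  for (j in seq_len(nrow(regimen))) {
    tj <- regimen$time[j]; D <- regimen$dose[j]
    if (regimen$formulation[j] == "PP1M") {
      r <- p$f1 * D / p$tl1
      acts[[length(acts) + 1]] <- list(time = tj, dy = c(D, 0, 0, 0),
                                       dr = r)
      acts[[length(acts) + 1]] <- list(time = tj + p$tl1,
                                       dy = c(-(1 - p$f1) * D,
                                              (1 - p$f1) * D, 0, 0),
                                       dr = -r)
    } else {
      acts[[length(acts) + 1]] <- list(time = tj,
                                       dy = c(0, 0, p$f3 * D,
                                              (1 - p$f3) * D), dr = 0)
    }
  }
  acts <- acts[order(vapply(acts, `[[`, numeric(1), "time"))]
  rhs <- function(t, y, parms) {
    rel0 <- parms$r0
    rel1 <- p$ka1 * y[2]
    relr <- p$kar3_max * y[3] / (p$kar3_50 + y[3])
    rels <- p$kas3_max * y[4]^p$gamma / (p$kas3_50^p$gamma + y[4]^p$gamma)
    kel <- p$CL / p$V
    list(c(-rel0, -rel1, -relr, -rels,
           rel0 + rel1 + relr + rels - kel * y[5],
           y[5] / p$V * 1000, kel * y[5]))
  }
  y <- c(0, 0, 0, 0, p$Qc0, 0, 0)
  t <- 0; r0 <- 0; ia <- 1
  out <- matrix(NA_real_, length(times), 7)
  it <- 1
  apply_acts <- function(tcur) {
    while (ia <= length(acts) && acts[[ia]]$time <= tcur + 1e-12) {
      y[1:4] <<- y[1:4] + acts[[ia]]$dy
      r0 <<- r0 + acts[[ia]]$dr
      ia <<- ia + 1
    }
  }
  apply_acts(0)
  while (it <= length(times) && times[it] <= 0) {
    out[it, ] <- y; it <- it + 1
  }
  repeat {
    t_act <- if (ia <= length(acts)) acts[[ia]]$time else Inf
    t_out <- if (it <= length(times)) times[it] else Inf
    tstop <- min(t_act, t_out)
    if (!is.finite(tstop)) break
    if (tstop > t) {
      sol <- deSolve::lsoda(y, c(t, tstop), rhs, parms = list(r0 = r0),
                            rtol = rtol, atol = atol)
      y <- as.numeric(sol[nrow(sol), -1])
      t <- tstop
    }
    apply_acts(t)
    while (it <= length(times) && times[it] <= t + 1e-12) {
      out[it, ] <- y; it <- it + 1
    }
  }
  data.frame(time = times, conc = out[, 5] / p$V * 1000,
             Qdepot1_fast = out[, 1], Qdepot1_slow = out[, 2],
             Qdepot_r3 = out[, 3], Qdepot_s3 = out[, 4],
             Qcentral = out[, 5], AUCstate = out[, 6], Qelim = out[, 7])
}

# random but valid subject and regimen generators for property tests
random_subject <- function() {
  test_subject(f1 = runif(1, 0.05, 0.9), ka1 = exp(runif(1, log(0.005),
                                                         log(0.08))),
               f3 = runif(1, 0.05, 0.9),
               kar3_max = exp(runif(1, log(2), log(30))),
               kar3_50 = exp(runif(1, log(30), log(500))),
               kas3_max = exp(runif(1, log(1), log(15))),
               kas3_50 = exp(runif(1, log(50), log(1000))),
               gamma = runif(1, 1, 2.5),
               CL = exp(runif(1, log(50), log(300))),
               V = exp(runif(1, log(150), log(800))),
               Qc0 = exp(runif(1, log(5), log(100))))
}

random_regimen <- function() {
  n1 <- sample(1:4, 1); n3 <- sample(1:4, 1)
  t1 <- sort(sample(seq(0, 90, by = 14), n1))
  t3 <- sort(90 + cumsum(sample(c(60, 91, 120), n3, replace = TRUE)))
  dosing_regimen(c(t1, t3),
                 c(runif(n1, 50, 150), runif(n3, 175, 525)),
                 c(rep("PP1M", n1), rep("PP3M", n3)))
}
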