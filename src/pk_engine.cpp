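// Structural PK engine for joint PP1M / PP3M long-acting injectable
// kinetics, plus the Metropolis-Hastings sampler used for formulation-shift
// recalibration.  Everything that sits inside hot simulation loops lives
// here; R-level wrappers add validation and bookkeeping.
//
// State vector (amounts in mg eq., time in days):
//   0 Qfast  : PP1M depot amount under zero-order release (holds the full
//              dose until the zero-order window ends; the non-released
//              (1-f1) share then transfers to the first-order depot)
//   1 Qslow  : PP1M first-order depot
//   2 Qr3    : PP3M rapid saturable depot
//   3 Qs3    : PP3M slow saturable (Hills) depot
//   4 Qc     : central compartment
//   5 AUC    : running integral of concentration (ng/mL * day)
//   6 Qelim  : cumulative eliminated amount (mass-balance auxiliary)
//
// Concentration (ng/mL) = Qc / V * 1000   (Qc mg, V L).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const int NSTATE = 7;
static const double NEG_TOL = 1e-9;  // states below -NEG_TOL are an error

struct PKParams {
  double f1, tl1, ka1;
  double f3, kar3_max, kar3_50, kas3_max, kas3_50, gamma;
  double CL, V, Qc0;
};

// piecewise-constant zero-order release rate handled per segment
struct PKAction {          // instantaneous state change at a time point
  double time;
  double dQfast, dQslow, dQr3, dQs3;
  double dRate0;           // change in total zero-order release rate
};

static inline void pk_rhs(const double *y, double *dy, const PKParams &p,
                          double rate0) {
  double rel0 = rate0;                         // zero-order PP1M release
  double rel1 = p.ka1 * y[1];                  // first-order PP1M release
  double qr = y[2] > 0.0 ? y[2] : 0.0;
  double qs = y[3] > 0.0 ? y[3] : 0.0;
  double relr = p.kar3_max * qr / (p.kar3_50 + qr);
  double qsg = std::pow(qs, p.gamma);
  double rels = p.kas3_max * qsg / (std::pow(p.kas3_50, p.gamma) + qsg);
  double kel = p.CL / p.V;
  dy[0] = -rel0;
  dy[1] = -rel1;
  dy[2] = -relr;
  dy[3] = -rels;
  dy[4] = rel0 + rel1 + relr + rels - kel * y[4];
  dy[5] = y[4] / p.V * 1000.0;                 // concentration in ng/mL
  dy[6] = kel * y[4];
}

// Dormand-Prince 5(4) with FSAL, adaptive step, hard stop at tstop.
// Returns false on non-finite state.
static bool dp45_advance(double *y, double t0, double tstop,
                         const PKParams &p, double rate0,
                         double rtol, double atol, double &terr) {
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                      c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695,
                      e4 = 71.0 / 1920, e5 = -17253.0 / 339200,
                      e6 = 22.0 / 525, e7 = -1.0 / 40;

  double t = t0;
  double h = std::min(1.0, tstop - t0);
  if (h <= 0.0) return true;
  double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], k5[NSTATE],
      k6[NSTATE], k7[NSTATE], yt[NSTATE], ynew[NSTATE];
  pk_rhs(y, k1, p, rate0);
  int n_reject = 0;
  while (t < tstop - 1e-12 * std::max(1.0, tstop)) {
    if (h > tstop - t) h = tstop - t;
    for (int i = 0; i < NSTATE; ++i) yt[i] = y[i] + h * a21 * k1[i];
    pk_rhs(yt, k2, p, rate0);
    for (int i = 0; i < NSTATE; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    pk_rhs(yt, k3, p, rate0);
    for (int i = 0; i < NSTATE; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    pk_rhs(yt, k4, p, rate0);
    for (int i = 0; i < NSTATE; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                          a54 * k4[i]);
    pk_rhs(yt, k5, p, rate0);
    for (int i = 0; i < NSTATE; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    pk_rhs(yt, k6, p, rate0);
    for (int i = 0; i < NSTATE; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    pk_rhs(ynew, k7, p, rate0);
    double errnorm = 0.0;
    for (int i = 0; i < NSTATE; ++i) {
      double err = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                        e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = err / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / NSTATE);
    if (!std::isfinite(errnorm)) { terr = t; return false; }
    if (errnorm <= 1.0) {
      t += h;
      for (int i = 0; i < NSTATE; ++i) {
        y[i] = ynew[i];
        k1[i] = k7[i];                        // FSAL
        if (!std::isfinite(y[i])) { terr = t; return false; }
      }
      n_reject = 0;
    } else {
      if (++n_reject > 50) { terr = t; return false; }
    }
    double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h < 1e-10) h = 1e-10;
  }
  return true;
}

static std::vector<PKAction> build_actions(const PKParams &p,
                                           const NumericMatrix &events) {
  std::vector<PKAction> acts;
  for (int j = 0; j < events.nrow(); ++j) {
    double tj = events(j, 0), dose = events(j, 1);
    int type = (int)events(j, 2);
    if (dose < 0.0) stop("dose amounts must be non-negative");
    if (dose == 0.0) continue;
    if (type == 1) {
      double rate = p.f1 * dose / p.tl1;
      PKAction a1 = {tj, dose, 0.0, 0.0, 0.0, rate};
      PKAction a2 = {tj + p.tl1, -(1.0 - p.f1) * dose,
                     (1.0 - p.f1) * dose, 0.0, 0.0, -rate};
      acts.push_back(a1);
      acts.push_back(a2);
    } else if (type == 3) {
      PKAction a = {tj, 0.0, 0.0, p.f3 * dose, (1.0 - p.f3) * dose, 0.0};
      acts.push_back(a);
    } else {
      stop("unknown formulation code %d (expected 1 or 3)", type);
    }
  }
  std::sort(acts.begin(), acts.end(),
            [](const PKAction &a, const PKAction &b) { return a.time < b.time; });
  return acts;
}

static void clamp_states(double *y, double t) {
  for (int i = 0; i < NSTATE; ++i) {
    if (y[i] < 0.0) {
      if (y[i] < -NEG_TOL)
        stop("state violation: component %d = %g at t = %g", i + 1, y[i], t);
      y[i] = 0.0;
    }
  }
}

// Core solve: states (post-event convention at event times) at `times`.
// `out` must be length(times) x NSTATE, row-major fill via Rcpp matrix.
static void pk_solve_core(const PKParams &p, const NumericMatrix &events,
                          const NumericVector &times, double rtol,
                          double atol, NumericMatrix &out) {
  int nt = times.size();
  for (int i = 1; i < nt; ++i)
    if (times[i] < times[i - 1]) stop("output times must be non-decreasing");
  if (nt > 0 && times[0] < 0.0) stop("output times must be >= 0");

  std::vector<PKAction> acts = build_actions(p, events);
  double y[NSTATE] = {0, 0, 0, 0, p.Qc0, 0, 0};
  double t = 0.0, rate0 = 0.0, terr = 0.0;
  size_t ia = 0;
  int it = 0;

  // apply actions at t = 0 before anything else
  while (ia < acts.size() && acts[ia].time <= 0.0) {
    y[0] += acts[ia].dQfast; y[1] += acts[ia].dQslow;
    y[2] += acts[ia].dQr3;   y[3] += acts[ia].dQs3;
    rate0 += acts[ia].dRate0;
    ++ia;
  }
  clamp_states(y, t);
  while (it < nt && times[it] <= 0.0) {
    for (int s = 0; s < NSTATE; ++s) out(it, s) = y[s];
    ++it;
  }

  while (it < nt || ia < acts.size()) {
    double t_next_act = ia < acts.size() ? acts[ia].time : R_PosInf;
    double t_next_out = it < nt ? times[it] : R_PosInf;
    double tstop = std::min(t_next_act, t_next_out);
    if (!std::isfinite(tstop)) break;
    if (tstop > t) {
      if (!dp45_advance(y, t, tstop, p, rate0, rtol, atol, terr))
        stop("integration failure: non-finite state near t = %g", terr);
      t = tstop;
      clamp_states(y, t);
    }
    // events first (post-event convention), then record outputs at t
    while (ia < acts.size() && acts[ia].time <= t + 1e-12) {
      y[0] += acts[ia].dQfast; y[1] += acts[ia].dQslow;
      y[2] += acts[ia].dQr3;   y[3] += acts[ia].dQs3;
      rate0 += acts[ia].dRate0;
      ++ia;
    }
    clamp_states(y, t);
    while (it < nt && times[it] <= t + 1e-12) {
      for (int s = 0; s < NSTATE; ++s) out(it, s) = y[s];
      ++it;
    }
  }
}

static PKParams params_from_vector(const NumericVector &pv) {
  if (pv.size() != 12) stop("parameter vector must have length 12");
  PKParams p;
  p.f1 = pv[0]; p.tl1 = pv[1]; p.ka1 = pv[2]; p.f3 = pv[3];
  p.kar3_max = pv[4]; p.kar3_50 = pv[5]; p.kas3_max = pv[6];
  p.kas3_50 = pv[7]; p.gamma = pv[8]; p.CL = pv[9]; p.V = pv[10];
  p.Qc0 = pv[11];
  return p;
}

// [[Rcpp::export(name = ".pk_solve_cpp")]]
NumericMatrix pk_solve_cpp(NumericVector params, NumericMatrix events,
                           NumericVector times, double rtol = 1e-8,
                           double atol = 1e-10) {
  PKParams p = params_from_vector(params);
  NumericMatrix out(times.size(), NSTATE);
  pk_solve_core(p, events, times, rtol, atol, out);
  return out;
}

// Batched solve: one row of `params` per subject (same column order as
// pk_solve_cpp), shared events and output times; returns concentrations
// (ng/mL), subjects in rows.
// [[Rcpp::export(name = ".pk_conc_batch_cpp")]]
NumericMatrix pk_conc_batch_cpp(NumericMatrix params, NumericMatrix events,
                                NumericVector times, double rtol = 1e-8,
                                double atol = 1e-10) {
  int n = params.nrow(), nt = times.size();
  NumericMatrix out(n, nt);
  NumericMatrix st(nt, NSTATE);
  for (int i = 0; i < n; ++i) {
    PKParams p = params_from_vector(params(i, _));
    pk_solve_core(p, events, times, rtol, atol, st);
    for (int j = 0; j < nt; ++j) out(i, j) = st(j, 4) / p.V * 1000.0;
  }
  return out;
}

// Batched model-integrated exposures: Cmax on the supplied grid and the
// partial AUC from the augmented state between the first and last grid
// point.  Returns a (subjects x 2) matrix [cmax, auc].
// [[Rcpp::export(name = ".pk_exposure_batch_cpp")]]
NumericMatrix pk_exposure_batch_cpp(NumericMatrix params,
                                    NumericMatrix events,
                                    NumericVector grid, double rtol = 1e-8,
                                    double atol = 1e-10) {
  int n = params.nrow(), nt = grid.size();
  NumericMatrix out(n, 2);
  NumericMatrix st(nt, NSTATE);
  for (int i = 0; i < n; ++i) {
    PKParams p = params_from_vector(params(i, _));
    pk_solve_core(p, events, grid, rtol, atol, st);
    double cmax = 0.0;
    for (int j = 0; j < nt; ++j) {
      double c = st(j, 4) / p.V * 1000.0;
      if (c > cmax) cmax = c;
    }
    out(i, 0) = cmax;
    out(i, 1) = st(nt - 1, 5) - st(0, 5);
  }
  return out;
}

// -------------------------------------------------------------------------
// Hierarchical model pieces shared by log-posterior and the sampler.
//
// Subject latent vector z (all on the log scale):
//   0 log kappa_f1, 1 log kappa_f3, 2 log ka1, 3 log kar3_50,
//   4 log kas3_max, 5 log kas3_50, 6 log CL, 7 log V, 8 log Qc0
// kappa -> fraction via the configured transform.

static inline double frac_transform(double kappa, int transform) {
  if (transform == 0) return 1.0 / (1.0 + std::exp(-kappa));  // paper_logistic
  return kappa / (1.0 + kappa);                               // odds_ratio
}

static void subject_params_from_latent(const double *z, double tl1,
                                       double kar3_max, double gamma,
                                       int transform, PKParams &p) {
  p.f1 = frac_transform(std::exp(z[0]), transform);
  p.tl1 = tl1;
  p.ka1 = std::exp(z[2]);
  p.f3 = frac_transform(std::exp(z[1]), transform);
  p.kar3_max = kar3_max;
  p.kar3_50 = std::exp(z[3]);
  p.kas3_max = std::exp(z[4]);
  p.kas3_50 = std::exp(z[5]);
  p.gamma = gamma;
  p.CL = std::exp(z[6]);
  p.V = std::exp(z[7]);
  p.Qc0 = std::exp(z[8]);
}

// measurement log-likelihood of one subject given latent z
static double subject_loglik(const double *z, const NumericVector &obs_t,
                             const NumericVector &obs_logc, double tl1,
                             double kar3_max, double gamma, int transform,
                             const NumericMatrix &events, double sigma,
                             double rtol, double atol) {
  int n = obs_t.size();
  if (n == 0) return 0.0;
  PKParams p;
  subject_params_from_latent(z, tl1, kar3_max, gamma, transform, p);
  NumericMatrix out(n, NSTATE);
  try {
    pk_solve_core(p, events, obs_t, rtol, atol, out);
  } catch (...) {
    return R_NegInf;
  }
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double conc = out(i, 4) / p.V * 1000.0;
    if (!(conc > 0.0) || !std::isfinite(conc)) return R_NegInf;
    // lognormal density of the observed concentration (Jacobian included)
    ll += R::dnorm(obs_logc[i], std::log(conc), sigma, 1) - obs_logc[i];
  }
  return ll;
}

static inline double subject_logprior(const double *z, int arm,
                                      const NumericVector &prior_mean,
                                      const NumericVector &prior_sd,
                                      double log_delta2) {
  double lp = 0.0;
  for (int j = 0; j < 9; ++j) {
    double m = prior_mean[j];
    if (arm == 1 && j == 4) m += log_delta2;  // shifted kas3_max location
    lp += R::dnorm(z[j], m, prior_sd[j], 1);
  }
  return lp;
}

// [[Rcpp::export(name = ".log_posterior_cpp")]]
List log_posterior_cpp(double delta2, NumericMatrix subj_latent,
                       IntegerVector subj_arm, List obs_t_by_subj,
                       List obs_logc_by_subj, NumericMatrix events,
                       double tl1, double kar3_max, double gamma,
                       int transform, NumericVector prior_mean,
                       NumericVector prior_sd, double sigma,
                       double d2_prior_meanlog, double d2_prior_sdlog,
                       double rtol = 1e-8, double atol = 1e-10) {
  int n_subj = subj_latent.nrow();
  if (!(delta2 > 0.0)) stop("delta2 must be positive");
  double logd = std::log(delta2);
  double loglik = 0.0, logprior = 0.0;
  for (int i = 0; i < n_subj; ++i) {
    double z[9];
    for (int j = 0; j < 9; ++j) z[j] = subj_latent(i, j);
    NumericVector ot = obs_t_by_subj[i];
    NumericVector oc = obs_logc_by_subj[i];
    loglik += subject_loglik(z, ot, oc, tl1, kar3_max, gamma, transform,
                             events, sigma, rtol, atol);
    logprior += subject_logprior(z, subj_arm[i], prior_mean, prior_sd, logd);
  }
  double logprior_d2 = R::dnorm(logd, d2_prior_meanlog, d2_prior_sdlog, 1);
  return List::create(_["loglik"] = loglik, _["logprior_subj"] = logprior,
                      _["logprior_delta2"] = logprior_d2,
                      _["total"] = loglik + logprior + logprior_d2);
}

// [[Rcpp::export(name = ".run_mcmc_cpp")]]
List run_mcmc_cpp(List obs_t_by_subj, List obs_logc_by_subj,
                  IntegerVector subj_arm, NumericMatrix events, double tl1,
                  double kar3_max, double gamma, int transform,
                  NumericVector prior_mean, NumericVector prior_sd,
                  double sigma, double d2_prior_meanlog,
                  double d2_prior_sdlog, int n_chains, int n_iter,
                  int n_burnin, bool sample_subjects,
                  NumericMatrix init_latent, double scale_subj0,
                  double scale_d20, double rtol = 1e-8,
                  double atol = 1e-10) {
  int n_subj = subj_arm.size();
  int n_keep = n_iter - n_burnin;
  if (n_keep <= 0) stop("n_burnin must be smaller than n_iter");
  RNGScope scope;

  List chains(n_chains);
  NumericVector acc_d2(n_chains), acc_subj(n_chains);

  for (int c = 0; c < n_chains; ++c) {
    // state
    std::vector<double> z(9 * n_subj);
    for (int i = 0; i < n_subj; ++i)
      for (int j = 0; j < 9; ++j) z[9 * i + j] = init_latent(i, j);
    double logd = 0.0;
    if (sample_subjects) {
      // over-dispersed starts: jitter subjects and delta2
      for (int i = 0; i < n_subj; ++i)
        for (int j = 0; j < 9; ++j)
          z[9 * i + j] += 0.3 * prior_sd[j] * R::norm_rand();
    }
    logd += 0.3 * R::norm_rand();

    std::vector<double> loglik(n_subj), logpri(n_subj);
    for (int i = 0; i < n_subj; ++i) {
      NumericVector ot = obs_t_by_subj[i], oc = obs_logc_by_subj[i];
      loglik[i] = subject_loglik(&z[9 * i], ot, oc, tl1, kar3_max, gamma,
                                 transform, events, sigma, rtol, atol);
      logpri[i] = subject_logprior(&z[9 * i], subj_arm[i], prior_mean,
                                   prior_sd, logd);
    }
    double lp_d2 = R::dnorm(logd, d2_prior_meanlog, d2_prior_sdlog, 1);

    std::vector<double> scale_subj(n_subj, scale_subj0);
    double scale_d2 = scale_d20;
    std::vector<int> acc_win(n_subj, 0);
    int accd_win = 0, win = 0;
    long n_acc_subj = 0, n_prop_subj = 0, n_acc_d2 = 0;

    NumericMatrix draws(n_keep, 1 + 9 * n_subj);

    for (int iter = 0; iter < n_iter; ++iter) {
      if (iter % 200 == 0) Rcpp::checkUserInterrupt();
      if (sample_subjects) {
        for (int i = 0; i < n_subj; ++i) {
          double zp[9];
          for (int j = 0; j < 9; ++j)
            zp[j] = z[9 * i + j] + scale_subj[i] * R::norm_rand();
          NumericVector ot = obs_t_by_subj[i], oc = obs_logc_by_subj[i];
          double llp = subject_loglik(zp, ot, oc, tl1, kar3_max, gamma,
                                      transform, events, sigma, rtol, atol);
          double lpp = subject_logprior(zp, subj_arm[i], prior_mean,
                                        prior_sd, logd);
          double ratio = (llp + lpp) - (loglik[i] + logpri[i]);
          ++n_prop_subj;
          if (std::isfinite(ratio) && std::log(R::unif_rand()) < ratio) {
            for (int j = 0; j < 9; ++j) z[9 * i + j] = zp[j];
            loglik[i] = llp; logpri[i] = lpp;
            ++n_acc_subj; ++acc_win[i];
          }
        }
      }
      // delta2 block: only the test-arm population terms + prior involved
      {
        double logdp = logd + scale_d2 * R::norm_rand();
        double cur = lp_d2, prop = R::dnorm(logdp, d2_prior_meanlog,
                                            d2_prior_sdlog, 1);
        std::vector<double> logpri_p(n_subj);
        double dcur = 0.0, dprop = 0.0;
        for (int i = 0; i < n_subj; ++i) {
          if (subj_arm[i] == 1) {
            logpri_p[i] = subject_logprior(&z[9 * i], 1, prior_mean,
                                           prior_sd, logdp);
            dcur += logpri[i]; dprop += logpri_p[i];
          } else logpri_p[i] = logpri[i];
        }
        double ratio = (prop + dprop) - (cur + dcur);
        if (std::isfinite(ratio) && std::log(R::unif_rand()) < ratio) {
          logd = logdp; lp_d2 = prop;
          for (int i = 0; i < n_subj; ++i) logpri[i] = logpri_p[i];
          ++n_acc_d2; ++accd_win;
        }
      }
      ++win;
      // proposal adaptation during burn-in only (target ~30% acceptance)
      if (iter < n_burnin && win == 50) {
        for (int i = 0; i < n_subj; ++i) {
          double r = acc_win[i] / 50.0;
          scale_subj[i] *= std::exp(0.8 * (r - 0.3));
          scale_subj[i] = std::min(5.0, std::max(1e-4, scale_subj[i]));
          acc_win[i] = 0;
        }
        double rd = accd_win / 50.0;
        scale_d2 *= std::exp(0.8 * (rd - 0.3));
        scale_d2 = std::min(5.0, std::max(1e-4, scale_d2));
        accd_win = 0;
        win = 0;
      }
      if (iter >= n_burnin) {
        int k = iter - n_burnin;
        draws(k, 0) = std::exp(logd);
        for (int i = 0; i < 9 * n_subj; ++i) draws(k, 1 + i) = z[i];
      }
    }
    chains[c] = draws;
    acc_d2[c] = (double)n_acc_d2 / n_iter;
    acc_subj[c] = n_prop_subj > 0 ? (double)n_acc_subj / n_prop_subj : NA_REAL;
  }
  return List::create(_["chains"] = chains, _["accept_delta2"] = acc_d2,
                      _["accept_subjects"] = acc_subj);
}
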