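// Compiled simulation core: conductance-based LIF populations, saturating
// synaptic activations (fast and slow channel per neuron), exponential rate
// filters, dopamine reinforcement, two-trace eligibility plasticity and the
// synchronous network update loop.  The single-step kernels exported here are
// the same routines the session loop calls, so the R-level operations and the
// compiled session path share one implementation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// parameter vector layout (see R/neuron.R)
enum Par { P_C = 0, P_GL, P_EL, P_EE, P_EI, P_VTH, P_VRESET, P_TREF,
           P_TAU_SF, P_TAU_SS, P_RHO, P_RHO_SLOW, P_SIGMA, P_TAU_R, P_TONIC,
           P_NPAR };

// rule codes for projections
// dTTL with per-synapse traces (VTA or gated PFC variant), the
// dopamine-modulated Hebbian rule, and the population-level PFC variant
// used for the recurrent Timer pathway: one scalar trace pair driven by the
// population-mean rate product, applied as a uniform shift of the whole
// weight matrix (per-synapse heterogeneity preserved from initialization).
enum Rule { R_FIXED = 0, R_DTTL_VTA = 1, R_DTTL_PFC = 2, R_DA_HEBB = 3,
            R_DTTL_PFC_SCALAR = 4 };

static inline double dopamine_pw(double rda, double r0, double theta) {
  if (rda >= r0 + theta) return rda - (r0 + theta);
  if (rda <= r0 - theta) return rda - (r0 - theta);
  return 0.0;
}

// forward-Euler membrane update; spikes at threshold crossing, reset +
// absolute refractory clamp at vreset.  Noise is white current noise whose
// per-step voltage increment has s.d. sigma*sqrt(dt)/C (step-size invariant).
// `tonic_extra` is an optional per-neuron offset added to the common tonic
// current (used for heterogeneous excitability within a population).
static void lif_step_(arma::vec& v, arma::vec& ref_until,
                      arma::ivec& spikes,
                      const arma::vec& gE, const arma::vec& gI,
                      const arma::vec& par, double t, double dt,
                      bool with_noise,
                      const arma::vec* tonic_extra = nullptr) {
  const double C = par[P_C], gL = par[P_GL], EL = par[P_EL], EE = par[P_EE],
               EI = par[P_EI], vth = par[P_VTH], vreset = par[P_VRESET],
               tref = par[P_TREF], sigma = par[P_SIGMA], tonic = par[P_TONIC];
  const double sdt = std::sqrt(dt);
  const int n = v.n_elem;
  for (int i = 0; i < n; ++i) {
    spikes[i] = 0;
    if (t < ref_until[i]) { v[i] = vreset; continue; }
    double I = gL * (EL - v[i]) + gE[i] * (EE - v[i]) + gI[i] * (EI - v[i]) +
               tonic + (tonic_extra ? (*tonic_extra)[i] : 0.0);
    double dv = dt * I / C;
    if (with_noise && sigma > 0.0) dv += sigma * sdt / C * R::norm_rand();
    v[i] += dv;
    if (!std::isfinite(v[i]))
      stop("non-finite membrane potential at neuron %d (t = %.2f ms)", i + 1, t);
    if (v[i] >= vth) {
      spikes[i] = 1;
      v[i] = vreset;
      ref_until[i] = t + tref;
    }
  }
}

// saturating synaptic activation: exponential decay, jump by rho*(1-s) on
// spike; the update form keeps s in [0, 1].
static void syn_step_(arma::vec& s, const arma::ivec& spikes,
                      double tau, double rho, double dt) {
  const int n = s.n_elem;
  for (int i = 0; i < n; ++i) {
    s[i] -= dt * s[i] / tau;
    if (spikes[i]) s[i] += rho * (1.0 - s[i]);
  }
}

// exponential rate filter with unit area in Hz*s: each spike adds 1000/tau_r
// (tau_r in ms), so a stationary Poisson train at f Hz averages to f.
static void rate_step_(arma::vec& r, const arma::ivec& spikes,
                       double tau_r, double dt) {
  const int n = r.n_elem;
  for (int i = 0; i < n; ++i) {
    r[i] -= dt * r[i] / tau_r;
    if (spikes[i]) r[i] += 1000.0 / tau_r;
  }
}

// saturating eligibility trace: tau*dT/dt = -T + eta*H*(Tmax - T)
static void trace_step_(arma::mat& T, const arma::mat& H,
                        double eta, double tau, double tmax, double dt) {
  T += (dt / tau) * (-T + eta * (H % (tmax - T)));
}

// ---- exported single-step kernels -----------------------------------------

// [[Rcpp::export]]
List cpp_lif_step(NumericVector v, NumericVector ref_until,
                  NumericVector gE, NumericVector gI,
                  NumericVector par, double t, double dt, bool with_noise) {
  arma::vec v_ = as<arma::vec>(v), ref_ = as<arma::vec>(ref_until);
  arma::vec gE_ = as<arma::vec>(gE), gI_ = as<arma::vec>(gI);
  arma::vec par_ = as<arma::vec>(par);
  arma::ivec spk(v_.n_elem, arma::fill::zeros);
  lif_step_(v_, ref_, spk, gE_, gI_, par_, t, dt, with_noise);
  return List::create(_["v"] = v_, _["ref_until"] = ref_,
                      _["spikes"] = spk);
}

// [[Rcpp::export]]
NumericVector cpp_syn_step(NumericVector s, IntegerVector spikes,
                           double tau, double rho, double dt) {
  arma::vec s_ = as<arma::vec>(s);
  arma::ivec spk = as<arma::ivec>(spikes);
  syn_step_(s_, spk, tau, rho, dt);
  return wrap(s_);
}

// [[Rcpp::export]]
NumericVector cpp_rate_step(NumericVector r, IntegerVector spikes,
                            double tau_r, double dt) {
  arma::vec r_ = as<arma::vec>(r);
  arma::ivec spk = as<arma::ivec>(spikes);
  rate_step_(r_, spk, tau_r, dt);
  return wrap(r_);
}

// [[Rcpp::export]]
NumericMatrix cpp_trace_step(NumericMatrix T, NumericMatrix H,
                             double eta, double tau, double tmax, double dt) {
  arma::mat T_ = as<arma::mat>(T), H_ = as<arma::mat>(H);
  trace_step_(T_, H_, eta, tau, tmax, dt);
  return wrap(T_);
}

// [[Rcpp::export]]
NumericVector cpp_dopamine(NumericVector rda, double r0, double theta) {
  const int n = rda.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = dopamine_pw(rda[i], r0, theta);
  return out;
}

// ---- full network loop -----------------------------------------------------

struct ProjC {
  int src, tgt;
  bool inhibitory, use_slow;
  int rule;
  double eta, wmax, alpha;
  double eta_p, eta_d, tau_p, tau_d, tmax_p, tmax_d;
  arma::mat W, Tp, Td;
};

// One synchronous network update per step: conductances -> membranes ->
// spikes -> activations -> rates -> D(t) -> trace and weight updates.
// Runs `n_warm` un-recorded warm-up steps (no events, no learning) so that
// rate filters settle before the trial clock starts at t = 0.
// [[Rcpp::export]]
List cpp_run_network(List state, List group_params, List projections,
                     NumericMatrix events, double dt, int n_steps, int n_warm,
                     bool learning, double r0, double theta, int da_index,
                     int record_stride, double bin_width,
                     IntegerVector bin_groups) {
  const int ng = state.size();
  std::vector<arma::vec> v(ng), sf(ng), ss(ng), r(ng), ref(ng), par(ng);
  std::vector<arma::vec> tonic_extra(ng);
  std::vector<bool> has_extra(ng, false);
  std::vector<arma::ivec> spk(ng);
  std::vector<arma::vec> gE(ng), gI(ng);
  for (int g = 0; g < ng; ++g) {
    List st = state[g];
    v[g] = as<arma::vec>(st["v"]);
    sf[g] = as<arma::vec>(st["s_fast"]);
    ss[g] = as<arma::vec>(st["s_slow"]);
    r[g] = as<arma::vec>(st["r"]);
    ref[g] = as<arma::vec>(st["ref_until"]);
    List gp = group_params[g];
    par[g] = as<arma::vec>(gp["par"]);
    if (gp.containsElementNamed("tonic_extra") &&
        !Rf_isNull(gp["tonic_extra"])) {
      tonic_extra[g] = as<arma::vec>(gp["tonic_extra"]);
      has_extra[g] = true;
    }
    spk[g].zeros(v[g].n_elem);
    gE[g].zeros(v[g].n_elem);
    gI[g].zeros(v[g].n_elem);
  }

  const int np = projections.size();
  std::vector<ProjC> pr(np);
  for (int p = 0; p < np; ++p) {
    List pj = projections[p];
    ProjC& q = pr[p];
    q.src = as<int>(pj["src"]); q.tgt = as<int>(pj["tgt"]);
    q.inhibitory = as<bool>(pj["inhibitory"]);
    q.use_slow = as<bool>(pj["use_slow"]);
    q.rule = as<int>(pj["rule"]);
    q.W = as<arma::mat>(pj["W"]);
    if (q.rule != R_FIXED) {
      q.eta = as<double>(pj["eta"]); q.wmax = as<double>(pj["wmax"]);
      q.alpha = as<double>(pj["alpha"]);
      q.eta_p = as<double>(pj["eta_p"]); q.eta_d = as<double>(pj["eta_d"]);
      q.tau_p = as<double>(pj["tau_p"]); q.tau_d = as<double>(pj["tau_d"]);
      q.tmax_p = as<double>(pj["tmax_p"]); q.tmax_d = as<double>(pj["tmax_d"]);
      q.Tp = as<arma::mat>(pj["Tp"]);
      q.Td = as<arma::mat>(pj["Td"]);
    }
  }

  const int n_ev = events.nrow();
  const int n_rec = n_steps / record_stride;
  arma::mat pop_rates(n_rec, ng, arma::fill::zeros);
  arma::vec D_rec(n_rec, arma::fill::zeros);
  arma::vec t_rec(n_rec, arma::fill::zeros);
  // mean eligibility traces per plastic projection, recorded for diagnostics
  int n_plastic = 0;
  for (int p = 0; p < np; ++p) if (pr[p].rule != R_FIXED) ++n_plastic;
  arma::mat tp_rec(n_rec, n_plastic, arma::fill::zeros);
  arma::mat td_rec(n_rec, n_plastic, arma::fill::zeros);

  const int nbg = bin_groups.size();
  const int n_bins = (int)std::floor(n_steps * dt / bin_width + 1e-9);
  std::vector<arma::mat> counts(nbg);
  for (int b = 0; b < nbg; ++b)
    counts[b].zeros(v[bin_groups[b]].n_elem, std::max(n_bins, 1));

  const int total = n_warm + n_steps;
  for (int step = 0; step < total; ++step) {
    const bool in_trial = step >= n_warm;
    const double t = (step - n_warm) * dt;

    // conductances (Eq: g = W s, per channel)
    for (int g = 0; g < ng; ++g) { gE[g].zeros(); gI[g].zeros(); }
    for (int p = 0; p < np; ++p) {
      const ProjC& q = pr[p];
      const arma::vec& s_pre = q.use_slow ? ss[q.src] : sf[q.src];
      if (q.inhibitory) gI[q.tgt] += q.W * s_pre;
      else              gE[q.tgt] += q.W * s_pre;
    }
    if (in_trial) {
      for (int e = 0; e < n_ev; ++e) {
        if (t >= events(e, 1) && t < events(e, 1) + events(e, 2))
          gE[(int)events(e, 0)] += events(e, 3);
      }
    }

    // membranes, spikes, activations, rates
    for (int g = 0; g < ng; ++g) {
      lif_step_(v[g], ref[g], spk[g], gE[g], gI[g], par[g], t, dt, true,
                has_extra[g] ? &tonic_extra[g] : nullptr);
      syn_step_(sf[g], spk[g], par[g][P_TAU_SF], par[g][P_RHO], dt);
      syn_step_(ss[g], spk[g], par[g][P_TAU_SS], par[g][P_RHO_SLOW], dt);
      rate_step_(r[g], spk[g], par[g][P_TAU_R], dt);
    }

    // global dopamine reinforcement from the DA population mean rate
    const double rda = arma::mean(r[da_index]);
    const double D = dopamine_pw(rda, r0, theta);

    // plasticity (traces + weights), only during the recorded trial
    if (learning && in_trial) {
      for (int p = 0; p < np; ++p) {
        ProjC& q = pr[p];
        if (q.rule == R_FIXED) continue;
        if (q.rule == R_DTTL_PFC_SCALAR) {
          double h = arma::mean(r[q.tgt]) * arma::mean(r[q.src]);
          if (D > 0.0) h /= (1.0 + q.alpha * D);
          double& tp = q.Tp(0, 0);
          double& td = q.Td(0, 0);
          tp += (dt / q.tau_p) * (-tp + q.eta_p * h * (q.tmax_p - tp));
          td += (dt / q.tau_d) * (-td + q.eta_d * h * (q.tmax_d - td));
          if (D != 0.0) {
            q.W += q.eta * D * (tp - td) * dt;
            q.W.clamp(0.0, q.wmax);
          }
          continue;
        }
        arma::mat H = r[q.tgt] * r[q.src].t();
        if (q.rule == R_DA_HEBB) {
          if (D != 0.0) {
            q.W += (q.eta * D * dt) * H;
            q.W.clamp(0.0, q.wmax);
          }
        } else {
          if (q.rule == R_DTTL_PFC && D > 0.0) H /= (1.0 + q.alpha * D);
          trace_step_(q.Tp, H, q.eta_p, q.tau_p, q.tmax_p, dt);
          trace_step_(q.Td, H, q.eta_d, q.tau_d, q.tmax_d, dt);
          if (D != 0.0) {
            q.W += (q.eta * D * dt) * (q.Tp - q.Td);
            q.W.clamp(0.0, q.wmax);
          }
        }
      }
    }

    // recorders
    if (in_trial) {
      const int k = step - n_warm;
      if (nbg > 0 && n_bins > 0) {
        int bin = (int)(t / bin_width);
        if (bin >= n_bins) bin = n_bins - 1;
        for (int b = 0; b < nbg; ++b) {
          const arma::ivec& s = spk[bin_groups[b]];
          for (arma::uword i = 0; i < s.n_elem; ++i)
            if (s[i]) counts[b](i, bin) += 1.0;
        }
      }
      if ((k + 1) % record_stride == 0) {
        const int j = (k + 1) / record_stride - 1;
        if (j < n_rec) {
          for (int g = 0; g < ng; ++g) pop_rates(j, g) = arma::mean(r[g]);
          D_rec[j] = D;
          t_rec[j] = t + dt;
          int pi = 0;
          for (int p = 0; p < np; ++p) {
            if (pr[p].rule == R_FIXED) continue;
            tp_rec(j, pi) = arma::mean(arma::mean(pr[p].Tp));
            td_rec(j, pi) = arma::mean(arma::mean(pr[p].Td));
            ++pi;
          }
        }
      }
    }
  }

  // pack updated state and weights
  List new_state(ng);
  for (int g = 0; g < ng; ++g)
    new_state[g] = List::create(_["v"] = v[g], _["s_fast"] = sf[g],
                                _["s_slow"] = ss[g], _["r"] = r[g],
                                _["ref_until"] = ref[g]);
  List new_proj(np);
  for (int p = 0; p < np; ++p) {
    if (pr[p].rule == R_FIXED)
      new_proj[p] = List::create(_["W"] = pr[p].W);
    else
      new_proj[p] = List::create(_["W"] = pr[p].W, _["Tp"] = pr[p].Tp,
                                 _["Td"] = pr[p].Td);
  }
  List cnt(nbg);
  for (int b = 0; b < nbg; ++b) cnt[b] = wrap(counts[b]);

  return List::create(_["time"] = t_rec, _["pop_rates"] = pop_rates,
                      _["D"] = D_rec, _["trace_p"] = tp_rec,
                      _["trace_d"] = td_rec, _["counts"] = cnt,
                      _["state"] = new_state, _["projections"] = new_proj);
}
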