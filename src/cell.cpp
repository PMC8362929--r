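#include <Rcpp.h>
#include "tt06.h"

using namespace Rcpp;

static const char *TT_STATE_NAMES[TT_NVARS] = {
    "v",  "m",  "h",    "j",   "d",    "f",    "f2",  "fcass", "r", "s",
    "xr1", "xr2", "xs", "rq", "cai", "casr", "cass", "nai",   "ki"};

TTParams tt_params_from_list(const List &par) {
  TTParams p;
  tt_default_params(p, as<int>(par["celltype"]));
  const double temp = as<double>(par["temperature_c"]);
  const double q10g = as<double>(par["q10_gates"]);
  const double q10c = as<double>(par["q10_conductance"]);
  const double q10k = as<double>(par["q10_katp"]);
  p.phi_gate = std::pow(q10g, (temp - 37.0) / 10.0);
  p.phi_cond = std::pow(q10c, (temp - 37.0) / 10.0);
  p.phi_katp = std::pow(q10k, (temp - 37.0) / 10.0);
  p.rtonf = 8314.472 * (273.15 + temp) / 96485.3415;
  p.g_katp = as<double>(par["g_katp"]);
  tt_apply_ischemia(p, as<double>(par["severity"]), as<double>(par["ko_max"]),
                    as<double>(par["f_atp_max"]),
                    as<double>(par["current_block"]));
  return p;
}

static void tt_check_finite(const double *y, double t) {
  for (int k = 0; k < TT_NVARS; ++k) {
    if (!R_finite(y[k]))
      stop("non-finite state variable '%s' at t = %.3f ms",
           TT_STATE_NAMES[k], t);
  }
}

// [[Rcpp::export]]
NumericVector cpp_cell_init_state() {
  NumericVector y(TT_NVARS);
  tt_init_state(y.begin());
  y.attr("names") = CharacterVector(TT_STATE_NAMES, TT_STATE_NAMES + TT_NVARS);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_cell_step(NumericVector state, List par, double dt,
                            double i_stim) {
  if (state.size() != TT_NVARS)
    stop("state must have %d variables", TT_NVARS);
  tt_check_finite(state.begin(), NA_REAL);
  NumericVector y = clone(state);
  TTParams p = tt_params_from_list(par);
  tt_step(y.begin(), p, dt, i_stim);
  y.attr("names") = CharacterVector(TT_STATE_NAMES, TT_STATE_NAMES + TT_NVARS);
  return y;
}

// Paced single-cell run. Records the membrane potential from
// `record_from_ms` onward at `record_dt` sampling.
// [[Rcpp::export]]
List cpp_run_paced(List par, double cl, int n_beats, double dt,
                   double stim_amp, double stim_dur, double record_dt,
                   double record_from_ms, Nullable<NumericVector> init) {
  TTParams p = tt_params_from_list(par);
  double y[TT_NVARS];
  if (init.isNotNull()) {
    NumericVector y0(init);
    if (y0.size() != TT_NVARS) stop("init state must have %d variables", TT_NVARS);
    for (int k = 0; k < TT_NVARS; ++k) y[k] = y0[k];
  } else {
    tt_init_state(y);
  }

  const double t_end = cl * n_beats;
  const long n_steps = (long)std::ceil(t_end / dt);
  const int rec_every = std::max(1, (int)std::round(record_dt / dt));

  std::vector<double> rec_t, rec_v;
  rec_t.reserve((size_t)((t_end - record_from_ms) / (rec_every * dt)) + 4);
  rec_v.reserve(rec_t.capacity());

  for (long i = 0; i < n_steps; ++i) {
    const double t = i * dt;
    const double phase = t - cl * std::floor(t / cl);
    const double istim = (phase < stim_dur) ? stim_amp : 0.0;
    if (t >= record_from_ms && (i % rec_every) == 0) {
      rec_t.push_back(t);
      rec_v.push_back(y[0]);
    }
    tt_step(y, p, dt, istim);
    if ((i & 1023) == 0) tt_check_finite(y, t);
  }
  tt_check_finite(y, t_end);

  NumericVector yf(y, y + TT_NVARS);
  yf.attr("names") = CharacterVector(TT_STATE_NAMES, TT_STATE_NAMES + TT_NVARS);
  return List::create(_["t"] = wrap(rec_t), _["vm"] = wrap(rec_v),
                      _["final_state"] = yf);
}
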