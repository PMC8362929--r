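#include <Rcpp.h>
#include "tt06.h"

using namespace Rcpp;

TTParams tt_params_from_list(const List &par); // cell.cpp

// Monodomain reaction-diffusion on a regular (nx, ny, nz) grid with no-flux
// boundaries, operator splitting (reaction: ionic model, diffusion: 7-point
// finite differences with face-averaged diffusivity) and a unipolar
// pseudo-ECG from the dipole-source integral
//   phi_e(t) = - sum_i D_i * grad(Vm)_i . grad(1/r_i) * dV.
//
// Arguments (all node vectors in x-fastest order, 0-based indices):
//   celltype   int per node (0 epi, 1 endo, 2 mid)
//   severity   ischemia severity per node in [0,1]
//   diff       diffusivity per node, cm^2/ms (already scaled for severity)
//   stimuli    list of list(nodes=<int vec>, amp, dur, times=<numeric vec>)
//   electrode  xyz position in mm (grid node (0,0,0) sits at the origin)
//   init       NULL, or matrix n x 19, or matrix 3 x 19 (per cell type)
//   snapshot_times  times (ms) at which to store full Vm fields
//   stop_when_quiet if true, stop once all Vm < -65 mV after the last
//                   stimulus has been delivered
// [[Rcpp::export]]
List cpp_simulate_tissue(int nx, int ny, int nz, double dx_mm,
                         IntegerVector celltype, NumericVector severity,
                         NumericVector diff, List base_par, List stimuli,
                         double dt, double t_start, double t_end,
                         NumericVector electrode, double ecg_dt,
                         Nullable<NumericMatrix> init,
                         NumericVector snapshot_times, bool stop_when_quiet,
                         double act_marker_ms) {
  const long n = (long)nx * ny * nz;
  if (celltype.size() != n || severity.size() != n || diff.size() != n)
    stop("per-node vectors must have length nx*ny*nz = %d", (int)n);

  const double dx_cm = dx_mm / 10.0;
  const double inv_dx2 = 1.0 / (dx_cm * dx_cm);

  // explicit diffusion stability check
  double dmax = 0.0;
  for (long i = 0; i < n; ++i) dmax = std::max(dmax, diff[i]);
  int ndim = (nx > 1) + (ny > 1) + (nz > 1);
  const double dt_max = (dx_cm * dx_cm) / (2.0 * std::max(1, ndim) * dmax);
  if (dt > dt_max)
    stop("diffusion stability violated: dt = %g ms exceeds bound %g ms; "
         "reduce dt or coarsen the grid", dt, dt_max);

  // per-node ionic parameters: severity enters the ischemia triad
  TTParams base = tt_params_from_list(base_par);
  const double ko_max = as<double>(base_par["ko_max"]);
  const double fatp_max = as<double>(base_par["f_atp_max"]);
  const double block = as<double>(base_par["current_block"]);
  std::vector<TTParams> parv((size_t)n);
  for (long i = 0; i < n; ++i) {
    TTParams p = base;
    tt_apply_ischemia(p, severity[i], ko_max, fatp_max, block);
    p.celltype = celltype[i];
    parv[i] = p;
  }

  // state
  std::vector<double> Y((size_t)n * TT_NVARS);
  if (init.isNotNull()) {
    NumericMatrix y0(init);
    if (y0.ncol() != TT_NVARS)
      stop("init must have %d columns", TT_NVARS);
    if (y0.nrow() == n) {
      for (long i = 0; i < n; ++i)
        for (int k = 0; k < TT_NVARS; ++k) Y[i * TT_NVARS + k] = y0(i, k);
    } else if (y0.nrow() == 3) {
      for (long i = 0; i < n; ++i)
        for (int k = 0; k < TT_NVARS; ++k)
          Y[i * TT_NVARS + k] = y0(celltype[i], k);
    } else {
      stop("init must have either n or 3 rows");
    }
  } else {
    for (long i = 0; i < n; ++i) tt_init_state(&Y[i * TT_NVARS]);
  }

  // stimuli
  struct Stim {
    std::vector<long> nodes;
    double amp, dur;
    std::vector<double> times;
  };
  std::vector<Stim> stims;
  double last_stim_end = t_start;
  for (int s = 0; s < stimuli.size(); ++s) {
    List sl = stimuli[s];
    Stim st;
    IntegerVector nd = sl["nodes"];
    for (int q = 0; q < nd.size(); ++q) {
      if (nd[q] < 0 || nd[q] >= n) stop("stimulus node index out of range");
      st.nodes.push_back(nd[q]);
    }
    st.amp = as<double>(sl["amp"]);
    st.dur = as<double>(sl["dur"]);
    NumericVector tm = sl["times"];
    for (int q = 0; q < tm.size(); ++q) {
      st.times.push_back(tm[q]);
      last_stim_end = std::max(last_stim_end, tm[q] + st.dur);
    }
    stims.push_back(st);
  }

  // electrode geometry in cm
  const double ex = electrode[0] / 10.0, ey = electrode[1] / 10.0,
               ez = electrode[2] / 10.0;
  const double voxvol = dx_cm * dx_cm * dx_cm;
  // precompute grad(1/r) per node
  std::vector<double> gex((size_t)n), gey((size_t)n), gez((size_t)n);
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        const long i = (long)iz * nx * ny + (long)iy * nx + ix;
        const double px = ix * dx_cm - ex, py = iy * dx_cm - ey,
                     pz = iz * dx_cm - ez;
        const double r2 = px * px + py * py + pz * pz;
        const double r3 = r2 * std::sqrt(r2);
        gex[i] = -px / r3;
        gey[i] = -py / r3;
        gez[i] = -pz / r3;
      }

  std::vector<double> V((size_t)n), Lap((size_t)n);
  std::vector<double> istim((size_t)n, 0.0);

  // activation bookkeeping: upward crossing of 0 mV, re-armed below -40 mV
  std::vector<int> armed((size_t)n, 1), act_n((size_t)n, 0),
      act_n_after((size_t)n, 0);
  std::vector<double> last_act((size_t)n, NA_REAL);

  const long n_steps = (long)std::ceil((t_end - t_start) / dt);
  const int ecg_every = std::max(1, (int)std::round(ecg_dt / dt));
  std::vector<double> ecg_t, ecg_phi;
  ecg_t.reserve((size_t)(n_steps / ecg_every) + 2);
  ecg_phi.reserve(ecg_t.capacity());

  NumericMatrix snaps((int)n, snapshot_times.size());
  int next_snap = 0;

  auto idx = [&](int ix, int iy, int iz) {
    return (long)iz * nx * ny + (long)iy * nx + ix;
  };

  double t = t_start;
  double stopped_at = NA_REAL;
  for (long step = 0; step < n_steps; ++step) {
    t = t_start + step * dt;

    // stimulus currents
    std::fill(istim.begin(), istim.end(), 0.0);
    bool any_stim = false;
    for (const Stim &st : stims)
      for (double t0 : st.times)
        if (t >= t0 && t < t0 + st.dur) {
          for (long nd : st.nodes) istim[nd] = st.amp;
          any_stim = true;
        }

    for (long i = 0; i < n; ++i) V[i] = Y[i * TT_NVARS];

    // pseudo-ECG and snapshots on the pre-step field
    if ((step % ecg_every) == 0) {
      double phi = 0.0;
      for (int iz = 0; iz < nz; ++iz)
        for (int iy = 0; iy < ny; ++iy)
          for (int ix = 0; ix < nx; ++ix) {
            const long i = idx(ix, iy, iz);
            const double gx =
                nx == 1 ? 0.0
                        : (V[idx(std::min(ix + 1, nx - 1), iy, iz)] -
                           V[idx(std::max(ix - 1, 0), iy, iz)]) /
                              ((std::min(ix + 1, nx - 1) - std::max(ix - 1, 0)) *
                               dx_cm);
            const double gy =
                ny == 1 ? 0.0
                        : (V[idx(ix, std::min(iy + 1, ny - 1), iz)] -
                           V[idx(ix, std::max(iy - 1, 0), iz)]) /
                              ((std::min(iy + 1, ny - 1) - std::max(iy - 1, 0)) *
                               dx_cm);
            const double gz =
                nz == 1 ? 0.0
                        : (V[idx(ix, iy, std::min(iz + 1, nz - 1))] -
                           V[idx(ix, iy, std::max(iz - 1, 0))]) /
                              ((std::min(iz + 1, nz - 1) - std::max(iz - 1, 0)) *
                               dx_cm);
            phi -= diff[i] * (gx * gex[i] + gy * gey[i] + gz * gez[i]);
          }
      ecg_t.push_back(t);
      ecg_phi.push_back(phi * voxvol);
    }
    if (next_snap < snapshot_times.size() && t >= snapshot_times[next_snap]) {
      for (long i = 0; i < n; ++i) snaps(i, next_snap) = V[i];
      ++next_snap;
    }

    // diffusion term on the pre-reaction field (face-averaged diffusivity)
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix) {
          const long i = idx(ix, iy, iz);
          double acc = 0.0;
          if (ix > 0) {
            const long nb = idx(ix - 1, iy, iz);
            acc += 0.5 * (diff[i] + diff[nb]) * (V[nb] - V[i]);
          }
          if (ix < nx - 1) {
            const long nb = idx(ix + 1, iy, iz);
            acc += 0.5 * (diff[i] + diff[nb]) * (V[nb] - V[i]);
          }
          if (iy > 0) {
            const long nb = idx(ix, iy - 1, iz);
            acc += 0.5 * (diff[i] + diff[nb]) * (V[nb] - V[i]);
          }
          if (iy < ny - 1) {
            const long nb = idx(ix, iy + 1, iz);
            acc += 0.5 * (diff[i] + diff[nb]) * (V[nb] - V[i]);
          }
          if (iz > 0) {
            const long nb = idx(ix, iy, iz - 1);
            acc += 0.5 * (diff[i] + diff[nb]) * (V[nb] - V[i]);
          }
          if (iz < nz - 1) {
            const long nb = idx(ix, iy, iz + 1);
            acc += 0.5 * (diff[i] + diff[nb]) * (V[nb] - V[i]);
          }
          Lap[i] = acc * inv_dx2;
        }

    // reaction step + diffusion increment + activation detection
    double vmax = -1e9;
    for (long i = 0; i < n; ++i) {
      double *y = &Y[i * TT_NVARS];
      tt_step(y, parv[i], dt, istim[i]);
      y[0] += dt * Lap[i];
      const double v = y[0];
      if (!R_finite(v))
        stop("non-finite membrane potential at node %d, t = %.2f ms", (int)i + 1,
             t);
      if (armed[i] && v > 0.0) {
        armed[i] = 0;
        act_n[i] += 1;
        if (t >= act_marker_ms) act_n_after[i] += 1;
        last_act[i] = t;
      } else if (!armed[i] && v < -40.0) {
        armed[i] = 1;
      }
      vmax = std::max(vmax, v);
    }

    if (stop_when_quiet && !any_stim && t > last_stim_end + 5.0 &&
        vmax < -65.0) {
      stopped_at = t;
      break;
    }
  }

  NumericMatrix yf((int)n, TT_NVARS);
  for (long i = 0; i < n; ++i)
    for (int k = 0; k < TT_NVARS; ++k) yf(i, k) = Y[i * TT_NVARS + k];

  return List::create(
      _["ecg_t"] = wrap(ecg_t), _["ecg_phi"] = wrap(ecg_phi),
      _["act_count"] = wrap(act_n), _["act_count_after"] = wrap(act_n_after),
      _["last_activation_ms"] = wrap(last_act), _["snapshots"] = snaps,
      _["final_state"] = yf, _["stopped_at"] = stopped_at);
}
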