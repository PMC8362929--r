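#' Configure a transmural ventricular wedge
#'
#' Geometry and physiology of the monodomain wedge: a slab spanning the
#' ventricular wall from endocardium (stimulated face, x = 0) to
#' epicardium, subdivided into endo/M/epi layers along the transmural
#' axis, with an optional per-node ischemia severity field and a unipolar
#' pseudo-ECG electrode on the transmural axis beyond the epicardial
#' face. In `"2d"` mode the depth dimension collapses to a single node
#' (a transmural sheet), the desk-scale configuration used for morphology
#' and re-entry studies.
#'
#' @param dims_mm (transmural, width, depth) extent in mm
#' @param dx_mm node spacing, mm; must divide all dims
#' @param layer_fractions endo/M/epi thickness shares summing to 1;
#'   `c(0, 1, 0)` gives an all-M sheet
#' @param diffusivity isotropic diffusion coefficient, cm^2/ms
#' @param temperature_c simulation temperature, C
#' @param ischemia_severity uniform severity in \[0, 1] (ignored where
#'   `severity_field` is given)
#' @param severity_field optional matrix (nx x ny) of per-node severities,
#'   replicated across depth (e.g. from [resample_severity_sheet()])
#' @param electrode_offset_mm electrode distance beyond the epicardial
#'   face along the transmural axis, mm
#' @param mode `"2d"` (one node deep) or `"3d"`
#' @param diffusivity_floor local diffusivity fraction at severity 1
#'   (structural heterogeneity slows conduction in low-flow tissue)
#' @param q10_gates,q10_conductance,q10_katp,g_katp,ko_max,f_atp_max,current_block
#'   cell-model settings, see [cell_params()]
#' @return an object of class `wedge_config`
#' @export
wedge_config <- function(dims_mm = c(15, 20, 20), dx_mm = 0.25,
                         layer_fractions = c(endo = 0.10, mid = 0.30,
                                             epi = 0.60),
                         diffusivity = 1.54e-3, temperature_c = 37,
                         ischemia_severity = 0, severity_field = NULL,
                         electrode_offset_mm = 30,
                         mode = c("2d", "3d"), diffusivity_floor = 0.3,
                         q10_gates = 3, q10_conductance = 1.3,
                         q10_katp = 3, g_katp = 2,
                         ko_max = 8, f_atp_max = 0.005,
                         current_block = 0.25) {
  mode <- match.arg(mode)
  if (abs(sum(layer_fractions) - 1) > 1e-9)
    abort("`layer_fractions` must sum to 1")
  if (diffusivity <= 0) abort("`diffusivity` must be > 0")
  n <- dims_mm / dx_mm
  if (any(abs(n - round(n)) > 1e-9))
    abort("`dx_mm` must divide every wedge dimension")
  structure(list(dims_mm = dims_mm, dx_mm = dx_mm,
                 layer_fractions = layer_fractions,
                 diffusivity = diffusivity, temperature_c = temperature_c,
                 ischemia_severity = ischemia_severity,
                 severity_field = severity_field,
                 electrode_offset_mm = electrode_offset_mm, mode = mode,
                 diffusivity_floor = diffusivity_floor,
                 q10_gates = q10_gates, q10_conductance = q10_conductance,
                 q10_katp = q10_katp, g_katp = g_katp, ko_max = ko_max,
                 f_atp_max = f_atp_max, current_block = current_block),
            class = "wedge_config")
}

#' Build the wedge node grid
#'
#' Discretizes a [wedge_config()] into per-node cell types (endo/M/epi by
#' transmural position: a node whose centre lies in the first
#' `layer_fractions[1]` share of the wall is endocardial, and so on),
#' severities, and diffusivities (scaled linearly down to
#' `diffusivity_floor` of the global value at severity 1).
#'
#' @param config a [wedge_config()]
#' @return an object of class `wedge_model`
#' @export
build_wedge <- function(config) {
  stopifnot(inherits(config, "wedge_config"))
  nx <- as.integer(round(config$dims_mm[1] / config$dx_mm))
  ny <- as.integer(round(config$dims_mm[2] / config$dx_mm))
  nz <- if (config$mode == "2d") 1L
        else as.integer(round(config$dims_mm[3] / config$dx_mm))
  frac <- (rep(seq_len(nx), times = ny * nz) - 0.5) / nx
  lf <- config$layer_fractions
  celltype <- ifelse(frac < lf[1], 1L,              # endo
                     ifelse(frac < lf[1] + lf[2], 2L, 0L))  # mid, epi
  n <- nx * ny * nz
  if (!is.null(config$severity_field)) {
    sf <- config$severity_field
    if (!all(dim(sf) == c(nx, ny)))
      abort(sprintf("severity_field must be %d x %d", nx, ny))
    severity <- rep(as.numeric(sf), times = nz)
  } else {
    severity <- rep(config$ischemia_severity, n)
  }
  diffv <- config$diffusivity *
    (1 - (1 - config$diffusivity_floor) * severity)
  electrode <- c(config$dims_mm[1] + config$electrode_offset_mm,
                 (ny - 1) * config$dx_mm / 2, (nz - 1) * config$dx_mm / 2)
  structure(list(config = config, nx = nx, ny = ny, nz = nz,
                 celltype = as.integer(celltype), severity = severity,
                 diffusivity = diffv, electrode_mm = electrode),
            class = "wedge_model")
}

#' @export
print.wedge_model <- function(x, ...) {
  cat(sprintf("<wedge> %d x %d x %d nodes @ %.2g mm (%s), %.0f C\n",
              x$nx, x$ny, x$nz, x$config$dx_mm, x$config$mode,
              x$config$temperature_c))
  cat(sprintf("  layers endo/M/epi: %s | severity range %.2f-%.2f\n",
              paste(table(factor(x$celltype[seq_len(x$nx)],
                                 levels = c(1, 2, 0))), collapse = "/"),
              min(x$severity), max(x$severity)))
  invisible(x)
}

# 0-based node indices of a box region (1-based index ranges per axis)
wedge_nodes <- function(wedge, ix = seq_len(wedge$nx),
                        iy = seq_len(wedge$ny), iz = seq_len(wedge$nz)) {
  g <- expand.grid(ix = ix - 1L, iy = iy - 1L, iz = iz - 1L)
  as.integer(g$iz * wedge$nx * wedge$ny + g$iy * wedge$nx + g$ix)
}

#' Endocardial-face pacing stimulus
#'
#' S1 stimulus applied to a 1 mm-deep slab at the endocardial (x = 0)
#' face of the wedge.
#'
#' @param wedge a [build_wedge()] model
#' @param times stimulus onset times, ms
#' @param amp amplitude, pA/pF (depolarizing negative)
#' @param dur duration, ms
#' @return a stimulus definition for [simulate_wedge()]
#' @export
stim_s1_endo <- function(wedge, times, amp = -52, dur = 2) {
  depth <- max(1L, as.integer(round(1 / wedge$config$dx_mm)))
  list(nodes = wedge_nodes(wedge, ix = seq_len(min(depth, wedge$nx))),
       amp = amp, dur = dur, times = times)
}

#' Cross-field premature stimulus over one quadrant
#'
#' S2 stimulus covering the quadrant x < dims/2, y < dims/2 (all depths),
#' the standard cross-field geometry for re-entry induction.
#'
#' @inheritParams stim_s1_endo
#' @export
stim_s2_quadrant <- function(wedge, times, amp = -52, dur = 3) {
  list(nodes = wedge_nodes(wedge, ix = seq_len(max(1L, wedge$nx %/% 2L)),
                           iy = seq_len(max(1L, wedge$ny %/% 2L))),
       amp = amp, dur = dur, times = times)
}

#' Run the monodomain wedge simulation
#'
#' Operator-split monodomain update (ionic reaction per node, 7-point
#' finite-difference diffusion with no-flux boundaries) with a unipolar
#' pseudo-ECG recorded at the configured electrode as the dipole-source
#' sum `phi_e = -sum D grad(Vm) . grad(1/r) dV` over the grid.
#'
#' @param wedge a [build_wedge()] model
#' @param stimuli list of stimulus definitions ([stim_s1_endo()],
#'   [stim_s2_quadrant()], or `list(nodes, amp, dur, times)` with 0-based
#'   node indices)
#' @param t_end end time, ms
#' @param dt time step, ms (checked against the explicit diffusion
#'   stability bound)
#' @param t_start start time, ms (for resuming from `init`)
#' @param init optional initial state: matrix `n x 19`, or `3 x 19` with
#'   one row per cell-type code (epi, endo, mid)
#' @param ecg_dt pseudo-ECG sampling interval, ms
#' @param snapshot_times times at which to store full Vm fields
#' @param stop_when_quiet stop early once every node is below -65 mV
#'   after the last stimulus (used by re-entry assays)
#' @param act_marker_ms activations at or after this time are counted
#'   separately (re-entry detection)
#' @return an object of class `wedge_sim`: `ecg` tibble (`t_ms`,
#'   `phi_e`), `activation` tibble (per-node counts and last activation
#'   time), `snapshots`, `final_state`, `stopped_at`
#' @export
simulate_wedge <- function(wedge, stimuli, t_end, dt = 0.02, t_start = 0,
                           init = NULL, ecg_dt = 1,
                           snapshot_times = numeric(0),
                           stop_when_quiet = FALSE, act_marker_ms = -Inf) {
  stopifnot(inherits(wedge, "wedge_model"))
  cfg <- wedge$config
  base_par <- list(celltype = 0L, temperature_c = cfg$temperature_c,
                   q10_gates = cfg$q10_gates,
                   q10_conductance = cfg$q10_conductance,
                   q10_katp = cfg$q10_katp,
                   g_katp = cfg$g_katp, severity = 0, ko_max = cfg$ko_max,
                   f_atp_max = cfg$f_atp_max,
                   current_block = cfg$current_block)
  out <- cpp_simulate_tissue(
    wedge$nx, wedge$ny, wedge$nz, cfg$dx_mm, wedge$celltype,
    wedge$severity, wedge$diffusivity, base_par, stimuli, dt, t_start,
    t_end, wedge$electrode_mm, ecg_dt, init, as.numeric(snapshot_times),
    stop_when_quiet, act_marker_ms)
  structure(list(
    ecg = tibble(t_ms = out$ecg_t, phi_e = out$ecg_phi),
    activation = tibble(node = seq_len(length(out$act_count)),
                        n_activations = out$act_count,
                        n_after_marker = out$act_count_after,
                        last_activation_ms = out$last_activation_ms),
    snapshots = out$snapshots, snapshot_times = as.numeric(snapshot_times),
    final_state = out$final_state, stopped_at = out$stopped_at,
    wedge = wedge), class = "wedge_sim")
}

#' @method autoplot wedge_sim
#' @export
autoplot.wedge_sim <- function(object, ...) {
  ggplot2::ggplot(object$ecg, ggplot2::aes(x = .data$t_ms, y = .data$phi_e)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "pseudo-ECG (arb. units)") +
    ggplot2::theme_minimal()
}

# single-cell quasi-steady states per cell type under the wedge's
# condition; rows ordered by cell-type code (epi, endo, mid)
wedge_init_states <- function(config, cl = 800, n_beats = 5,
                              severity = NULL) {
  sev <- if (is.null(severity)) config$ischemia_severity else severity
  states <- lapply(c("epi", "endo", "mid"), function(ct) {
    p <- cell_params(ct, temperature_c = config$temperature_c,
                     q10_gates = config$q10_gates,
                     q10_conductance = config$q10_conductance,
                     q10_katp = config$q10_katp,
                     ischemia_severity = sev, ko_max = config$ko_max,
                     f_atp_max = config$f_atp_max, g_katp = config$g_katp,
                     current_block = config$current_block)
    run_paced(p, cl = cl, n_beats = n_beats)$final_state
  })
  do.call(rbind, states)
}

#' Paced pseudo-ECG under a named study condition
#'
#' Runs one endocardially paced beat of the wedge under `"control"`
#' (severity 0, 37 C), `"NT_PD"` (severity 1, 37 C) or `"TH_PD"`
#' (severity 1, 32 C), after per-cell-type single-cell pre-pacing, and
#' extracts ECG features from the final beat. The pseudo-ECG includes a
#' 20 ms pre-stimulus baseline.
#'
#' @param condition `"control"`, `"NT_PD"` or `"TH_PD"`
#' @param config a [wedge_config()]; its temperature and severity are
#'   overridden by the condition
#' @param t_beat recording window after the stimulus, ms
#' @param dt integration step, ms
#' @param pre_beats single-cell pre-pacing beats
#' @return an object of class `wedge_condition`: `condition`, `sim` (a
#'   `wedge_sim`), `features` (one-row tibble from
#'   [extract_ecg_features()])
#' @export
run_condition <- function(condition = c("control", "NT_PD", "TH_PD"),
                          config = wedge_config(dx_mm = 0.5),
                          t_beat = 800, dt = 0.02, pre_beats = 5) {
  condition <- match.arg(condition)
  sev <- if (condition == "control") 0 else 1
  temp <- if (condition == "TH_PD") 32 else 37
  cfg <- config
  cfg$ischemia_severity <- sev
  cfg$temperature_c <- temp
  cfg$severity_field <- NULL
  wedge <- build_wedge(cfg)
  init <- wedge_init_states(cfg, n_beats = pre_beats)
  stim_t <- 20
  sim <- simulate_wedge(wedge, list(stim_s1_endo(wedge, times = stim_t)),
                        t_end = stim_t + t_beat, dt = dt, init = init,
                        stop_when_quiet = TRUE)
  activated <- sum(sim$activation$n_activations > 0)
  stim_sz <- length(stim_s1_endo(wedge, times = stim_t)$nodes)
  propagated <- activated > 2 * stim_sz
  feats <- if (propagated) {
    extract_ecg_features(sim$ecg, stim_time = stim_t)
  } else {
    warn(sprintf("condition %s: propagation failure (%d node(s) activated)",
                 condition, activated))
    extract_ecg_features(tibble(t_ms = sim$ecg$t_ms,
                                phi_e = 0 * sim$ecg$phi_e),
                         stim_time = stim_t)
  }
  structure(list(condition = condition, sim = sim, features = feats,
                 propagated = propagated),
            class = "wedge_condition")
}

#' @export
print.wedge_condition <- function(x, ...) {
  f <- x$features
  cat(sprintf("<wedge %s> QRS %.0f ms, QT %.0f ms, ST %.0f ms, T %s (%.3g)\n",
              x$condition, f$qrs_ms, f$qt_ms, f$st_ms, f$t_polarity,
              f$t_amp))
  invisible(x)
}

#' S1-S2 cross-field re-entry induction assay
#'
#' Delivers two conditioning S1 beats at the endocardial face followed by
#' a premature cross-field S2 over one quadrant at each coupling
#' interval, and reports whether re-entry was induced (any node
#' activating at least 3 times after S2 with self-sustained activity) and
#' for how long it persisted. The S1 phase is simulated once and each
#' coupling interval resumes from the stored state.
#'
#' @param config a [wedge_config()], typically an all-M 2D sheet with a
#'   `severity_field` for the PD conditions
#' @param condition `"control"`, `"NT_PD"` or `"TH_PD"` (sets severity
#'   scaling of the field and temperature)
#' @param coupling_intervals S2 coupling intervals (ms after the last S1);
#'   scan these around the refractory period of the most-recovered tissue
#' @param s1_count,s1_cl number and cycle length of conditioning S1 beats
#' @param persistence_cap follow-up window after S2, ms
#' @param dt integration step, ms
#' @return a tibble: `coupling_interval_ms`, `induced`, `persistence_ms`,
#'   `terminated_spontaneously`, `n_reentrant_nodes`
#' @export
s1s2_reentry_assay <- function(config,
                               condition = c("NT_PD", "TH_PD", "control"),
                               coupling_intervals, s1_count = 1,
                               s1_cl = 700, persistence_cap = 1200,
                               dt = 0.02) {
  condition <- match.arg(condition)
  if (length(coupling_intervals) < 1)
    abort("at least one coupling interval is required")
  cfg <- config
  cfg$temperature_c <- if (condition == "TH_PD") 32 else 37
  if (condition == "control") {
    cfg$severity_field <- NULL
    cfg$ischemia_severity <- 0
  }
  wedge <- build_wedge(cfg)
  settle <- 100
  s1_times <- settle + s1_cl * (seq_len(s1_count) - 1)
  last_s1 <- max(s1_times)
  init <- wedge_init_states(cfg, n_beats = 3,
                            severity = stats::median(wedge$severity))
  t_chk <- last_s1 + max(10, min(coupling_intervals) - 10)
  base <- simulate_wedge(wedge, list(stim_s1_endo(wedge, times = s1_times)),
                         t_end = t_chk, dt = dt, init = init, ecg_dt = 5)
  out <- vector("list", length(coupling_intervals))
  for (i in seq_along(coupling_intervals)) {
    ci <- coupling_intervals[i]
    s2_t <- last_s1 + ci
    sim <- simulate_wedge(
      wedge,
      list(stim_s1_endo(wedge, times = s1_times),
           stim_s2_quadrant(wedge, times = s2_t)),
      t_end = s2_t + persistence_cap, dt = dt, t_start = t_chk,
      init = base$final_state, ecg_dt = 5, stop_when_quiet = TRUE,
      act_marker_ms = s2_t)
    n_re <- sum(sim$activation$n_after_marker >= 3, na.rm = TRUE)
    induced <- n_re >= 1
    persistence <- if (induced) {
      max(sim$activation$last_activation_ms, na.rm = TRUE) - s2_t
    } else 0
    out[[i]] <- tibble(coupling_interval_ms = ci, induced = induced,
                       persistence_ms = persistence,
                       terminated_spontaneously =
                         induced && !is.na(sim$stopped_at),
                       n_reentrant_nodes = n_re)
  }
  bind_rows(out)
}
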