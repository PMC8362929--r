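#' Q10 temperature scaling factor
#'
#' Standard Q10 law: the factor applied to a rate or conductance at
#' `temperature_c`, relative to the 37 C reference. Cooling below 37 C
#' with `q10 > 1` yields a factor below 1 (kinetics slow, conductances
#' fall).
#'
#' @param q10 Q10 coefficient, >= 1
#' @param temperature_c temperature in Celsius
#' @return `q10^((temperature_c - 37)/10)`
#' @examples
#' temperature_factor(3, 32) # ~0.577: gate rates roughly halve at 32 C
#' @export
temperature_factor <- function(q10, temperature_c) {
  if (any(q10 < 1)) abort("`q10` must be >= 1")
  q10^((temperature_c - 37) / 10)
}

#' Parameterize the human ventricular cell model
#'
#' Builds the parameter set for the ventricular cardiomyocyte ionic model
#' (epicardial, mid-myocardial or endocardial variant) under a given
#' temperature and ischemic-stress severity.
#'
#' Therapeutic hypothermia is modeled as Q10 scaling: all gate rates are
#' multiplied by `temperature_factor(q10_gates, temperature_c)` and all
#' sarcolemmal conductances/pump rates by
#' `temperature_factor(q10_conductance, temperature_c)`; Nernst potentials
#' use the absolute temperature. The ischemic ("PD") condition is the
#' acute phase-1a triad, linearly interpolated in `ischemia_severity`:
#' extracellular K+ rises from 5.4 toward `ko_max` mM, the ATP-sensitive
#' K+ current activates up to `f_atp_max` open fraction (conductance
#' `g_katp` at full activation), and the fast Na+ and L-type Ca2+
#' conductances fall by `current_block`. All of these are configuration,
#' not measurements: they are chosen to produce the canonical ischemic
#' phenotype (abbreviated AP, slower upstroke, elevated resting
#' potential).
#'
#' @param cell_type "epi", "mid" or "endo"
#' @param temperature_c simulation temperature, 25-42 C (37 nominal,
#'   32 for therapeutic hypothermia)
#' @param q10_gates Q10 of channel gating kinetics (default 3)
#' @param q10_conductance Q10 of channel conductances (default 1.3)
#' @param q10_katp Q10 of the ATP-sensitive K+ conductance (default 3:
#'   the ischemic K+ leak is strongly suppressed by cooling, which is what
#'   lets hypothermia pull the ischemic AP and ECG back toward control)
#' @param ischemia_severity 0 (control) to 1 (full ischemic condition)
#' @param ko_max extracellular K+ at severity 1, mM (default 8: strong
#'   hyperkalemia with physiologic, not near-failing, conduction)
#' @param f_atp_max ATP-sensitive K+ open fraction at severity 1
#' @param g_katp maximal I_KATP conductance (mS/uF) at open fraction 1
#' @param current_block fractional reduction of G_Na and G_CaL at
#'   severity 1
#' @return an object of class `cell_params`
#' @export
cell_params <- function(cell_type = c("epi", "mid", "endo"),
                        temperature_c = 37, q10_gates = 3,
                        q10_conductance = 1.3, q10_katp = 3,
                        ischemia_severity = 0,
                        ko_max = 8, f_atp_max = 0.005, g_katp = 2,
                        current_block = 0.25) {
  cell_type <- match.arg(cell_type)
  if (temperature_c < 25 || temperature_c > 42)
    abort("`temperature_c` must lie in [25, 42]")
  if (q10_gates < 1 || q10_conductance < 1 || q10_katp < 1)
    abort("Q10 values must be >= 1")
  if (ischemia_severity < 0 || ischemia_severity > 1)
    abort("`ischemia_severity` must lie in [0, 1]")
  structure(list(cell_type = cell_type, temperature_c = temperature_c,
                 q10_gates = q10_gates, q10_conductance = q10_conductance,
                 q10_katp = q10_katp,
                 ischemia_severity = ischemia_severity, ko_max = ko_max,
                 f_atp_max = f_atp_max, g_katp = g_katp,
                 current_block = current_block),
            class = "cell_params")
}

celltype_code <- function(cell_type) {
  c(epi = 0L, endo = 1L, mid = 2L)[[cell_type]]
}

# R-list form consumed by the compiled model
cpp_par <- function(p, severity = NULL) {
  list(celltype = celltype_code(p$cell_type),
       temperature_c = p$temperature_c, q10_gates = p$q10_gates,
       q10_conductance = p$q10_conductance, q10_katp = p$q10_katp,
       g_katp = p$g_katp,
       severity = if (is.null(severity)) p$ischemia_severity else severity,
       ko_max = p$ko_max, f_atp_max = p$f_atp_max,
       current_block = p$current_block)
}

#' Resting initial state of the cell model
#' @return named numeric vector of the 19 state variables
#' @export
cell_state_init <- function() cpp_cell_init_state()

#' Advance the cell model by one integration step
#'
#' One operator step: Rush-Larsen exponential update for the 12 gating
#' variables, forward Euler for membrane potential and concentrations.
#'
#' @param state named state vector (see [cell_state_init()])
#' @param params a [cell_params()]
#' @param dt time step, ms; the explicit scheme requires dt <= 0.02
#' @param i_stim stimulus current, pA/pF (depolarizing is negative)
#' @return the updated state vector
#' @export
cell_step <- function(state, params, dt = 0.02, i_stim = 0) {
  stopifnot(inherits(params, "cell_params"))
  if (dt > 0.02 + 1e-12)
    abort("explicit integration requires dt <= 0.02 ms")
  cpp_cell_step(state, cpp_par(params), dt, i_stim)
}

#' Pace the cell model and extract action-potential features
#'
#' Runs `n_beats` stimulated beats at cycle length `cl` and returns the
#' membrane-potential trace of the final beat together with its features:
#' APD90 (from maximum-upstroke time to 90% repolarization, measured from
#' AP peak relative to the pre-stimulus resting potential), maximum
#' upstroke velocity, resting potential and amplitude. If the stimulus
#' fails to elicit an action potential (amplitude < 40 mV) the features
#' are returned as `NA` with `elicited = FALSE`.
#'
#' @param params a [cell_params()]
#' @param cl pacing cycle length, ms (>= 300)
#' @param n_beats number of beats (>= 1; >= 10 for quasi-steady features)
#' @param dt integration step, ms
#' @param stim_amp,stim_dur stimulus amplitude (pA/pF) and duration (ms)
#' @param record_dt sampling interval of the returned trace, ms
#' @param record_beats how many final beats to record
#' @param init optional initial state (defaults to the model's resting
#'   state)
#' @return an object of class `coolwedge_ap`: `trace` (tibble `t_ms`,
#'   `vm_mv`, time zero at the last recorded stimulus), `features`
#'   (one-row tibble), `final_state`, `params`
#' @export
run_paced <- function(params, cl = 1000, n_beats = 10, dt = 0.02,
                      stim_amp = -52, stim_dur = 1, record_dt = 0.05,
                      record_beats = 1, init = NULL) {
  stopifnot(inherits(params, "cell_params"))
  if (cl < 300) abort("`cl` must be >= 300 ms")
  if (n_beats < 1) abort("`n_beats` must be >= 1")
  rec_from <- cl * (n_beats - record_beats)
  out <- cpp_run_paced(cpp_par(params), cl, n_beats, dt, stim_amp,
                       stim_dur, record_dt, rec_from, init)
  t_ms <- out$t - cl * (n_beats - 1)   # 0 at last stimulus
  feats <- ap_features(t_ms, out$vm, stim_time = 0)
  structure(list(trace = tibble(t_ms = t_ms, vm_mv = out$vm),
                 features = feats, final_state = out$final_state,
                 params = params, cl = cl, n_beats = n_beats),
            class = "coolwedge_ap")
}

# AP features from a single-beat trace; stim_time marks the pacing
# stimulus within t
ap_features <- function(t, vm, stim_time = 0) {
  pre <- vm[t <= stim_time]
  v_rest <- if (length(pre)) pre[length(pre)] else vm[1]
  beat <- t >= stim_time
  tb <- t[beat]; vb <- vm[beat]
  pk_i <- which.max(vb)
  amplitude <- vb[pk_i] - v_rest
  if (amplitude < 40) {
    return(tibble(apd90 = NA_real_, dvdt_max = NA_real_, v_rest = v_rest,
                  amplitude = amplitude, elicited = FALSE))
  }
  dv <- diff(vb) / diff(tb)
  up_i <- which.max(dv)
  v90 <- vb[pk_i] - 0.9 * (vb[pk_i] - v_rest)
  rep_i <- which(vb < v90 & seq_along(vb) > pk_i)[1]
  apd90 <- if (is.na(rep_i)) NA_real_ else tb[rep_i] - tb[up_i]
  tibble(apd90 = apd90, dvdt_max = max(dv), v_rest = v_rest,
         amplitude = amplitude, elicited = TRUE)
}

#' @export
print.coolwedge_ap <- function(x, ...) {
  f <- x$features
  cat(sprintf(
    "<paced AP> %s, %.0f C, severity %.2f | APD90 %s ms, dV/dt_max %s mV/ms, V_rest %.1f mV\n",
    x$params$cell_type, x$params$temperature_c,
    x$params$ischemia_severity,
    ifelse(is.na(f$apd90), "NA", sprintf("%.1f", f$apd90)),
    ifelse(is.na(f$dvdt_max), "NA", sprintf("%.0f", f$dvdt_max)),
    f$v_rest))
  invisible(x)
}

#' @method tidy coolwedge_ap
#' @export
tidy.coolwedge_ap <- function(x, ...) x$trace

#' @method glance coolwedge_ap
#' @export
glance.coolwedge_ap <- function(x, ...) {
  dplyr::bind_cols(tibble(cell_type = x$params$cell_type,
                          temperature_c = x$params$temperature_c,
                          severity = x$params$ischemia_severity,
                          cl = x$cl), x$features)
}

#' @method autoplot coolwedge_ap
#' @export
autoplot.coolwedge_ap <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$t_ms, y = .data$vm_mv)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)") +
    ggplot2::theme_minimal()
}
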