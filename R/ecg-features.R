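#' Extract QRS, QT, ST and T-wave features from a pseudo-ECG
#'
#' Measurement conventions (noiseless simulated traces):
#' * the isoelectric line is the median of the 20 ms window before the
#'   stimulus;
#' * QRS onset is the stimulus time; the J point is the first return of
#'   `|phi_e|` below `j_frac` of the QRS peak after the last QRS extremum
#'   (local extrema above 25% of the QRS peak within `qrs_window`);
#' * the T wave is the largest-|area| baseline-crossing-delimited
#'   deflection after the J point; its onset is the first crossing of
#'   `t_onset_frac` of the T extremum, giving ST = J point to T onset
#'   (the default 25% keeps the onset meaningful when repolarization
#'   begins immediately after activation and no isoelectric ST segment
#'   exists, as in severe ischemia);
#' * T end uses the tangent method: the steepest post-peak slope toward
#'   baseline extrapolated to the isoelectric line, giving QT = stimulus
#'   to T end;
#' * polarity is the sign of the T extremum, `"biphasic"` when the
#'   opposite-sign deflection reaches `biphasic_frac` of it.
#'
#' A flat trace returns all-`NA` features with `flat = TRUE`; a T wave
#' that has not returned toward baseline by the end of the trace is an
#' error asking for a longer simulation.
#'
#' @param ecg a tibble/data.frame with columns `t_ms` and `phi_e`
#'   (sampling interval <= 1 ms), or a `wedge_sim`
#' @param stim_time stimulus (QRS onset) time, ms
#' @param qrs_window window after the stimulus searched for QRS extrema,
#'   ms
#' @param j_frac,t_onset_frac,biphasic_frac measurement thresholds
#' @param flat_tol absolute amplitude below which the trace counts as
#'   flat
#' @return a one-row tibble: `qrs_ms`, `qt_ms`, `st_ms`, `t_amp`,
#'   `t_polarity`, `t_peak_ms`, `flat`
#' @export
extract_ecg_features <- function(ecg, stim_time, qrs_window = 150,
                                 j_frac = 0.05, t_onset_frac = 0.25,
                                 biphasic_frac = 0.25, flat_tol = 1e-9) {
  if (inherits(ecg, "wedge_sim")) ecg <- ecg$ecg
  t <- ecg$t_ms; phi <- ecg$phi_e
  if (length(t) < 10) abort("trace too short")
  if (max(t) <= stim_time) abort("trace must extend beyond the stimulus")
  dt_samp <- median(diff(t))
  if (dt_samp > 1 + 1e-9) abort("sampling interval must be <= 1 ms")

  pre <- phi[t >= stim_time - 20 & t < stim_time]
  iso <- if (length(pre)) median(pre) else 0
  phi <- phi - iso

  null_feats <- tibble(qrs_ms = NA_real_, qt_ms = NA_real_,
                       st_ms = NA_real_, t_amp = NA_real_,
                       t_polarity = NA_character_, t_peak_ms = NA_real_,
                       flat = TRUE)
  if (max(abs(phi[t >= stim_time])) < flat_tol) return(null_feats)

  post <- t >= stim_time
  tp <- t[post]; pp <- phi[post]

  # --- QRS end (J point) -------------------------------------------------
  inw <- tp <= stim_time + qrs_window
  qrs_peak <- max(abs(pp[inw]))
  a <- abs(pp)
  is_ext <- c(FALSE, diff(sign(diff(a))) < 0, FALSE) & inw &
    a >= 0.25 * qrs_peak
  last_ext <- if (any(is_ext)) max(which(is_ext)) else which.max(a * inw)
  after <- which(seq_along(tp) > last_ext & a < j_frac * qrs_peak)
  if (!length(after))
    abort("QRS does not return to baseline; extend the trace or widen qrs_window")
  j_i <- after[1]
  qrs_ms <- tp[j_i] - stim_time

  # --- T wave: largest-|area| lobe after J --------------------------------
  seg <- seq(j_i, length(tp))
  s <- sign(pp[seg]); s[s == 0] <- 1
  lobe_id <- cumsum(c(1, abs(diff(s)) > 0))
  areas <- tapply(abs(pp[seg]) * dt_samp, lobe_id, sum)
  peaks <- tapply(abs(pp[seg]), lobe_id, max)
  # ignore residual QRS tail lobes with negligible area
  t_lobe <- as.integer(names(which.max(areas)))
  li <- seg[lobe_id == t_lobe]
  pk_i <- li[which.max(abs(pp[li]))]
  t_amp <- pp[pk_i]
  t_peak_ms <- tp[pk_i]

  # T onset and ST interval
  on_i <- li[abs(pp[li]) >= t_onset_frac * abs(t_amp)][1]
  st_ms <- max(0, tp[on_i] - tp[j_i])

  # T end by the tangent method
  post_pk <- li[li > pk_i]
  if (!length(post_pk) ||
      min(abs(pp[post_pk])) > 0.5 * abs(t_amp))
    abort("T wave has not returned toward baseline; run a longer simulation")
  slopes <- diff(pp[c(post_pk[1] - 1L, post_pk)]) / dt_samp
  toward <- which(sign(slopes) == -sign(t_amp))
  if (!length(toward))
    abort("no descending T limb found; run a longer simulation")
  k <- toward[which.max(abs(slopes[toward]))]
  idx <- post_pk[k]
  t_end <- tp[idx] - pp[idx] / slopes[k]
  qt_ms <- t_end - stim_time
  if (!is.finite(qt_ms) || qt_ms > max(tp) - stim_time + 50)
    abort("T end extrapolates beyond the trace; run a longer simulation")

  # polarity
  other <- peaks[names(peaks) != as.character(t_lobe)]
  polarity <- if (length(other) && max(other) >= biphasic_frac * abs(t_amp))
    "biphasic" else if (t_amp >= 0) "positive" else "negative"

  tibble(qrs_ms = qrs_ms, qt_ms = qt_ms, st_ms = st_ms, t_amp = t_amp,
         t_polarity = polarity, t_peak_ms = t_peak_ms, flat = FALSE)
}
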