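# Independent oracles, deliberately sharing no code with the package:
# plain-loop implementations used to cross-check the fast paths.

# Relative dispersion at one aggregation factor by explicit block loops.
# Same geometry convention as the estimator (blocks double along X then Y)
# but computed by direct iteration.
oracle_rd <- function(bf, mask, m, min_coverage = 0.5) {
  k <- round(log2(m))
  bx <- 2^ceiling(k / 2); by <- 2^floor(k / 2)
  d <- dim(bf)
  means <- c()
  for (z in seq_len(d[3])) {
    for (i0 in seq(1, d[1] - bx + 1, by = bx)) {
      for (j0 in seq(1, d[2] - by + 1, by = by)) {
        vals <- c(); nm <- 0
        for (i in i0:(i0 + bx - 1)) for (j in j0:(j0 + by - 1)) {
          if (mask[i, j, z]) { vals <- c(vals, bf[i, j, z]); nm <- nm + 1 }
        }
        if (nm >= min_coverage * bx * by && nm > 0)
          means <- c(means, mean(vals))
      }
    }
  }
  if (length(means) < 2) return(list(rd = NA_real_, n = length(means)))
  list(rd = sd(means) / mean(means), n = length(means))
}

# FD by explicit least squares on the oracle RD curve
oracle_fd <- function(bf, mask, factors, min_blocks = 20) {
  rd <- sapply(factors, function(m) oracle_rd(bf, mask, m)$rd)
  nb <- sapply(factors, function(m) oracle_rd(bf, mask, m)$n)
  ok <- !is.na(rd) & nb >= min_blocks & rd > 0
  x <- log(factors[ok]); y <- log(rd[ok])
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  1 - slope
}

# Two-sided exact signed-rank p by direct bitmask enumeration
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  centre <- sum(r) / 2
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    w <- sum(r[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L])
    if (abs(w - centre) >= abs(v - centre) - 1e-9) hits <- hits + 1L
  }
  hits / 2^n
}

# Unipolar dipole-sum pseudo-ECG recomputed from a stored Vm field by
# explicit loops (electrode position in mm, grid x-fastest)
oracle_pseudo_ecg <- function(vm, nx, ny, nz, dx_mm, diff_vec, electrode_mm) {
  dx <- dx_mm / 10
  e <- electrode_mm / 10
  V <- array(vm, c(nx, ny, nz))
  D <- array(diff_vec, c(nx, ny, nz))
  phi <- 0
  for (iz in seq_len(nz)) for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    gr <- function(axis) {
      id <- c(ix, iy, iz)
      lim <- c(nx, ny, nz)[axis]
      if (lim == 1) return(0)
      lo <- id; hi <- id
      lo[axis] <- max(1, id[axis] - 1); hi[axis] <- min(lim, id[axis] + 1)
      (V[hi[1], hi[2], hi[3]] - V[lo[1], lo[2], lo[3]]) /
        ((hi[axis] - lo[axis]) * dx)
    }
    p <- (c(ix, iy, iz) - 1) * dx - e
    r3 <- sum(p^2)^1.5
    ginv <- -p / r3
    phi <- phi - D[ix, iy, iz] * sum(c(gr(1), gr(2), gr(3)) * ginv)
  }
  phi * dx^3
}

# synthetic pseudo-ECG: rectangular QRS + Gaussian T with closed-form
# tangent end at t_peak + 2*sd
make_synthetic_ecg <- function(stim_time = 20, qrs_dur = 80, qrs_amp = 1,
                               t_peak = 300, t_sd = 30, t_amp = 0.5,
                               t_total = 480, dt = 1) {
  t <- seq(0, t_total, by = dt)
  phi <- numeric(length(t))
  phi[t >= stim_time & t < stim_time + qrs_dur] <- qrs_amp
  tt <- stim_time + t_peak
  phi <- phi + t_amp * exp(-(t - tt)^2 / (2 * t_sd^2)) * (t > stim_time + qrs_dur)
  tibble::tibble(t_ms = t, phi_e = phi)
}
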