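test_that("layer fractions partition transmural nodes by the stated rule", {
  cfg <- wedge_config(dims_mm = c(15, 2, 2), dx_mm = 0.25, mode = "2d",
                      layer_fractions = c(endo = 0.45, mid = 0.30,
                                          epi = 0.25))
  w <- build_wedge(cfg)
  expect_equal(w$nx, 60L)
  line <- w$celltype[seq_len(w$nx)]
  expect_equal(sum(line == 1L), 27)  # endo
  expect_equal(sum(line == 2L), 18)  # mid
  expect_equal(sum(line == 0L), 15)  # epi
})

test_that("severity scales local diffusivity down to the configured floor", {
  sf <- matrix(0, 20, 20); sf[8:12, 8:12] <- 1
  cfg <- wedge_config(dims_mm = c(10, 10, 10), dx_mm = 0.5, mode = "2d",
                      severity_field = sf)
  w <- build_wedge(cfg)
  D <- matrix(w$diffusivity, 20, 20)
  expect_equal(D[10, 10], 0.3 * cfg$diffusivity)
  expect_equal(D[1, 1], cfg$diffusivity)
  w0 <- build_wedge(wedge_config(dims_mm = c(10, 10, 10), dx_mm = 0.5,
                                 mode = "2d"))
  expect_true(all(w0$severity == 0))
})

test_that("config validation enforces geometry and physics constraints", {
  expect_error(wedge_config(layer_fractions = c(0.5, 0.3, 0.3)), "sum")
  expect_error(wedge_config(dims_mm = c(15, 20, 20), dx_mm = 0.4),
               "divide")
  expect_error(wedge_config(diffusivity = 0), "diffusivity")
  expect_error(simulate_wedge(build_wedge(wedge_config(dx_mm = 0.5)),
                              list(), t_end = 1, dt = 1),
               "stability")
})

test_that("quiescent tissue yields an identically zero pseudo-ECG", {
  cfg <- wedge_config(dims_mm = c(5, 5, 5), dx_mm = 0.5, mode = "2d")
  w <- build_wedge(cfg)
  sim <- simulate_wedge(w, list(), t_end = 30)
  expect_lt(max(abs(sim$ecg$phi_e)), 1e-9)
  expect_true(all(sim$activation$n_activations == 0))
})

test_that("uniform Vm is a fixed point of the diffusion operator", {
  cfg <- wedge_config(dims_mm = c(5, 5, 5), dx_mm = 0.5, mode = "3d",
                      layer_fractions = c(endo = 0, mid = 1, epi = 0))
  w <- build_wedge(cfg)
  # heterogeneous diffusivity must not move a uniform field either
  set.seed(1)
  w$diffusivity <- w$diffusivity * runif(length(w$diffusivity), 0.4, 1)
  y0 <- cell_state_init()
  init <- matrix(rep(y0, each = w$nx * w$ny * w$nz),
                 nrow = w$nx * w$ny * w$nz)
  sim <- simulate_wedge(w, list(), t_end = 2, init = init)
  # any drift is purely ionic (identical per node), so Vm stays uniform
  vms <- sim$final_state[, 1]
  expect_lt(diff(range(vms)), 1e-9)
  expect_lt(max(abs(sim$ecg$phi_e)), 1e-9)
})

test_that("pseudo-ECG matches the independent dipole-sum oracle", {
  cfg <- wedge_config(dims_mm = c(10, 6, 6), dx_mm = 0.5, mode = "2d")
  w <- build_wedge(cfg)
  init <- coolwedge:::wedge_init_states(cfg, n_beats = 2)
  sim <- simulate_wedge(w, list(stim_s1_endo(w, times = 2)), t_end = 30,
                        ecg_dt = 1, snapshot_times = c(10, 20))
  for (k in 1:2) {
    t_snap <- sim$snapshot_times[k]
    want <- oracle_pseudo_ecg(sim$snapshots[, k], w$nx, w$ny, w$nz,
                              cfg$dx_mm, w$diffusivity, w$electrode_mm)
    got <- sim$ecg$phi_e[sim$ecg$t_ms == t_snap]
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("paced control wedge shows endo-to-epi activation and upright T", {
  r <- run_condition("control", config = wedge_config(dx_mm = 0.5,
                                                      mode = "2d"))
  expect_true(r$propagated)
  f <- r$features
  expect_equal(f$t_polarity, "positive")
  expect_gt(f$t_amp, 0)
  # QRS deflection is positive (activation travels toward the electrode)
  e <- r$sim$ecg
  qrs_seg <- e$phi_e[e$t_ms >= 20 & e$t_ms <= 20 + f$qrs_ms]
  expect_gt(max(qrs_seg), 0)
  expect_gt(max(qrs_seg), max(abs(min(qrs_seg)), 0))
  # activation order along the transmural axis
  act <- matrix(r$sim$activation$last_activation_ms, nrow = r$sim$wedge$nx)
  mid_y <- ncol(act) %/% 2
  expect_true(act[1, mid_y] < act[nrow(act), mid_y])
})

test_that("doubling the electrode distance shrinks the signal", {
  peak_at <- function(offset) {
    cfg <- wedge_config(dims_mm = c(10, 6, 6), dx_mm = 0.5, mode = "2d",
                        electrode_offset_mm = offset)
    w <- build_wedge(cfg)
    init <- coolwedge:::wedge_init_states(cfg, n_beats = 2)
    sim <- simulate_wedge(w, list(stim_s1_endo(w, times = 2)), t_end = 40)
    max(abs(sim$ecg$phi_e))
  }
  expect_gt(peak_at(30), peak_at(60))
})

test_that("conduction velocity on a strand is physiological at 37 C", {
  cfg <- wedge_config(dims_mm = c(20, 0.5, 0.5), dx_mm = 0.5, mode = "2d",
                      layer_fractions = c(endo = 0, mid = 1, epi = 0))
  w <- build_wedge(cfg)
  init <- coolwedge:::wedge_init_states(cfg, n_beats = 2)
  sim <- simulate_wedge(w, list(stim_s1_endo(w, times = 5)), t_end = 80,
                        init = init)
  act <- sim$activation$last_activation_ms
  # measure between 5 and 15 mm to avoid stimulus and boundary effects
  i1 <- 11; i2 <- 31
  cv_cm_s <- ((i2 - i1) * 0.05) / ((act[i2] - act[i1]) / 1000)
  expect_gt(cv_cm_s, 40)
  expect_lt(cv_cm_s, 80)
})

test_that("mesh refinement changes QRS and QT by under 5%", {
  f1 <- run_condition("control",
                      config = wedge_config(dims_mm = c(10, 8, 8),
                                            dx_mm = 0.5, mode = "2d"),
                      t_beat = 600)$features
  f2 <- run_condition("control",
                      config = wedge_config(dims_mm = c(10, 8, 8),
                                            dx_mm = 0.25, mode = "2d"),
                      t_beat = 600)$features
  expect_lt(abs(f1$qt_ms - f2$qt_ms) / f2$qt_ms, 0.05)
  expect_lt(abs(f1$qrs_ms - f2$qrs_ms), max(0.05 * f2$qrs_ms, 5))
})
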