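test_that("Q10 factor obeys the closed form and its identities", {
  expect_identical(temperature_factor(3, 37), 1)
  expect_identical(temperature_factor(1, 29.3), 1)
  expect_equal(temperature_factor(3, 32), 3^(-0.5), tolerance = 1e-12)
  expect_equal(temperature_factor(3, 32), 0.5774, tolerance = 1e-4)
  expect_error(temperature_factor(0.8, 32), "q10")
})

test_that("the resting cell is stable without stimulation", {
  p <- cell_params("epi")
  r <- run_paced(p, cl = 1000, n_beats = 1, stim_amp = 0, record_beats = 1)
  drift <- diff(range(r$trace$vm_mv))
  expect_lt(drift, 1)
})

test_that("a stimulated control cell fires with a fast upstroke", {
  r <- run_paced(cell_params("epi"), cl = 1000, n_beats = 2)
  f <- r$features
  expect_true(f$elicited)
  expect_gt(f$dvdt_max, 100)
  expect_gt(f$amplitude, 100)
  expect_lt(f$v_rest, -80)
})

test_that("halving the time step changes APD90 by under 1 ms", {
  a1 <- run_paced(cell_params("epi"), cl = 800, n_beats = 3,
                  dt = 0.02)$features$apd90
  a2 <- run_paced(cell_params("epi"), cl = 800, n_beats = 3,
                  dt = 0.01)$features$apd90
  expect_lt(abs(a1 - a2), 1)
})

test_that("single-step interface preserves state validity and errors on bad dt", {
  y <- cell_state_init()
  p <- cell_params("epi")
  y2 <- cell_step(y, p, dt = 0.02, i_stim = -52)
  expect_length(y2, 19)
  expect_gt(y2[["v"]], y[["v"]])  # depolarizing stimulus raises Vm
  expect_error(cell_step(y, p, dt = 0.05), "0.02")
  y[["v"]] <- NaN
  expect_error(cell_step(y, p, dt = 0.02), "non-finite")
})

test_that("ischemia and hypothermia produce the canonical AP phenotypes", {
  feats <- function(...) run_paced(cell_params(...), cl = 1000,
                                   n_beats = 8)$features
  ctrl37 <- feats("epi")
  pd37 <- feats("epi", ischemia_severity = 1)
  ctrl32 <- feats("epi", temperature_c = 32)
  pd32 <- feats("epi", ischemia_severity = 1, temperature_c = 32)
  # ordering at matched pacing
  expect_lt(pd37$apd90, ctrl37$apd90)
  expect_lt(ctrl37$apd90, ctrl32$apd90)
  expect_gt(pd32$apd90, pd37$apd90)
  # ischemic cells rest depolarized with slower upstrokes
  expect_gt(pd37$v_rest, ctrl37$v_rest + 5)
  expect_lt(pd37$dvdt_max, ctrl37$dvdt_max)
  expect_lt(ctrl32$dvdt_max, ctrl37$dvdt_max)
})

test_that("APD90 increases monotonically as temperature falls 37 to 32", {
  temps <- c(37, 35.5, 34, 33, 32)
  apds <- sapply(temps, function(tc)
    run_paced(cell_params("epi", temperature_c = tc), cl = 1000,
              n_beats = 6)$features$apd90)
  expect_true(all(diff(apds) > 0))
})

test_that("the mid-myocardial variant outlasts the epicardial one", {
  epi <- run_paced(cell_params("epi"), n_beats = 8)$features$apd90
  mid <- run_paced(cell_params("mid"), n_beats = 8)$features$apd90
  endo <- run_paced(cell_params("endo"), n_beats = 8)$features$apd90
  expect_gt(mid, epi + 30)
  expect_gt(mid, endo + 30)
})

test_that("gates stay in [0,1] and concentrations positive over 50 beats", {
  p <- cell_params("epi", ischemia_severity = 0.5)
  r <- run_paced(p, cl = 400, n_beats = 50, record_beats = 1)
  y <- r$final_state
  gates <- y[c("m", "h", "j", "d", "f", "f2", "fcass", "r", "s",
               "xr1", "xr2", "xs", "rq")]
  expect_true(all(gates >= 0 & gates <= 1))
  conc <- y[c("cai", "casr", "cass", "nai", "ki")]
  expect_true(all(conc > 0))
  expect_true(all(abs(r$trace$vm_mv) < 100))
})

test_that("compiled model matches the independent R reference to < 1 mV", {
  ref <- ref_run_paced(ref_cell_params("epi"), cl = 500, n_beats = 1,
                       dt = 0.02, sample_every = 50)
  r <- run_paced(cell_params("epi"), cl = 500, n_beats = 1, dt = 0.02,
                 record_dt = 1, record_beats = 1)
  vm_pkg <- r$trace$vm_mv[match(round(ref$t, 6), round(r$trace$t_ms, 6))]
  ok <- !is.na(vm_pkg)
  expect_gt(sum(ok), 400)
  expect_lt(max(abs(vm_pkg[ok] - ref$vm[ok])), 1)
})

test_that("failed stimulation is flagged with null features", {
  r <- run_paced(cell_params("epi"), cl = 1000, n_beats = 1,
                 stim_amp = -1, stim_dur = 0.5)
  expect_false(r$features$elicited)
  expect_true(is.na(r$features$apd90))
})

test_that("parameter validation rejects out-of-range configurations", {
  expect_error(cell_params(temperature_c = 20), "temperature")
  expect_error(cell_params(q10_gates = 0.5), "Q10")
  expect_error(cell_params(ischemia_severity = 1.2), "severity")
})
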