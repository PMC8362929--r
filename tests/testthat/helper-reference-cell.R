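# Reference implementation of the human ventricular myocyte model
# (2006 formulation) in plain R, written independently of src/ as the
# oracle for the compiled path. Same published equations, same
# Rush-Larsen + Euler scheme, different code.

ref_cell_init <- function() {
  c(V = -86.2, m = 0, h = 0.75, j = 0.75, d = 0, f = 1, f2 = 1,
    fcass = 1, r = 0, s = 1, xr1 = 0, xr2 = 1, xs = 0, Rq = 1,
    Cai = 7e-5, CaSR = 1.3, CaSS = 7e-5, Nai = 7.67, Ki = 138.3)
}

ref_cell_params <- function(cell_type = "epi", temperature_c = 37,
                            q10_gates = 3, q10_conductance = 1.3,
                            q10_katp = 3, severity = 0, ko_max = 8,
                            f_atp_max = 0.005, g_katp = 2,
                            current_block = 0.25) {
  list(cell_type = cell_type,
       phig = q10_gates^((temperature_c - 37) / 10),
       phic = q10_conductance^((temperature_c - 37) / 10),
       phik = q10_katp^((temperature_c - 37) / 10),
       rtf = 8314.472 * (273.15 + temperature_c) / 96485.3415,
       Ko = 5.4 + severity * (ko_max - 5.4),
       fatp = severity * f_atp_max,
       gkatp = g_katp,
       sna = 1 - current_block * severity,
       scal = 1 - current_block * severity)
}

ref_cell_step <- function(y, p, dt, istim = 0) {
  FARADAY <- 96485.3415; CM <- 0.185
  VC <- 0.016404; VSR <- 0.001094; VSS <- 5.468e-5
  rtf <- p$rtf; phig <- p$phig; phic <- p$phic
  V <- y["V"]

  EK <- rtf * log(p$Ko / y["Ki"])
  ENa <- rtf * log(140 / y["Nai"])
  EKs <- rtf * log((p$Ko + 0.03 * 140) / (y["Ki"] + 0.03 * y["Nai"]))
  ECa <- 0.5 * rtf * log(2 / y["Cai"])

  gna <- 14.838 * p$sna * phic
  ina <- gna * y["m"]^3 * y["h"] * y["j"] * (V - ENa)

  vshift <- V - 15
  ef <- exp(2 * vshift / rtf)
  ical_drv <- if (abs(vshift) < 1e-6) {
    2 * FARADAY * (0.25 * y["CaSS"] - 2)
  } else {
    4 * vshift * (FARADAY / rtf) * (0.25 * y["CaSS"] * ef - 2) / (ef - 1)
  }
  ical <- 3.98e-5 * p$scal * phic * y["d"] * y["f"] * y["f2"] *
    y["fcass"] * ical_drv

  gto <- if (p$cell_type == "endo") 0.073 else 0.294
  ito <- gto * phic * y["r"] * y["s"] * (V - EK)

  rko <- sqrt(p$Ko / 5.4)
  ikr <- 0.153 * phic * rko * y["xr1"] * y["xr2"] * (V - EK)
  gks <- if (p$cell_type == "mid") 0.098 else 0.392
  iks <- gks * phic * y["xs"]^2 * (V - EKs)

  a1 <- 0.1 / (1 + exp(0.06 * (V - EK - 200)))
  b1 <- (3 * exp(2e-4 * (V - EK + 100)) + exp(0.1 * (V - EK - 10))) /
    (1 + exp(-0.5 * (V - EK)))
  ik1 <- 5.405 * phic * rko * (a1 / (a1 + b1)) * (V - EK)

  inaca <- 1000 * phic *
    (exp(0.35 * V / rtf) * y["Nai"]^3 * 2 -
       exp(-0.65 * V / rtf) * 140^3 * y["Cai"] * 2.5) /
    ((87.5^3 + 140^3) * (1.38 + 2) * (1 + 0.1 * exp(-0.65 * V / rtf)))

  inak <- 2.724 * phic * p$Ko * y["Nai"] /
    ((p$Ko + 1) * (y["Nai"] + 40) *
       (1 + 0.1245 * exp(-0.1 * V / rtf) + 0.0353 * exp(-V / rtf)))

  ipca <- 0.1238 * phic * y["Cai"] / (5e-4 + y["Cai"])
  ipk <- 0.0146 * phic * (V - EK) / (1 + exp((25 - V) / 5.98))
  ibna <- 2.9e-4 * phic * (V - ENa)
  ibca <- 5.92e-4 * phic * (V - ECa)
  ikatp <- p$gkatp * p$phik * p$fatp * (p$Ko / 5.4)^0.24 * (V - EK)

  itot <- ina + ical + ito + ikr + iks + ik1 + inaca + inak + ipca +
    ipk + ibna + ibca + ikatp

  # gate steady states and time constants
  rl <- function(g, inf, tau) inf - (inf - g) * exp(-dt * phig / tau)

  minf <- (1 + exp((-56.86 - V) / 9.03))^-2
  taum <- (1 / (1 + exp((-60 - V) / 5))) *
    (0.1 / (1 + exp((V + 35) / 5)) + 0.1 / (1 + exp((V - 50) / 200)))
  hinf <- (1 + exp((V + 71.55) / 7.43))^-2
  if (V >= -40) {
    tauh <- 1 / (0.77 / (0.13 * (1 + exp(-(V + 10.66) / 11.1))))
  } else {
    ah <- 0.057 * exp(-(V + 80) / 6.8)
    bh <- 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V)
    tauh <- 1 / (ah + bh)
  }
  if (V >= -40) {
    tauj <- 1 / (0.6 * exp(0.057 * V) / (1 + exp(-0.1 * (V + 32))))
  } else {
    aj <- (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.02424 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
    tauj <- 1 / (aj + bj)
  }
  dinf <- 1 / (1 + exp((-8 - V) / 7.5))
  taud <- (1.4 / (1 + exp((-35 - V) / 13)) + 0.25) *
    (1.4 / (1 + exp((V + 5) / 5))) + 1 / (1 + exp((50 - V) / 20))
  finf <- 1 / (1 + exp((V + 20) / 7))
  tauf <- 1102.5 * exp(-(V + 27)^2 / 225) +
    200 / (1 + exp((13 - V) / 10)) + 180 / (1 + exp((V + 30) / 10)) + 20
  f2inf <- 0.67 / (1 + exp((V + 35) / 7)) + 0.33
  tauf2 <- 562 * exp(-(V + 27)^2 / 240) + 31 / (1 + exp((25 - V) / 10)) +
    80 / (1 + exp((V + 30) / 10))
  fcinf <- 0.6 / (1 + (y["CaSS"] / 0.05)^2) + 0.4
  taufc <- 80 / (1 + (y["CaSS"] / 0.05)^2) + 2
  rinf <- 1 / (1 + exp((20 - V) / 6))
  taur <- 9.5 * exp(-(V + 40)^2 / 1800) + 0.8
  if (p$cell_type == "endo") {
    sinf <- 1 / (1 + exp((V + 28) / 5))
    taus <- 1000 * exp(-(V + 67)^2 / 1000) + 8
  } else {
    sinf <- 1 / (1 + exp((V + 20) / 5))
    taus <- 85 * exp(-(V + 45)^2 / 320) + 5 / (1 + exp((V - 20) / 5)) + 3
  }
  x1inf <- 1 / (1 + exp((-26 - V) / 7))
  taux1 <- (450 / (1 + exp((-45 - V) / 10))) * (6 / (1 + exp((V + 30) / 11.5)))
  x2inf <- 1 / (1 + exp((V + 88) / 24))
  taux2 <- (3 / (1 + exp((-60 - V) / 20))) * (1.12 / (1 + exp((V - 60) / 20)))
  xsinf <- 1 / (1 + exp((-5 - V) / 14))
  tauxs <- (1400 / sqrt(1 + exp((5 - V) / 6))) *
    (1 / (1 + exp((V - 35) / 15))) + 80

  out <- y
  out["m"] <- rl(y["m"], minf, taum)
  out["h"] <- rl(y["h"], hinf, tauh)
  out["j"] <- rl(y["j"], hinf, tauj)
  out["d"] <- rl(y["d"], dinf, taud)
  out["f"] <- rl(y["f"], finf, tauf)
  out["f2"] <- rl(y["f2"], f2inf, tauf2)
  out["fcass"] <- rl(y["fcass"], fcinf, taufc)
  out["r"] <- rl(y["r"], rinf, taur)
  out["s"] <- rl(y["s"], sinf, taus)
  out["xr1"] <- rl(y["xr1"], x1inf, taux1)
  out["xr2"] <- rl(y["xr2"], x2inf, taux2)
  out["xs"] <- rl(y["xs"], xsinf, tauxs)

  # calcium subsystem
  kcasr <- 2.5 - 1.5 / (1 + (1.5 / y["CaSR"])^2)
  opn <- (0.15 / kcasr) * y["CaSS"]^2 * y["Rq"] /
    (0.06 + (0.15 / kcasr) * y["CaSS"]^2)
  out["Rq"] <- y["Rq"] + dt * (-0.045 * kcasr * y["CaSS"] * y["Rq"] +
                                 0.005 * (1 - y["Rq"]))
  irel <- 0.102 * opn * (y["CaSR"] - y["CaSS"])
  ileak <- 3.6e-4 * (y["CaSR"] - y["Cai"])
  iup <- 0.006375 / (1 + (2.5e-4 / y["Cai"])^2)
  ixfer <- 0.0038 * (y["CaSS"] - y["Cai"])

  bc <- 1 / (1 + 0.2 * 0.001 / (y["Cai"] + 0.001)^2)
  bsr <- 1 / (1 + 10 * 0.3 / (y["CaSR"] + 0.3)^2)
  bss <- 1 / (1 + 0.4 * 2.5e-4 / (y["CaSS"] + 2.5e-4)^2)

  out["Cai"] <- y["Cai"] + dt * bc *
    ((ileak - iup) * VSR / VC + ixfer -
       (ibca + ipca - 2 * inaca) * CM / (2 * VC * FARADAY))
  out["CaSR"] <- y["CaSR"] + dt * bsr * (iup - irel - ileak)
  out["CaSS"] <- y["CaSS"] + dt * bss *
    (-ical * CM / (2 * VSS * FARADAY) + irel * VSR / VSS - ixfer * VC / VSS)

  out["Nai"] <- y["Nai"] - dt * (ina + ibna + 3 * inak + 3 * inaca) *
    CM / (VC * FARADAY)
  out["Ki"] <- y["Ki"] - dt *
    (ik1 + ito + ikr + iks + ikatp - 2 * inak + ipk + istim) *
    CM / (VC * FARADAY)

  out["V"] <- V - dt * (itot + istim)
  out
}

# paced reference run; returns sampled Vm
ref_run_paced <- function(p, cl, n_beats, dt = 0.02, stim_amp = -52,
                          stim_dur = 1, sample_every = 25) {
  y <- ref_cell_init()
  nstep <- round(cl * n_beats / dt)
  vs <- numeric(0); ts <- numeric(0)
  for (i in seq_len(nstep)) {
    t <- (i - 1) * dt
    ist <- if ((t %% cl) < stim_dur) stim_amp else 0
    y <- ref_cell_step(y, p, dt, ist)
    if (i %% sample_every == 0) { vs <- c(vs, y[["V"]]); ts <- c(ts, t + dt) }
  }
  list(t = ts, vm = vs, final = y)
}
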