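#ifndef COOLWEDGE_TT06_H
#define COOLWEDGE_TT06_H

#include <cmath>

// Human ventricular myocyte model (ten Tusscher & Panfilov 2006 formulation)
// with multiplicative temperature scaling of gate kinetics and channel
// conductances, plus an acute-ischemia triad (hyperkalemia, ATP-sensitive K+
// current, reduced fast Na+ / L-type Ca2+ conductances).
//
// State layout (NVARS doubles per cell):
//  0 V    mV          7 fcass          14 Cai  mM
//  1 m                8 r              15 CaSR mM
//  2 h                9 s              16 CaSS mM
//  3 j               10 xr1            17 Nai  mM
//  4 d               11 xr2            18 Ki   mM
//  5 f               12 xs
//  6 f2              13 Rq  (RyR adaptation)

#define TT_NVARS 19

enum TTCellType { TT_EPI = 0, TT_ENDO = 1, TT_MID = 2 };

struct TTParams {
  int celltype;      // TT_EPI / TT_ENDO / TT_MID
  double Ko;         // extracellular K+, mM (5.4 control)
  double gna_scale;  // multiplicative scale on G_Na
  double gcal_scale; // multiplicative scale on G_CaL
  double f_atp;      // open fraction of ATP-sensitive K+ channels (0 control)
  double g_katp;     // maximal I_KATP conductance at f_atp = 1, mS/uF
  double phi_gate;   // Q10 factor on gate rates (1 at 37 C)
  double phi_cond;   // Q10 factor on conductances (1 at 37 C)
  double phi_katp;   // Q10 factor on the ATP-sensitive K+ conductance
  double rtonf;      // R*T/F at simulation temperature, mV
};

// severity in [0,1] -> ischemia triad, linear interpolation
inline void tt_apply_ischemia(TTParams &p, double severity,
                              double ko_max = 9.0, double f_atp_max = 0.005,
                              double block = 0.25) {
  p.Ko = 5.4 + severity * (ko_max - 5.4);
  p.f_atp = severity * f_atp_max;
  p.gna_scale = 1.0 - block * severity;
  p.gcal_scale = 1.0 - block * severity;
}

inline void tt_default_params(TTParams &p, int celltype) {
  p.celltype = celltype;
  p.Ko = 5.4;
  p.gna_scale = 1.0;
  p.gcal_scale = 1.0;
  p.f_atp = 0.0;
  p.g_katp = 155.0;
  p.phi_gate = 1.0;
  p.phi_cond = 1.0;
  p.phi_katp = 1.0;
  p.rtonf = 8314.472 * 310.15 / 96485.3415;
}

// resting initial conditions (model's published starting point)
inline void tt_init_state(double *y) {
  y[0] = -86.2;   // V
  y[1] = 0.0;     // m
  y[2] = 0.75;    // h
  y[3] = 0.75;    // j
  y[4] = 0.0;     // d
  y[5] = 1.0;     // f
  y[6] = 1.0;     // f2
  y[7] = 1.0;     // fcass
  y[8] = 0.0;     // r
  y[9] = 1.0;     // s
  y[10] = 0.0;    // xr1
  y[11] = 1.0;    // xr2
  y[12] = 0.0;    // xs
  y[13] = 1.0;    // Rq
  y[14] = 0.00007;// Cai
  y[15] = 1.3;    // CaSR
  y[16] = 0.00007;// CaSS
  y[17] = 7.67;   // Nai
  y[18] = 138.3;  // Ki
}

// One reaction step: Rush-Larsen for gates, forward Euler for V and
// concentrations. i_stim in pA/pF (depolarizing stimulus is negative).
// Returns dV/dt (mV/ms) actually applied.
inline double tt_step(double *y, const TTParams &p, double dt, double i_stim) {
  const double F = 96485.3415, Cm = 0.185;
  const double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
  const double Bufc = 0.2, Kbufc = 0.001, Bufsr = 10.0, Kbufsr = 0.3;
  const double Bufss = 0.4, Kbufss = 0.00025;
  const double Vmaxup = 0.006375, Kup = 0.00025;
  const double Vrel = 0.102, Vleak = 0.00036, Vxfer = 0.0038;
  const double k1p = 0.15, k2p = 0.045, k3 = 0.060, k4 = 0.005;
  const double EC = 1.5, maxsr = 2.5, minsr = 1.0;
  const double Nao = 140.0, Cao = 2.0, pKNa = 0.03;
  const double KmK = 1.0, KmNa = 40.0, knak = 2.724;
  const double knaca = 1000.0, KmNai = 87.5, KmCa = 1.38, ksat = 0.1,
               ncx_gamma = 0.35, ncx_alpha = 2.5;
  const double GK1 = 5.405, GKr = 0.153, GpCa = 0.1238, KpCa = 0.0005,
               GpK = 0.0146, GbNa = 0.00029, GbCa = 0.000592;

  const double rtonf = p.rtonf, invrtonf = 1.0 / rtonf;
  const double phi_g = p.phi_gate, phi_c = p.phi_cond;

  double V = y[0];
  double m = y[1], h = y[2], j = y[3], d = y[4], f = y[5], f2 = y[6],
         fcass = y[7], r = y[8], s = y[9], xr1 = y[10], xr2 = y[11],
         xs = y[12], Rq = y[13];
  double Cai = y[14], CaSR = y[15], CaSS = y[16], Nai = y[17], Ki = y[18];

  const double GNa = 14.838 * p.gna_scale * phi_c;
  const double GCaL = 0.0000398 * p.gcal_scale * phi_c;
  const double Gto = (p.celltype == TT_ENDO ? 0.073 : 0.294) * phi_c;
  const double GKs = (p.celltype == TT_MID ? 0.098 : 0.392) * phi_c;

  // reversal potentials
  const double Ek = rtonf * std::log(p.Ko / Ki);
  const double Ena = rtonf * std::log(Nao / Nai);
  const double Eks = rtonf * std::log((p.Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  const double Eca = 0.5 * rtonf * std::log(Cao / Cai);

  // currents
  const double INa = GNa * m * m * m * h * j * (V - Ena);

  double ICaL;
  {
    const double vm15 = V - 15.0;
    const double expf = std::exp(2.0 * vm15 * invrtonf);
    // GHK-type driving term; prefactor 4*(V-15)*F^2/(R*T)
    double drive;
    if (std::fabs(vm15) < 1e-6) {
      // limit as V -> 15 mV
      drive = 2.0 * F * (0.25 * CaSS - Cao);
    } else {
      drive = 4.0 * vm15 * (F * invrtonf) *
              (0.25 * CaSS * expf - Cao) / (expf - 1.0);
    }
    ICaL = GCaL * d * f * f2 * fcass * drive;
  }

  const double Ito = Gto * r * s * (V - Ek);
  const double sqrtko = std::sqrt(p.Ko / 5.4);
  const double IKr = GKr * phi_c * sqrtko * xr1 * xr2 * (V - Ek);
  const double IKs = GKs * xs * xs * (V - Eks);

  double IK1;
  {
    const double ak1 = 0.1 / (1.0 + std::exp(0.06 * (V - Ek - 200.0)));
    const double bk1 =
        (3.0 * std::exp(0.0002 * (V - Ek + 100.0)) +
         std::exp(0.1 * (V - Ek - 10.0))) /
        (1.0 + std::exp(-0.5 * (V - Ek)));
    IK1 = GK1 * phi_c * sqrtko * ak1 / (ak1 + bk1) * (V - Ek);
  }

  const double INaCa =
      knaca * phi_c *
      (std::exp(ncx_gamma * V * invrtonf) * Nai * Nai * Nai * Cao -
       std::exp((ncx_gamma - 1.0) * V * invrtonf) * Nao * Nao * Nao * Cai *
           ncx_alpha) /
      ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
       (1.0 + ksat * std::exp((ncx_gamma - 1.0) * V * invrtonf)));

  const double INaK =
      knak * phi_c * p.Ko * Nai /
      ((p.Ko + KmK) * (Nai + KmNa) *
       (1.0 + 0.1245 * std::exp(-0.1 * V * invrtonf) +
        0.0353 * std::exp(-V * invrtonf)));

  const double IpCa = GpCa * phi_c * Cai / (KpCa + Cai);
  const double IpK = GpK * phi_c * (V - Ek) / (1.0 + std::exp((25.0 - V) / 5.98));
  const double IbNa = GbNa * phi_c * (V - Ena);
  const double IbCa = GbCa * phi_c * (V - Eca);

  // ATP-sensitive K+ current (Shaw-Rudy-type), zero at f_atp = 0
  const double IKatp =
      p.g_katp * p.phi_katp * p.f_atp * std::pow(p.Ko / 5.4, 0.24) * (V - Ek);

  const double Iion = INa + ICaL + Ito + IKr + IKs + IK1 + INaCa + INaK +
                      IpCa + IpK + IbNa + IbCa + IKatp;

  // --- gate updates (Rush-Larsen), rates scaled by phi_g -----------------
  {
    const double minf_d = 1.0 + std::exp((-56.86 - V) / 9.03);
    const double minf = 1.0 / (minf_d * minf_d);
    const double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    const double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                      0.10 / (1.0 + std::exp((V - 50.0) / 200.0));
    const double taum = am * bm / phi_g;
    y[1] = minf - (minf - m) * std::exp(-dt / taum);

    const double hinf_d = 1.0 + std::exp((V + 71.55) / 7.43);
    const double hinf = 1.0 / (hinf_d * hinf_d);
    double ah, bh;
    if (V >= -40.0) {
      ah = 0.0;
      bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    } else {
      ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
      bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
    }
    const double tauh = 1.0 / ((ah + bh) * phi_g);
    y[2] = hinf - (hinf - h) * std::exp(-dt / tauh);

    double aj, bj;
    if (V >= -40.0) {
      aj = 0.0;
      bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      aj = (-2.5428e4 * std::exp(0.2444 * V) -
            6.948e-6 * std::exp(-0.04391 * V)) *
           (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.02424 * std::exp(-0.01052 * V) /
           (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    const double tauj = 1.0 / ((aj + bj) * phi_g);
    y[3] = hinf - (hinf - j) * std::exp(-dt / tauj);

    const double dinf = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
    const double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
    const double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
    const double gd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
    const double taud = (ad * bd + gd) / phi_g;
    y[4] = dinf - (dinf - d) * std::exp(-dt / taud);

    const double finf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
    const double tauf = (1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
                         200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
                         180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0) /
                        phi_g;
    y[5] = finf - (finf - f) * std::exp(-dt / tauf);

    const double f2inf = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
    const double tauf2 = (562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
                          31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
                          80.0 / (1.0 + std::exp((V + 30.0) / 10.0))) /
                         phi_g;
    y[6] = f2inf - (f2inf - f2) * std::exp(-dt / tauf2);

    const double css_ratio = CaSS / 0.05;
    const double fcassinf = 0.6 / (1.0 + css_ratio * css_ratio) + 0.4;
    const double taufcass = (80.0 / (1.0 + css_ratio * css_ratio) + 2.0) / phi_g;
    y[7] = fcassinf - (fcassinf - fcass) * std::exp(-dt / taufcass);

    const double rinf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
    const double taur =
        (9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8) / phi_g;
    y[8] = rinf - (rinf - r) * std::exp(-dt / taur);

    double sinf, taus;
    if (p.celltype == TT_ENDO) {
      sinf = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
      taus = (1000.0 * std::exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0) /
             phi_g;
    } else {
      sinf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
      taus = (85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
              5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0) /
             phi_g;
    }
    y[9] = sinf - (sinf - s) * std::exp(-dt / taus);

    const double xr1inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
    const double axr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
    const double bxr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
    const double tauxr1 = axr1 * bxr1 / phi_g;
    y[10] = xr1inf - (xr1inf - xr1) * std::exp(-dt / tauxr1);

    const double xr2inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
    const double axr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
    const double bxr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
    const double tauxr2 = axr2 * bxr2 / phi_g;
    y[11] = xr2inf - (xr2inf - xr2) * std::exp(-dt / tauxr2);

    const double xsinf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
    const double axs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
    const double bxs = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
    const double tauxs = (axs * bxs + 80.0) / phi_g;
    y[12] = xsinf - (xsinf - xs) * std::exp(-dt / tauxs);
  }

  // --- calcium subsystem --------------------------------------------------
  const double kcasr =
      maxsr - (maxsr - minsr) / (1.0 + (EC / CaSR) * (EC / CaSR));
  const double k1 = k1p / kcasr;
  const double k2 = k2p * kcasr;
  const double O = k1 * CaSS * CaSS * Rq / (k3 + k1 * CaSS * CaSS);
  y[13] = Rq + dt * (-k2 * CaSS * Rq + k4 * (1.0 - Rq));

  const double Irel = Vrel * O * (CaSR - CaSS);
  const double Ileak = Vleak * (CaSR - Cai);
  const double Iup = Vmaxup / (1.0 + (Kup / Cai) * (Kup / Cai));
  const double Ixfer = Vxfer * (CaSS - Cai);

  const double dcai =
      Kbufc + Cai;
  const double bufc_fac = 1.0 / (1.0 + Bufc * Kbufc / (dcai * dcai));
  const double dcasr = Kbufsr + CaSR;
  const double bufsr_fac = 1.0 / (1.0 + Bufsr * Kbufsr / (dcasr * dcasr));
  const double dcass = Kbufss + CaSS;
  const double bufss_fac = 1.0 / (1.0 + Bufss * Kbufss / (dcass * dcass));

  y[14] = Cai + dt * bufc_fac *
                    ((Ileak - Iup) * Vsr / Vc + Ixfer -
                     (IbCa + IpCa - 2.0 * INaCa) * Cm / (2.0 * Vc * F));
  y[15] = CaSR + dt * bufsr_fac * (Iup - Irel - Ileak);
  y[16] = CaSS + dt * bufss_fac *
                     (-ICaL * Cm / (2.0 * Vss * F) + Irel * Vsr / Vss -
                      Ixfer * Vc / Vss);

  // --- Na+, K+ ------------------------------------------------------------
  y[17] = Nai - dt * (INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * Cm / (Vc * F);
  y[18] = Ki - dt * (IK1 + Ito + IKr + IKs + IKatp - 2.0 * INaK + IpK + i_stim) *
                   Cm / (Vc * F);

  const double dV = -(Iion + i_stim);
  y[0] = V + dt * dV;
  return dV;
}

#endif
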