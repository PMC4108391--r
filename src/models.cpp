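#include "models.h"

// ---------------------------------------------------------------------------
// Physical constants and GPB model parameters (Grandi-Pasqualini-Bers 2010
// human ventricular model, endo/epi variants, with a late sodium current of
// the Maltsev/Undrovinas formulation as used in failing-heart adaptations).
// ---------------------------------------------------------------------------

const char* OV_NAMES[N_OV] = {
  "GNa", "GNaL", "GNaB", "GK1", "GKr", "GKs", "GKp", "Gto",
  "GClCa", "GClB", "PCa", "IbarNCX", "IbarNaK", "IbarPMCA", "GCaB",
  "Vmax_SERCA", "SR_leak", "RyR_ks", "RyR_koCa"
};

namespace {

const double R_GAS = 8314.0;      // J/(kmol K)
const double FRDY  = 96485.0;     // C/mol
const double TEMP  = 310.0;       // K
const double FoRT  = FRDY / (R_GAS * TEMP);
const double CMEM  = 1.3810e-10;  // F, whole-cell membrane capacitance

// cell geometry
const double CELL_LENGTH = 100.0;   // um
const double CELL_RADIUS = 10.25;   // um
const double VCELL = M_PI * CELL_RADIUS * CELL_RADIUS * CELL_LENGTH * 1e-15; // L
const double VMYO  = 0.65 * VCELL;
const double VSR   = 0.035 * VCELL;
const double VSL   = 0.02 * VCELL;
const double VJUNC = 0.0539 * 0.01 * VCELL;
const double J_CA_JUNCSL = 1.0 / 1.2134e12;           // L/ms
const double J_CA_SLMYO  = 1.0 / 2.68510e11;
const double J_NA_JUNCSL = 1.0 / (1.6382e12 / 3.0 * 100.0);
const double J_NA_SLMYO  = 1.0 / (1.8308e10 / 3.0 * 100.0);

// membrane fractions
const double FJUNC = 0.11, FSL = 0.89;
const double FJUNC_CAL = 0.9, FSL_CAL = 0.1;

// fixed ionic concentrations (mM)
const double KO = 5.4, NAO = 140.0, CAO = 1.8, CLI = 15.0, CLO = 150.0;
const double MGI = 1.0;

// maximal conductances / transport rates
const double GNA   = 23.0;        // mS/uF
const double GNAL  = 0.0065;      // mS/uF, late sodium addition
const double GNAB  = 0.597e-3;
const double GKP   = 0.002;
const double GKS_J = 0.0035, GKS_SL = 0.0035;
const double P_NAK_PERM = 0.01833;  // IKs Na permeability ratio
const double GCLCA = 0.5 * 0.109625;
const double KD_CLCA = 100e-3;
const double GCLB  = 9e-3;
const double PCA = 0.5 * 5.4e-4, PK = 0.5 * 2.7e-7, PNA = 0.5 * 1.5e-8;
const double IBAR_NCX = 4.5;
const double KM_CAI = 3.59e-3, KM_CAO = 1.3, KM_NAI = 12.29, KM_NAO = 87.5;
const double KSAT = 0.32, NU = 0.27, KDACT = 0.150e-3;
const double IBAR_NAK = 1.8;
const double KM_NAIP = 11.0, KM_KO = 1.5;
const double IBAR_PMCA = 0.0673, KM_PCA = 0.5e-3;
const double GCAB = 5.513e-4;

// SR calcium handling
const double VMAX_SERCA = 5.3114e-3;  // mM/ms
const double KMF = 0.246e-3, KMR = 1.7, HILL_SERCA = 1.787;
const double KS_RYR = 25.0, KO_CA = 10.0, KOM = 0.06;
const double KI_CA = 0.5, KIM = 0.005, EC50SR = 0.45;
const double MAX_SR = 15.0, MIN_SR = 1.0;
const double SR_LEAK = 5.348e-6;

// buffering
const double BMAX_NAJ = 7.561, BMAX_NASL = 1.65;
const double KOFF_NA = 1e-3, KON_NA = 0.1e-3;
const double BMAX_TNCLOW = 70e-3, KOFF_TNCL = 19.6e-3, KON_TNCL = 32.7;
const double BMAX_TNCHIGH = 140e-3;
const double KOFF_TNCHCA = 0.032e-3, KON_TNCHCA = 2.37;
const double KOFF_TNCHMG = 3.33e-3, KON_TNCHMG = 3e-3;
const double BMAX_CAM = 24e-3, KOFF_CAM = 238e-3, KON_CAM = 34.0;
const double BMAX_MYOSIN = 140e-3;
const double KOFF_MYOCA = 0.46e-3, KON_MYOCA = 13.8;
const double KOFF_MYOMG = 0.057e-3, KON_MYOMG = 0.0157;
const double BMAX_SR = 19.0 * 0.9e-3, KOFF_SR = 60e-3, KON_SR = 100.0;
const double BMAX_SLLSL = 37.4e-3 * VMYO / VSL;
const double BMAX_SLLJ  = 4.6e-3 * VMYO / VJUNC * 0.1;
const double BMAX_SLHSL = 13.4e-3 * VMYO / VSL;
const double BMAX_SLHJ  = 1.65e-3 * VMYO / VJUNC * 0.1;
const double KOFF_SLL = 1300e-3, KON_SLL = 100.0;
const double KOFF_SLH = 30e-3, KON_SLH = 100.0;
const double BMAX_CSQN = 140e-3 * VMYO / VSR;
const double KOFF_CSQN = 65.0, KON_CSQN = 100.0;

// endo/epi transient-outward split
const double GTO_SLOW_EPI = 0.13 * 0.12, GTO_FAST_EPI = 0.13 * 0.88;
const double GTO_SLOW_ENDO = 0.13 * 0.3 * 0.964, GTO_FAST_ENDO = 0.13 * 0.3 * 0.036;

inline double sq(double x) { return x * x; }

// x/(exp(a*x)-1) with removable singularity at x=0
inline double xon_expm1(double x, double a) {
  double ax = a * x;
  if (std::fabs(ax) < 1e-7) return 1.0 / (a * (1.0 + 0.5 * ax));
  return x / (std::exp(ax) - 1.0);
}

// exact exponential update for a linear ODE x' = a - b x over dt; the
// series branch is exact to ~1e-8 for b*dt < 0.02 and avoids exp calls
inline double lin_exp_update(double x, double a, double b, double dt) {
  double xinf = a / b;
  double u = b * dt;
  double e = (u < 0.02) ? 1.0 - u * (1.0 - 0.5 * u * (1.0 - u / 3.0))
                        : std::exp(-u);
  return xinf + (x - xinf) * e;
}

// x^p for x > 0 via exp/log (faster than std::pow on this hot path)
inline double powp(double x, double p) { return std::exp(p * std::log(x)); }

} // namespace

// ---------------------------------------------------------------------------
// voltage-dependent quantities (exact)
// ---------------------------------------------------------------------------
void gpb_vdep_exact(double v, double dt, GpbVdep& r) {
  // fast sodium
  r.minf = 1.0 / sq(1.0 + std::exp(-(56.86 + v) / 9.03));
  double taum = 0.1292 * std::exp(-sq((v + 45.79) / 15.54))
              + 0.06487 * std::exp(-sq((v - 4.823) / 51.12));
  r.mrl = std::exp(-dt / taum);

  double ah = (v >= -40.0) ? 0.0 : 0.057 * std::exp(-(v + 80.0) / 6.8);
  double bh = (v >= -40.0)
      ? 0.77 / (0.13 * (1.0 + std::exp(-(v + 10.66) / 11.1)))
      : 2.7 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.3485 * v);
  double tauh = 1.0 / (ah + bh);
  r.hinf = 1.0 / sq(1.0 + std::exp((v + 71.55) / 7.43));
  r.hrl = std::exp(-dt / tauh);

  double aj = (v >= -40.0) ? 0.0
      : ((-2.5428e4 * std::exp(0.2444 * v) - 6.948e-6 * std::exp(-0.04391 * v))
         * (v + 37.78)) / (1.0 + std::exp(0.311 * (v + 79.23)));
  double bj = (v >= -40.0)
      ? (0.6 * std::exp(0.057 * v)) / (1.0 + std::exp(-0.1 * (v + 32.0)))
      : (0.02424 * std::exp(-0.01052 * v)) / (1.0 + std::exp(-0.1378 * (v + 40.14)));
  double tauj = 1.0 / (aj + bj);
  r.jinf = r.hinf;
  r.jrl = std::exp(-dt / tauj);

  // late sodium (LR-style activation, slow inactivation tau 600 ms)
  double aml, x = v + 47.13;
  if (std::fabs(x) < 1e-7) aml = 3.2;
  else aml = 0.32 * x / (1.0 - std::exp(-0.1 * x));
  double bml = 0.08 * std::exp(-v / 11.0);
  r.mlinf = aml / (aml + bml);
  r.mlrl = std::exp(-dt * (aml + bml));
  r.hlinf = 1.0 / (1.0 + std::exp((v + 91.0) / 6.1));
  r.hlrl = std::exp(-dt / 600.0);

  // L-type calcium gates
  r.dinf = 1.0 / (1.0 + std::exp(-(v + 5.0) / 6.0));
  double vd5 = v + 5.0;
  double taud;
  if (std::fabs(vd5) < 1e-7)
    taud = r.dinf / (0.035 * 6.0);
  else
    taud = r.dinf * (1.0 - std::exp(-vd5 / 6.0)) / (0.035 * vd5);
  r.drl = std::exp(-dt / taud);
  double finf = 1.0 / (1.0 + std::exp((v + 35.0) / 9.0))
              + 0.6 / (1.0 + std::exp((50.0 - v) / 20.0));
  r.finf = finf > 1.0 ? 1.0 : finf;
  double tauf = 1.0 / (0.0197 * std::exp(-sq(0.0337 * (v + 14.5))) + 0.02);
  r.frl = std::exp(-dt / tauf);

  // transient outward
  r.xtosinf = 1.0 / (1.0 + std::exp(-(v - 19.0) / 13.0));
  r.ytosinf = 1.0 / (1.0 + std::exp((v + 19.5) / 5.0));
  double tauxtos = 9.0 / (1.0 + std::exp((v + 3.0) / 15.0)) + 0.5;
  double tauytos = 800.0 / (1.0 + std::exp((v + 60.0) / 10.0)) + 30.0;
  r.xtosrl = std::exp(-dt / tauxtos);
  r.ytosrl = std::exp(-dt / tauytos);
  r.xtofinf = r.xtosinf;
  r.ytofinf = r.ytosinf;
  double tauxtof = 8.5 * std::exp(-sq((v + 45.0) / 50.0)) + 0.5;
  double tauytof = 85.0 * std::exp(-sq(v + 40.0) / 220.0) + 5.5;
  r.xtofrl = std::exp(-dt / tauxtof);
  r.ytofrl = std::exp(-dt / tauytof);

  // rapid delayed rectifier
  r.xkrinf = 1.0 / (1.0 + std::exp(-(v + 10.0) / 5.0));
  double tauxkr = 550.0 / (1.0 + std::exp((-22.0 - v) / 9.0))
                  * 6.0 / (1.0 + std::exp((v + 11.0) / 9.0))
                + 230.0 / (1.0 + std::exp((v + 40.0) / 20.0));
  r.xkrrl = std::exp(-dt / tauxkr);
  r.rkr = 1.0 / (1.0 + std::exp((v + 74.0) / 24.0));

  // slow delayed rectifier
  r.xksinf = 1.0 / (1.0 + std::exp(-(v + 3.8) / 14.25));
  double tauxks = 990.1 / (1.0 + std::exp(-(v + 2.436) / 14.12));
  r.xksrl = std::exp(-dt / tauxks);

  // inward rectifier (internal K fixed at 120 mM)
  const double EK = (1.0 / FoRT) * std::log(KO / 120.0);
  double vek = v - EK;
  double aki = 1.02 / (1.0 + std::exp(0.2385 * (vek - 59.215)));
  double bki = (0.49124 * std::exp(0.08032 * (vek + 5.476))
              + std::exp(0.06175 * (vek - 594.31)))
             / (1.0 + std::exp(-0.5143 * (vek + 4.753)));
  r.ik1v = 0.35 * std::sqrt(KO / 5.4) * (aki / (aki + bki)) * vek;

  // plateau K
  r.kpv = 1.0 / (1.0 + std::exp(7.488 - v / 5.98));

  // Na/K pump voltage factor
  double sigma = (std::exp(NAO / 67.3) - 1.0) / 7.0;
  r.fnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * v * FoRT)
                  + 0.0365 * sigma * std::exp(-v * FoRT));

  // NCX voltage factors
  r.ncx_e1 = std::exp(NU * v * FoRT);
  r.ncx_e2 = std::exp((NU - 1.0) * v * FoRT);
  r.ncx_den = 1.0 / (1.0 + KSAT * r.ncx_e2);

  // GHK driving terms: ibar = a*Cin - b with a,b voltage-only
  double z2 = xon_expm1(v, 2.0 * FoRT);   // v/(exp(2 v F/RT)-1)
  double z1 = xon_expm1(v, FoRT);
  double e2 = std::exp(2.0 * v * FoRT);
  double e1 = std::exp(v * FoRT);
  r.aca = PCA * 4.0 * FRDY * FoRT * z2 * 0.341 * e2;
  r.bca = PCA * 4.0 * FRDY * FoRT * z2 * 0.341 * CAO;
  r.ana = PNA * FRDY * FoRT * z1 * 0.75 * e1;
  r.bna = PNA * FRDY * FoRT * z1 * 0.75 * NAO;
  r.ibark = PK * FRDY * FoRT * z1 * (0.75 * 120.0 * e1 - 0.75 * KO);
}

// ---------------------------------------------------------------------------
// lookup tables (linear interpolation over V)
// ---------------------------------------------------------------------------
namespace {
const int NQ_GPB = sizeof(GpbVdep) / sizeof(double);
const double TAB_VMIN = -120.0, TAB_VMAX = 90.0, TAB_DV = 0.02;
}

void GpbTables::build(double dt_) {
  dt = dt_;
  vmin = TAB_VMIN; dv = TAB_DV; inv_dv = 1.0 / dv;
  nv = (int)std::floor((TAB_VMAX - TAB_VMIN) / dv) + 2;
  tab.assign((size_t)nv * NQ_GPB, 0.0);
  GpbVdep r;
  for (int i = 0; i < nv; ++i) {
    gpb_vdep_exact(vmin + i * dv, dt, r);
    const double* src = reinterpret_cast<const double*>(&r);
    double* dst = &tab[(size_t)i * NQ_GPB];
    for (int q = 0; q < NQ_GPB; ++q) dst[q] = src[q];
  }
}

void GpbTables::lookup(double v, GpbVdep& r) const {
  double u = (v - vmin) * inv_dv;
  if (u < 0.0) u = 0.0;
  if (u > nv - 2) u = nv - 2;
  int i = (int)u;
  double w = u - i;
  const double* a = &tab[(size_t)i * NQ_GPB];
  const double* b = a + NQ_GPB;
  double* dst = reinterpret_cast<double*>(&r);
  for (int q = 0; q < NQ_GPB; ++q) dst[q] = a[q] + w * (b[q] - a[q]);
}

// ---------------------------------------------------------------------------
// one reaction step
// ---------------------------------------------------------------------------
double gpb_step(double vm, double* y, const GpbVdep& vd, const GpbParams& p,
                double dt, double istim) {
  const double* s = p.scale;

  // reversal potentials (internal Na dynamic, K and Cl fixed)
  double ena_junc = (1.0 / FoRT) * std::log(NAO / y[Y_NAJ]);
  double ena_sl   = (1.0 / FoRT) * std::log(NAO / y[Y_NASL]);
  const double ek  = (1.0 / FoRT) * std::log(KO / 120.0);
  double eca_junc = (0.5 / FoRT) * std::log(CAO / y[Y_CAJ]);
  double eca_sl   = (0.5 / FoRT) * std::log(CAO / y[Y_CASL]);
  const double ecl = (1.0 / FoRT) * std::log(CLI / CLO);
  double eks = (1.0 / FoRT)
      * std::log((KO + P_NAK_PERM * NAO) / (120.0 + P_NAK_PERM * y[Y_NAI]));

  // fast and late sodium
  double m3hj = y[Y_M] * y[Y_M] * y[Y_M] * y[Y_H] * y[Y_J];
  double gna = GNA * s[OV_GNA];
  double ina_junc = FJUNC * gna * m3hj * (vm - ena_junc);
  double ina_sl   = FSL * gna * m3hj * (vm - ena_sl);
  double ml3hl = y[Y_ML] * y[Y_ML] * y[Y_ML] * y[Y_HL];
  double gnal = GNAL * s[OV_GNAL];
  double inal_junc = FJUNC * gnal * ml3hl * (vm - ena_junc);
  double inal_sl   = FSL * gnal * ml3hl * (vm - ena_sl);
  double gnab = GNAB * s[OV_GNAB];
  double inab_junc = FJUNC * gnab * (vm - ena_junc);
  double inab_sl   = FSL * gnab * (vm - ena_sl);

  // Na/K pump
  double inak_base = IBAR_NAK * s[OV_NAK] * vd.fnak * KO / (KO + KM_KO);
  double kmj = KM_NAIP / y[Y_NAJ];  kmj *= kmj; kmj *= kmj;
  double kms = KM_NAIP / y[Y_NASL]; kms *= kms; kms *= kms;
  double inak_junc = FJUNC * inak_base / (1.0 + kmj);
  double inak_sl   = FSL * inak_base / (1.0 + kms);
  double inak = inak_junc + inak_sl;

  // K currents
  double ikr = 0.035 * std::sqrt(KO / 5.4) * s[OV_GKR] * y[Y_XKR] * vd.rkr * (vm - ek);
  double gks = (GKS_J * FJUNC + GKS_SL * FSL) * s[OV_GKS];
  double iks = gks * y[Y_XKS] * y[Y_XKS] * (vm - eks);
  double ikp = GKP * s[OV_GKP] * vd.kpv * (vm - ek);
  double gto_slow = (p.epi ? GTO_SLOW_EPI : GTO_SLOW_ENDO) * s[OV_GTO];
  double gto_fast = (p.epi ? GTO_FAST_EPI : GTO_FAST_ENDO) * s[OV_GTO];
  double itos = gto_slow * y[Y_XTOS] * y[Y_YTOS] * (vm - ek);
  double itof = gto_fast * y[Y_XTOF] * y[Y_YTOF] * (vm - ek);
  double ik1 = s[OV_GK1] * vd.ik1v;

  // Cl currents
  double iclca = GCLCA * s[OV_GCLCA]
      * (FJUNC / (1.0 + KD_CLCA / y[Y_CAJ]) + FSL / (1.0 + KD_CLCA / y[Y_CASL]))
      * (vm - ecl);
  double iclbk = GCLB * s[OV_GCLB] * (vm - ecl);

  // L-type Ca current (GHK), gates d, f, Ca-dependent inactivation
  double df = y[Y_D] * y[Y_F];
  double pca_s = s[OV_PCA];
  double ibarca_j = vd.aca * y[Y_CAJ] - vd.bca;
  double ibarca_sl = vd.aca * y[Y_CASL] - vd.bca;
  double ica_junc = pca_s * FJUNC_CAL * ibarca_j * df * (1.0 - y[Y_FCABJ]) * 0.45;
  double ica_sl   = pca_s * FSL_CAL * ibarca_sl * df * (1.0 - y[Y_FCABSL]) * 0.45;
  double icak = pca_s * vd.ibark * df
      * (FJUNC_CAL * (1.0 - y[Y_FCABJ]) + FSL_CAL * (1.0 - y[Y_FCABSL])) * 0.45;
  double ibarna_j  = vd.ana * y[Y_NAJ] - vd.bna;
  double ibarna_sl = vd.ana * y[Y_NASL] - vd.bna;
  double icana_junc = pca_s * FJUNC_CAL * ibarna_j * df * (1.0 - y[Y_FCABJ]) * 0.45;
  double icana_sl   = pca_s * FSL_CAL * ibarna_sl * df * (1.0 - y[Y_FCABSL]) * 0.45;

  // Na/Ca exchanger
  double ncx_bar = IBAR_NCX * s[OV_NCX];
  double caj = y[Y_CAJ], casl = y[Y_CASL];
  double naj3 = y[Y_NAJ] * y[Y_NAJ] * y[Y_NAJ];
  double nasl3 = y[Y_NASL] * y[Y_NASL] * y[Y_NASL];
  const double nao3 = NAO * NAO * NAO;
  double ka_j = 1.0 / (1.0 + sq(KDACT / caj));
  double ka_sl = 1.0 / (1.0 + sq(KDACT / casl));
  double knai3 = KM_NAI * KM_NAI * KM_NAI;
  double s3_j = KM_CAI * nao3 * (1.0 + naj3 / knai3)
      + KM_NAO * KM_NAO * KM_NAO * caj * (1.0 + caj / KM_CAI)
      + KM_CAO * naj3 + naj3 * CAO + nao3 * caj;
  double s3_sl = KM_CAI * nao3 * (1.0 + nasl3 / knai3)
      + KM_NAO * KM_NAO * KM_NAO * casl * (1.0 + casl / KM_CAI)
      + KM_CAO * nasl3 + nasl3 * CAO + nao3 * casl;
  double incx_junc = FJUNC * ncx_bar * ka_j
      * (vd.ncx_e1 * naj3 * CAO - vd.ncx_e2 * nao3 * caj) / s3_j * vd.ncx_den;
  double incx_sl = FSL * ncx_bar * ka_sl
      * (vd.ncx_e1 * nasl3 * CAO - vd.ncx_e2 * nao3 * casl) / s3_sl * vd.ncx_den;

  // sarcolemmal Ca pump and background
  double pmca_bar = IBAR_PMCA * s[OV_PMCA];
  double caj16 = powp(caj, 1.6), casl16 = powp(casl, 1.6);
  static const double kmpca16 = std::pow(KM_PCA, 1.6);
  double ipca_junc = FJUNC * pmca_bar * caj16 / (kmpca16 + caj16);
  double ipca_sl   = FSL * pmca_bar * casl16 / (kmpca16 + casl16);
  double gcab = GCAB * s[OV_GCAB];
  double icab_junc = FJUNC * gcab * (vm - eca_junc);
  double icab_sl   = FSL * gcab * (vm - eca_sl);

  // SR fluxes
  double casr = y[Y_CASR], cai = y[Y_CAI];
  double ecr = EC50SR / casr;
  double kcasr = MAX_SR - (MAX_SR - MIN_SR) / (1.0 + ecr * ecr * std::sqrt(ecr));
  double ko_sr = KO_CA * s[OV_RYR_KOCA] / kcasr;
  double ki_sr = KI_CA * kcasr;
  double ri = 1.0 - y[Y_RYRR] - y[Y_RYRO] - y[Y_RYRI];
  double d_ryrr = (KIM * ri - ki_sr * caj * y[Y_RYRR])
                - (ko_sr * caj * caj * y[Y_RYRR] - KOM * y[Y_RYRO]);
  double d_ryro = (ko_sr * caj * caj * y[Y_RYRR] - KOM * y[Y_RYRO])
                - (ki_sr * caj * y[Y_RYRO] - KIM * y[Y_RYRI]);
  double d_ryri = (ki_sr * caj * y[Y_RYRO] - KIM * y[Y_RYRI])
                - (KOM * y[Y_RYRI] - ko_sr * caj * caj * ri);
  double j_srcarel = KS_RYR * s[OV_RYR_KS] * y[Y_RYRO] * (casr - caj);
  double fw = powp(cai / KMF, HILL_SERCA);
  double rv = powp(casr / KMR, HILL_SERCA);
  double j_serca = VMAX_SERCA * s[OV_SERCA] * (fw - rv) / (1.0 + fw + rv);
  double j_srleak = SR_LEAK * s[OV_SRLEAK] * (casr - caj);

  // --- buffer updates (exact exponential step for the linear ODEs) ---
  // sodium buffers
  double nabj_new = lin_exp_update(y[Y_NABJ], KON_NA * y[Y_NAJ] * BMAX_NAJ,
                                   KON_NA * y[Y_NAJ] + KOFF_NA, dt);
  double nabsl_new = lin_exp_update(y[Y_NABSL], KON_NA * y[Y_NASL] * BMAX_NASL,
                                    KON_NA * y[Y_NASL] + KOFF_NA, dt);
  double d_nabj = (nabj_new - y[Y_NABJ]) / dt;
  double d_nabsl = (nabsl_new - y[Y_NABSL]) / dt;

  // cytosolic Ca/Mg buffers (high-affinity troponin and myosin share sites,
  // stepped with frozen occupancy of the partner species over dt)
  double tnchc = y[Y_TNCHC], tnchm = y[Y_TNCHM];
  double myoc = y[Y_MYOC], myom = y[Y_MYOM];
  double tncl_new = lin_exp_update(y[Y_TNCL], KON_TNCL * cai * BMAX_TNCLOW,
                                   KON_TNCL * cai + KOFF_TNCL, dt);
  double tnchc_new = lin_exp_update(tnchc, KON_TNCHCA * cai * (BMAX_TNCHIGH - tnchm),
                                    KON_TNCHCA * cai + KOFF_TNCHCA, dt);
  double tnchm_new = lin_exp_update(tnchm, KON_TNCHMG * MGI * (BMAX_TNCHIGH - tnchc),
                                    KON_TNCHMG * MGI + KOFF_TNCHMG, dt);
  double cam_new = lin_exp_update(y[Y_CAM], KON_CAM * cai * BMAX_CAM,
                                  KON_CAM * cai + KOFF_CAM, dt);
  double myoc_new = lin_exp_update(myoc, KON_MYOCA * cai * (BMAX_MYOSIN - myom),
                                   KON_MYOCA * cai + KOFF_MYOCA, dt);
  double myom_new = lin_exp_update(myom, KON_MYOMG * MGI * (BMAX_MYOSIN - myoc),
                                   KON_MYOMG * MGI + KOFF_MYOMG, dt);
  double srb_new = lin_exp_update(y[Y_SRB], KON_SR * cai * BMAX_SR,
                                  KON_SR * cai + KOFF_SR, dt);
  double j_cab_cytosol = ((tncl_new - y[Y_TNCL]) + (tnchc_new - tnchc)
      + (tnchm_new - tnchm) + (cam_new - y[Y_CAM]) + (myoc_new - myoc)
      + (myom_new - myom) + (srb_new - y[Y_SRB])) / dt;

  // junctional and SL membrane buffers
  double sllj_new = lin_exp_update(y[Y_SLLJ], KON_SLL * caj * BMAX_SLLJ,
                                   KON_SLL * caj + KOFF_SLL, dt);
  double sllsl_new = lin_exp_update(y[Y_SLLSL], KON_SLL * casl * BMAX_SLLSL,
                                    KON_SLL * casl + KOFF_SLL, dt);
  double slhj_new = lin_exp_update(y[Y_SLHJ], KON_SLH * caj * BMAX_SLHJ,
                                   KON_SLH * caj + KOFF_SLH, dt);
  double slhsl_new = lin_exp_update(y[Y_SLHSL], KON_SLH * casl * BMAX_SLHSL,
                                    KON_SLH * casl + KOFF_SLH, dt);
  double j_cab_junc = ((sllj_new - y[Y_SLLJ]) + (slhj_new - y[Y_SLHJ])) / dt;
  double j_cab_sl = ((sllsl_new - y[Y_SLLSL]) + (slhsl_new - y[Y_SLHSL])) / dt;

  // calsequestrin
  double csqn_new = lin_exp_update(y[Y_CSQNB], KON_CSQN * casr * BMAX_CSQN,
                                   KON_CSQN * casr + KOFF_CSQN, dt);
  double d_csqn = (csqn_new - y[Y_CSQNB]) / dt;

  // --- current groupings ---
  double ina_tot_junc = ina_junc + inal_junc + inab_junc + 3.0 * incx_junc
      + 3.0 * inak_junc + icana_junc;
  double ina_tot_sl = ina_sl + inal_sl + inab_sl + 3.0 * incx_sl
      + 3.0 * inak_sl + icana_sl;
  double ik_tot = itos + itof + ikr + iks + ik1 - 2.0 * inak + icak + ikp;
  double ica_tot_junc = ica_junc + icab_junc + ipca_junc - 2.0 * incx_junc;
  double ica_tot_sl = ica_sl + icab_sl + ipca_sl - 2.0 * incx_sl;
  double icl_tot = iclca + iclbk;
  double itot = ina_tot_junc + ina_tot_sl + icl_tot + ica_tot_junc + ica_tot_sl
      + ik_tot;

  // --- state updates ---
  // gates via Rush-Larsen
  y[Y_M] = vd.minf + (y[Y_M] - vd.minf) * vd.mrl;
  y[Y_H] = vd.hinf + (y[Y_H] - vd.hinf) * vd.hrl;
  y[Y_J] = vd.jinf + (y[Y_J] - vd.jinf) * vd.jrl;
  y[Y_D] = vd.dinf + (y[Y_D] - vd.dinf) * vd.drl;
  y[Y_F] = vd.finf + (y[Y_F] - vd.finf) * vd.frl;
  y[Y_XTOS] = vd.xtosinf + (y[Y_XTOS] - vd.xtosinf) * vd.xtosrl;
  y[Y_YTOS] = vd.ytosinf + (y[Y_YTOS] - vd.ytosinf) * vd.ytosrl;
  y[Y_XTOF] = vd.xtofinf + (y[Y_XTOF] - vd.xtofinf) * vd.xtofrl;
  y[Y_YTOF] = vd.ytofinf + (y[Y_YTOF] - vd.ytofinf) * vd.ytofrl;
  y[Y_XKR] = vd.xkrinf + (y[Y_XKR] - vd.xkrinf) * vd.xkrrl;
  y[Y_XKS] = vd.xksinf + (y[Y_XKS] - vd.xksinf) * vd.xksrl;
  y[Y_ML] = vd.mlinf + (y[Y_ML] - vd.mlinf) * vd.mlrl;
  y[Y_HL] = vd.hlinf + (y[Y_HL] - vd.hlinf) * vd.hlrl;

  // Ca-dependent ICaL inactivation (linear in state, exponential step)
  y[Y_FCABJ] = lin_exp_update(y[Y_FCABJ], 1.7 * caj, 1.7 * caj + 11.9e-3, dt);
  y[Y_FCABSL] = lin_exp_update(y[Y_FCABSL], 1.7 * casl, 1.7 * casl + 11.9e-3, dt);

  // RyR (forward Euler)
  y[Y_RYRR] += dt * d_ryrr;
  y[Y_RYRO] += dt * d_ryro;
  y[Y_RYRI] += dt * d_ryri;

  // buffers
  y[Y_NABJ] = nabj_new;  y[Y_NABSL] = nabsl_new;
  y[Y_TNCL] = tncl_new;  y[Y_TNCHC] = tnchc_new;  y[Y_TNCHM] = tnchm_new;
  y[Y_CAM] = cam_new;    y[Y_MYOC] = myoc_new;    y[Y_MYOM] = myom_new;
  y[Y_SRB] = srb_new;
  y[Y_SLLJ] = sllj_new;  y[Y_SLLSL] = sllsl_new;
  y[Y_SLHJ] = slhj_new;  y[Y_SLHSL] = slhsl_new;
  y[Y_CSQNB] = csqn_new;

  // ionic concentrations (forward Euler)
  double d_naj = -ina_tot_junc * CMEM / (VJUNC * FRDY)
      + J_NA_JUNCSL / VJUNC * (y[Y_NASL] - y[Y_NAJ]) - d_nabj;
  double d_nasl = -ina_tot_sl * CMEM / (VSL * FRDY)
      + J_NA_JUNCSL / VSL * (y[Y_NAJ] - y[Y_NASL])
      + J_NA_SLMYO / VSL * (y[Y_NAI] - y[Y_NASL]) - d_nabsl;
  double d_nai = J_NA_SLMYO / VMYO * (y[Y_NASL] - y[Y_NAI]);
  double d_caj = -ica_tot_junc * CMEM / (VJUNC * 2.0 * FRDY)
      + J_CA_JUNCSL / VJUNC * (casl - caj) - j_cab_junc
      + j_srcarel * VSR / VJUNC + j_srleak * VMYO / VJUNC;
  double d_casl = -ica_tot_sl * CMEM / (VSL * 2.0 * FRDY)
      + J_CA_JUNCSL / VSL * (caj - casl) + J_CA_SLMYO / VSL * (cai - casl)
      - j_cab_sl;
  double d_cai = -j_serca * VSR / VMYO - j_cab_cytosol
      + J_CA_SLMYO / VMYO * (casl - cai);
  double d_casr = j_serca - (j_srleak * VMYO / VSR + j_srcarel) - d_csqn;

  y[Y_NAJ] += dt * d_naj;
  y[Y_NASL] += dt * d_nasl;
  y[Y_NAI] += dt * d_nai;
  // internal K clamped (standard for this model at 1 Hz pacing)
  y[Y_CAJ] += dt * d_caj;
  y[Y_CASL] += dt * d_casl;
  y[Y_CAI] += dt * d_cai;
  y[Y_CASR] += dt * d_casr;

  return vm + dt * (-itot + istim);
}

// resting-state initial conditions (published model steady state at 1 Hz;
// relax_cell() refines them to this implementation's own quiescent state)
void gpb_initial_state(double* vm, double* y) {
  *vm = -81.4602;
  y[Y_M] = 1.405627e-3;  y[Y_H] = 9.867005e-1;  y[Y_J] = 9.915620e-1;
  y[Y_D] = 7.175662e-6;  y[Y_F] = 1.0;
  y[Y_FCABJ] = 2.421991e-2;  y[Y_FCABSL] = 1.452605e-2;
  y[Y_XTOS] = 4.051574e-3;   y[Y_YTOS] = 9.945511e-1;
  y[Y_XTOF] = 4.051574e-3;   y[Y_YTOF] = 9.945511e-1;
  y[Y_XKR] = 8.641386e-3;    y[Y_XKS] = 5.412034e-3;
  y[Y_ML] = 3.0e-3;          y[Y_HL] = 1.6e-1;
  y[Y_RYRR] = 8.884332e-1;   y[Y_RYRO] = 8.156628e-7;  y[Y_RYRI] = 1.024274e-7;
  y[Y_NABJ] = 3.539892;      y[Y_NABSL] = 7.720854e-1;
  y[Y_TNCL] = 8.773191e-3;   y[Y_TNCHC] = 1.078283e-1; y[Y_TNCHM] = 1.524002e-2;
  y[Y_CAM] = 2.911916e-4;    y[Y_MYOC] = 1.298754e-3;  y[Y_MYOM] = 1.381982e-1;
  y[Y_SRB] = 2.143165e-3;
  y[Y_SLLJ] = 9.566355e-3;   y[Y_SLLSL] = 1.110363e-1;
  y[Y_SLHJ] = 7.347888e-3;   y[Y_SLHSL] = 7.297378e-2;
  y[Y_CSQNB] = 1.242988;
  y[Y_NAJ] = 9.136;  y[Y_NASL] = 9.136;  y[Y_NAI] = 9.136;  y[Y_KI] = 120.0;
  y[Y_CAJ] = 1.737475e-4;  y[Y_CASL] = 1.031812e-4;  y[Y_CAI] = 8.597401e-5;
  y[Y_CASR] = 0.5545201;
}

// ---------------------------------------------------------------------------
// MacCannell active fibroblast (Cm 6.3 pF; currents in A/F)
// ---------------------------------------------------------------------------
namespace {
const double FIB_KI = 129.4349, FIB_NAI = 8.5547;   // mM, fixed
const double FIB_NAO = 130.011, FIB_KO = 5.4;
const double FIB_GKV = 0.25, FIB_GK1 = 0.4822, FIB_GBNA = 0.0095;
const double FIB_INAK_MAX = 2.002;
const double FIB_KMK = 1.0, FIB_KMNA = 11.0;
const double FIB_VREV = -150.0, FIB_B = -200.0;
const int NQ_FIB = sizeof(FibVdep) / sizeof(double);
}

void fib_vdep_exact(double v, double dt, FibVdep& r) {
  const double ek = (1.0 / FoRT) * std::log(FIB_KO / FIB_KI);
  const double ena = (1.0 / FoRT) * std::log(FIB_NAO / FIB_NAI);

  r.rinf = 1.0 / (1.0 + std::exp(-(v + 20.0) / 11.0));
  double taur = 20.3 + 138.0 * std::exp(-sq((v + 20.0) / 25.9));
  r.rrl = std::exp(-dt / taur);
  r.sinf = 1.0 / (1.0 + std::exp((v + 23.0) / 7.0));
  double taus = 1574.0 + 5268.0 * std::exp(-sq((v + 23.0) / 22.7));
  r.srl = std::exp(-dt / taus);

  double vek = v - ek;
  double a = 0.1 / (1.0 + std::exp(0.06 * (vek - 200.0)));
  double b = (3.0 * std::exp(0.0002 * (vek + 100.0)) + std::exp(0.1 * (vek - 10.0)))
           / (1.0 + std::exp(-0.5 * vek));
  r.ik1v = FIB_GK1 * (a / (a + b)) * vek;

  double na15 = std::pow(FIB_NAI, 1.5);
  r.inakv = FIB_INAK_MAX * (FIB_KO / (FIB_KO + FIB_KMK))
      * (na15 / (na15 + std::pow(FIB_KMNA, 1.5)))
      * (v - FIB_VREV) / (v - FIB_B);

  r.ibnav = FIB_GBNA * (v - ena);
}

void FibTables::build(double dt_) {
  dt = dt_;
  vmin = TAB_VMIN; dv = TAB_DV; inv_dv = 1.0 / dv;
  nv = (int)std::floor((TAB_VMAX - TAB_VMIN) / dv) + 2;
  tab.assign((size_t)nv * NQ_FIB, 0.0);
  FibVdep r;
  for (int i = 0; i < nv; ++i) {
    fib_vdep_exact(vmin + i * dv, dt, r);
    const double* src = reinterpret_cast<const double*>(&r);
    double* dst = &tab[(size_t)i * NQ_FIB];
    for (int q = 0; q < NQ_FIB; ++q) dst[q] = src[q];
  }
}

void FibTables::lookup(double v, FibVdep& r) const {
  double u = (v - vmin) * inv_dv;
  if (u < 0.0) u = 0.0;
  if (u > nv - 2) u = nv - 2;
  int i = (int)u;
  double w = u - i;
  const double* a = &tab[(size_t)i * NQ_FIB];
  const double* b = a + NQ_FIB;
  double* dst = reinterpret_cast<double*>(&r);
  for (int q = 0; q < NQ_FIB; ++q) dst[q] = a[q] + w * (b[q] - a[q]);
}

double fib_step(double vm, double* y, const FibVdep& vd, const FibParams& p,
                double dt, double istim) {
  const double ek = (1.0 / FoRT) * std::log(FIB_KO / FIB_KI);
  double ikv = p.scale_gkv * FIB_GKV * y[YF_R] * y[YF_S] * (vm - ek);
  double ik1 = p.scale_gk1 * vd.ik1v;
  double inak = p.scale_inak * vd.inakv;
  double ibna = p.scale_gbna * vd.ibnav;

  y[YF_R] = vd.rinf + (y[YF_R] - vd.rinf) * vd.rrl;
  y[YF_S] = vd.sinf + (y[YF_S] - vd.sinf) * vd.srl;

  return vm + dt * (-(ikv + ik1 + inak + ibna) + istim);
}

void fib_initial_state(double* vm, double* y) {
  *vm = -49.6;
  FibVdep r;
  fib_vdep_exact(-49.6, 1.0, r);
  y[YF_R] = r.rinf;
  y[YF_S] = r.sinf;
}
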