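#ifndef CARDIOWAVE_MODELS_H
#define CARDIOWAVE_MODELS_H

#include <vector>
#include <string>
#include <cmath>

// ---------------------------------------------------------------------------
// Grandi-Pasqualini-Bers (GPB) human ventricular myocyte model with an added
// late sodium current, plus the MacCannell active fibroblast model.
// All currents in A/F (pA/pF), time in ms, voltage in mV, concentrations mM.
// Gating variables advance by Rush-Larsen; linear buffer ODEs by exact
// exponential updates; everything else by forward Euler.
// ---------------------------------------------------------------------------

// indices into the myocyte gate/concentration vector (membrane potential is
// carried separately)
enum GpbIdx {
  Y_M = 0, Y_H, Y_J, Y_D, Y_F, Y_FCABJ, Y_FCABSL,
  Y_XTOS, Y_YTOS, Y_XTOF, Y_YTOF, Y_XKR, Y_XKS, Y_ML, Y_HL,
  Y_RYRR, Y_RYRO, Y_RYRI,
  Y_NABJ, Y_NABSL,
  Y_TNCL, Y_TNCHC, Y_TNCHM, Y_CAM, Y_MYOC, Y_MYOM, Y_SRB,
  Y_SLLJ, Y_SLLSL, Y_SLHJ, Y_SLHSL, Y_CSQNB,
  Y_NAJ, Y_NASL, Y_NAI, Y_KI,
  Y_CAJ, Y_CASL, Y_CAI, Y_CASR,
  N_GPB_Y  // 40
};

enum FibIdx { YF_R = 0, YF_S, N_FIB_Y };

// multiplicative conductance / flux overrides (order fixed; names in models.cpp)
enum OvIdx {
  OV_GNA = 0, OV_GNAL, OV_GNAB, OV_GK1, OV_GKR, OV_GKS, OV_GKP, OV_GTO,
  OV_GCLCA, OV_GCLB, OV_PCA, OV_NCX, OV_NAK, OV_PMCA, OV_GCAB,
  OV_SERCA, OV_SRLEAK, OV_RYR_KS, OV_RYR_KOCA,
  N_OV
};

extern const char* OV_NAMES[N_OV];

struct GpbParams {
  bool   epi;             // epicardial transmural variant (Ito split)
  double scale[N_OV];     // multiplicative overrides, all 1 for NC
  GpbParams() : epi(false) { for (int i = 0; i < N_OV; ++i) scale[i] = 1.0; }
};

// voltage-dependent quantities needed by one myocyte step
struct GpbVdep {
  // gate steady states and Rush-Larsen factors exp(-dt/tau)
  double minf, mrl, hinf, hrl, jinf, jrl, dinf, drl, finf, frl;
  double xtosinf, xtosrl, ytosinf, ytosrl, xtofinf, xtofrl, ytofinf, ytofrl;
  double xkrinf, xkrrl, xksinf, xksrl, mlinf, mlrl, hlinf, hlrl;
  // voltage-only current factors
  double ik1v;            // 0.35*sqrt(Ko/5.4)*kiss*(V-ek), before GK1 override
  double rkr;             // IKr inactivation factor
  double kpv;             // IKp voltage factor
  double fnak;            // INaK voltage factor
  double ncx_e1, ncx_e2;  // exp(nu V F/RT), exp((nu-1) V F/RT)
  double ncx_den;         // 1/(1+ksat*exp((nu-1) V F/RT))
  double aca, bca;        // ibarca = aca*Ca - bca (GHK, per permeability)
  double ana, bna;        // ibarna = ana*Na - bna
  double ibark;           // full K GHK term (internal K fixed)
};

// exact (closed-form) evaluation, used to build tables and as oracle
void gpb_vdep_exact(double v, double dt, GpbVdep& r);

struct GpbTables {
  double vmin, dv, inv_dv;
  int    nv;
  std::vector<double> tab;  // nv rows x NQ quantities, V-major
  double dt;
  void build(double dt);
  void lookup(double v, GpbVdep& r) const;
};

// one myocyte reaction step; returns new Vm. 'name_of_nan' receives the
// state name on non-finite results (empty when fine).
double gpb_step(double vm, double* y, const GpbVdep& vd, const GpbParams& p,
                double dt, double istim);

// published resting initial conditions (vm + 40 states)
void gpb_initial_state(double* vm, double* y);

// ---------------------------------------------------------------------------
// MacCannell active fibroblast
// ---------------------------------------------------------------------------
struct FibParams {
  double scale_gkv, scale_gk1, scale_gbna, scale_inak;
  FibParams() : scale_gkv(1), scale_gk1(1), scale_gbna(1), scale_inak(1) {}
};

struct FibVdep {
  double rinf, rrl, sinf, srl;
  double ik1v;   // full IK1(V) at unit scale
  double inakv;  // full INaK(V) at unit scale
  double ibnav;  // full IbNa(V) at unit scale
};

void fib_vdep_exact(double v, double dt, FibVdep& r);

struct FibTables {
  double vmin, dv, inv_dv;
  int    nv;
  std::vector<double> tab;
  double dt;
  void build(double dt);
  void lookup(double v, FibVdep& r) const;
};

double fib_step(double vm, double* y, const FibVdep& vd, const FibParams& p,
                double dt, double istim);

void fib_initial_state(double* vm, double* y);

#endif
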