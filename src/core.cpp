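// Core integration engine for the closed-loop 0D circulation, the aortic-valve
// state machine, the distributed coronary-segment solver and the partitioned
// 0D<->segment coupling loop. Internal units: mmHg, mL, s. SI enters only
// through the valve/stenosis formulas (rho in kg/m^3, mu in Pa s).
#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double MMHG = 133.322;        // Pa per mmHg
// SI -> internal conversions for R [Pa s/m^3], B [Pa s^2/m^6], L [Pa s^2/m^3]
static const double R_SI2MM = 1e-6 / MMHG;
static const double B_SI2MM = 1e-12 / MMHG;
static const double L_SI2MM = 1e-6 / MMHG;

// ---------------------------------------------------------------------------
// state vector layout (0-based)
enum StateIdx {
  iV_la = 0, iV_lv, iV_ra, iV_rv,
  iQ_av,
  iV_ao,
  iQ_ub, iV_uba, iV_ubc, iV_ubv,
  iQ_lb, iV_lba, iV_lbc, iV_lbv,
  iV_pa, iV_pc, iV_pv,
  iQ_lad,
  iV_epi_lad, iV_l1_lad, iV_l2_lad, iV_l3_lad, iV_ven_lad,
  iV_epi_lcx, iV_l1_lcx, iV_l2_lcx, iV_l3_lcx, iV_ven_lcx,
  iV_epi_rca, iV_l1_rca, iV_l2_rca, iV_l3_rca, iV_ven_rca,
  NSTATE
};

struct Chamber { double emax, emin, v0, onset, dur, pf; };

struct Branch {
  double rprox, lprox, cepi;
  double rin[3], rout[3], cl[3];
  double cven, rvout;
  double sten_b, sten_rex;   // Bernoulli coeff (mmHg/(mL/s)^2) and extra viscous R
  double rmult;              // autoregulation multiplier on arteriolar rin
  int drive;                 // 1 = LV, 2 = RV
};

struct Params {
  double rho, mu;
  double T;
  Chamber lv, la, rv, ra;
  // aortic valve
  double av_eoa_s, av_eoa_d, av_ado, av_leaflet, av_ar, av_ab, av_al;
  double av_rbase, av_lbase, av_ramp, av_eoa_min;
  double mi_r, tri_r, pul_r;
  // systemic
  double c_ao;
  double ub_rart, ub_lart, ub_cart, ub_rcap, ub_ccap, ub_rven, ub_cven, ub_rout;
  double lb_rart, lb_lart, lb_cart, lb_rcap, lb_ccap, lb_rven, lb_cven, lb_rout;
  // pulmonary
  double c_pa, p_rc, c_pc, p_rcv, c_pvn, p_rout;
  // coronary
  double gam1, gam2, gam3;
  Branch lad, lcx, rca;
  // lumped-mode equivalents of the coupled segment (in series with lad.rprox)
  double seg_req, seg_leq, seg_beq;
};

static double gp(const NumericVector& p, const char* nm) {
  CharacterVector nms = p.names();
  for (int i = 0; i < p.size(); ++i)
    if (std::strcmp(nms[i], nm) == 0) return p[i];
  stop("parameter '%s' missing from flattened config", nm);
  return NA_REAL;
}

static void fill_chamber(Chamber& c, const NumericVector& p, const std::string& pre) {
  c.emax  = gp(p, (pre + "_emax").c_str());
  c.emin  = gp(p, (pre + "_emin").c_str());
  c.v0    = gp(p, (pre + "_v0").c_str());
  c.onset = gp(p, (pre + "_onset").c_str());
  c.dur   = gp(p, (pre + "_dur").c_str());
  c.pf    = gp(p, (pre + "_pf").c_str());
}

static void fill_branch(Branch& b, const NumericVector& p, const std::string& pre) {
  b.rprox = gp(p, (pre + "_rprox").c_str());
  b.lprox = gp(p, (pre + "_lprox").c_str());
  b.cepi  = gp(p, (pre + "_cepi").c_str());
  for (int l = 0; l < 3; ++l) {
    std::string s = std::to_string(l + 1);
    b.rin[l]  = gp(p, (pre + "_rin"  + s).c_str());
    b.rout[l] = gp(p, (pre + "_rout" + s).c_str());
    b.cl[l]   = gp(p, (pre + "_cl"   + s).c_str());
  }
  b.cven    = gp(p, (pre + "_cven").c_str());
  b.rvout   = gp(p, (pre + "_rvout").c_str());
  b.sten_b  = gp(p, (pre + "_sten_b").c_str());
  b.sten_rex= gp(p, (pre + "_sten_rex").c_str());
  b.rmult   = gp(p, (pre + "_rmult").c_str());
  b.drive   = (int) gp(p, (pre + "_drive").c_str());
}

static Params parse_params(const NumericVector& p) {
  Params P;
  P.rho = gp(p, "rho"); P.mu = gp(p, "mu"); P.T = gp(p, "period");
  fill_chamber(P.lv, p, "lv"); fill_chamber(P.la, p, "la");
  fill_chamber(P.rv, p, "rv"); fill_chamber(P.ra, p, "ra");
  P.av_eoa_s = gp(p, "av_eoa_s"); P.av_eoa_d = gp(p, "av_eoa_d");
  P.av_ado = gp(p, "av_ado"); P.av_leaflet = gp(p, "av_leaflet");
  P.av_ar = gp(p, "av_ar"); P.av_ab = gp(p, "av_ab"); P.av_al = gp(p, "av_al");
  P.av_rbase = gp(p, "av_rbase"); P.av_lbase = gp(p, "av_lbase");
  P.av_ramp = gp(p, "av_ramp"); P.av_eoa_min = gp(p, "av_eoa_min");
  P.mi_r = gp(p, "mi_r"); P.tri_r = gp(p, "tri_r"); P.pul_r = gp(p, "pul_r");
  P.c_ao = gp(p, "c_ao");
  P.ub_rart = gp(p, "ub_rart"); P.ub_lart = gp(p, "ub_lart");
  P.ub_cart = gp(p, "ub_cart"); P.ub_rcap = gp(p, "ub_rcap");
  P.ub_ccap = gp(p, "ub_ccap"); P.ub_rven = gp(p, "ub_rven");
  P.ub_cven = gp(p, "ub_cven"); P.ub_rout = gp(p, "ub_rout");
  P.lb_rart = gp(p, "lb_rart"); P.lb_lart = gp(p, "lb_lart");
  P.lb_cart = gp(p, "lb_cart"); P.lb_rcap = gp(p, "lb_rcap");
  P.lb_ccap = gp(p, "lb_ccap"); P.lb_rven = gp(p, "lb_rven");
  P.lb_cven = gp(p, "lb_cven"); P.lb_rout = gp(p, "lb_rout");
  P.c_pa = gp(p, "c_pa"); P.p_rc = gp(p, "p_rc"); P.c_pc = gp(p, "c_pc");
  P.p_rcv = gp(p, "p_rcv"); P.c_pvn = gp(p, "c_pvn"); P.p_rout = gp(p, "p_rout");
  P.gam1 = gp(p, "gam1"); P.gam2 = gp(p, "gam2"); P.gam3 = gp(p, "gam3");
  fill_branch(P.lad, p, "lad"); fill_branch(P.lcx, p, "lcx"); fill_branch(P.rca, p, "rca");
  P.seg_req = gp(p, "seg_req"); P.seg_leq = gp(p, "seg_leq"); P.seg_beq = gp(p, "seg_beq");
  return P;
}

// ---------------------------------------------------------------------------
// elastance activation: exactly 0 outside the activation window and exactly
// 1 at its peak (at fraction pf of the duration). The upstroke uses a
// fast-foot cosine (near-linear onset, like the early power-law rise of
// Hill-type activations) so isovolumic pressure build-up is brisk; the
// relaxation limb is a plain raised cosine.
static double activation(double t, double onset, double dur, double T,
                         double pf) {
  double tt = t - onset;
  tt -= T * std::floor(tt / T);   // periodic wrap into [0, T)
  if (tt >= dur) return 0.0;
  double tp = pf * dur;
  if (tt < tp) return 0.5 * (1.0 - std::cos(M_PI * std::sqrt(tt / tp)));
  return 0.5 * (1.0 + std::cos(M_PI * (tt - tp) / (dur - tp)));
}

static double elastance_of(const Chamber& c, double t, double T) {
  return c.emin + (c.emax - c.emin) * activation(t, c.onset, c.dur, T, c.pf);
}

static double chamber_p(const Chamber& c, double V, double t, double T) {
  return elastance_of(c, t, T) * (V - c.v0);
}

// aortic valve R/B/L from geometry (inputs: EOA, Ado in cm^2, leaflet in cm;
// outputs in mmHg-mL-s units)
static void valve_rbl(double eoa_cm2, double ado_cm2, double l_cm,
                      double rho, double mu, double aR, double aB, double aL,
                      double& R, double& B, double& L) {
  double eoa = eoa_cm2 * 1e-4, ado = ado_cm2 * 1e-4, l = l_cm * 0.01;
  double Rsi = 8.0 * aR * M_PI * mu * l / (eoa * eoa);
  double d = 1.0 / eoa - 1.0 / ado;
  double Bsi = 0.5 * rho * aB * d * d;
  double Lsi = (2.0 * rho * aL / std::sqrt(M_PI)) *
               (1.0 / std::sqrt(eoa) - 1.0 / std::sqrt(ado));
  R = Rsi * R_SI2MM; B = Bsi * B_SI2MM; L = Lsi * L_SI2MM;
}

static inline double diode(double dp, double r) { return dp > 0 ? dp / r : 0.0; }

// algebraic flow through R + B|Q|Q element given a pressure difference
static double rb_flow(double dp, double r, double b) {
  if (b <= 0) return dp / r;
  double ad = std::fabs(dp);
  double q = (-r + std::sqrt(r * r + 4.0 * b * ad)) / (2.0 * b);
  return dp >= 0 ? q : -q;
}

// ---------------------------------------------------------------------------
// aux observable layout
enum AuxIdx {
  aP_lv = 0, aP_la, aP_rv, aP_ra, aP_ao,
  aQ_av, aEOA, aOPEN,
  aQ_mi, aQ_pul,
  aQ_lad, aQ_lcx, aQ_rca,
  aP_epi_lad, aP_epi_lcx, aP_epi_rca,
  aQ_lad_in1, aQ_lad_in2, aQ_lad_in3,
  aQ_cor_ven, aP_seg_in, aQ_seg_out, aP_root,
  NAUX
};

struct Boundary {        // segment-returned boundary data (coupled mode)
  bool coupled;
  double p_in;           // segment inlet pressure -> closes the 0D proximal flow ODE
  double q_out;          // segment outlet flow -> inflow of distal epicardial node
};

// branch contribution; returns proximal inflow actually drawn from the aorta
static double branch_derivs(const Branch& b, const Params& P, const double* y,
                            double* dy, double t, double p_ao, double p_ra,
                            double p_lv_ch, double p_rv_ch,
                            int i_epi, bool is_lad, const Boundary& bd,
                            double* q_in_rec, double& q_ven_out) {
  double p_epi = y[i_epi] / b.cepi;
  double p_drive = (b.drive == 1) ? p_lv_ch : p_rv_ch;
  if (p_drive < 0) p_drive = 0;
  double gam[3] = { P.gam1, P.gam2, P.gam3 };
  double p_ven = y[i_epi + 4] / b.cven;
  double q_in_sum = 0, q_out_sum = 0;
  for (int l = 0; l < 3; ++l) {
    double p_l = y[i_epi + 1 + l] / b.cl[l] + gam[l] * p_drive;
    double q_in  = (p_epi - p_l) / (b.rin[l] * b.rmult);
    double q_out = (p_l - p_ven) / b.rout[l];
    dy[i_epi + 1 + l] = q_in - q_out;
    q_in_sum += q_in; q_out_sum += q_out;
    if (q_in_rec) q_in_rec[l] = q_in;
  }
  q_ven_out = (p_ven - p_ra) / b.rvout;
  dy[i_epi + 4] = q_out_sum - q_ven_out;

  double q_prox;
  if (is_lad) {
    q_prox = y[iQ_lad];
    if (bd.coupled) {
      // added-mass-stabilized partitioned form: the segment's (known, fixed)
      // series inertance is carried inside the 0D momentum equation, and the
      // returned inlet pressure enters through its quasi-static part
      dy[iQ_lad] = (p_ao - bd.p_in - b.rprox * q_prox) /
                   (b.lprox + P.seg_leq);
      dy[i_epi] = bd.q_out - q_in_sum;
    } else {
      double rr = b.rprox + P.seg_req + b.sten_rex;
      double bb = b.sten_b + P.seg_beq;
      dy[iQ_lad] = (p_ao - p_epi - rr * q_prox - bb * q_prox * std::fabs(q_prox)) /
                   (b.lprox + P.seg_leq);
      dy[i_epi] = q_prox - q_in_sum;
    }
  } else {
    q_prox = rb_flow(p_ao - p_epi, b.rprox + b.sten_rex, b.sten_b);
    dy[i_epi] = q_prox - q_in_sum;
  }
  return q_prox;
}

// full network right-hand side; eoa_now (cm^2) and valve_closed are the current
// aortic-valve state (piecewise constant over a step)
static void derivs(const Params& P, const double* y, double t,
                   double eoa_now, bool valve_closed, const Boundary& bd,
                   double* dy, double* aux, bool valve_open = false) {
  double p_lv = chamber_p(P.lv, y[iV_lv], t, P.T);
  double p_la = chamber_p(P.la, y[iV_la], t, P.T);
  double p_rv = chamber_p(P.rv, y[iV_rv], t, P.T);
  double p_ra = chamber_p(P.ra, y[iV_ra], t, P.T);
  double p_ao = y[iV_ao] / P.c_ao;

  // aortic valve
  double q_av = y[iQ_av];
  if (valve_closed) {
    dy[iQ_av] = 0.0;
    q_av = 0.0;
  } else {
    double R, B, L;
    double eoa_eff = std::max(eoa_now, P.av_eoa_min);
    valve_rbl(eoa_eff, P.av_ado, P.av_leaflet, P.rho, P.mu,
              P.av_ar, P.av_ab, P.av_al, R, B, L);
    dy[iQ_av] = (p_lv - p_ao - (R + P.av_rbase) * q_av - B * q_av * std::fabs(q_av)) /
                (L + P.av_lbase);
  }

  // other valves (algebraic diodes)
  double q_mi  = diode(p_la - p_lv, P.mi_r);
  double q_tri = diode(p_ra - p_rv, P.tri_r);
  double p_pa  = y[iV_pa] / P.c_pa;
  double q_pul = diode(p_rv - p_pa, P.pul_r);

  // systemic upper body
  double p_uba = y[iV_uba] / P.ub_cart, p_ubc = y[iV_ubc] / P.ub_ccap,
         p_ubv = y[iV_ubv] / P.ub_cven;
  dy[iQ_ub] = (p_ao - p_uba - P.ub_rart * y[iQ_ub]) / P.ub_lart;
  double q_ubc = (p_uba - p_ubc) / P.ub_rcap;
  double q_ubv = (p_ubc - p_ubv) / P.ub_rven;
  double q_ubo = (p_ubv - p_ra) / P.ub_rout;
  dy[iV_uba] = y[iQ_ub] - q_ubc;
  dy[iV_ubc] = q_ubc - q_ubv;
  dy[iV_ubv] = q_ubv - q_ubo;

  // systemic lower body
  double p_lba = y[iV_lba] / P.lb_cart, p_lbc = y[iV_lbc] / P.lb_ccap,
         p_lbv = y[iV_lbv] / P.lb_cven;
  dy[iQ_lb] = (p_ao - p_lba - P.lb_rart * y[iQ_lb]) / P.lb_lart;
  double q_lbc = (p_lba - p_lbc) / P.lb_rcap;
  double q_lbv = (p_lbc - p_lbv) / P.lb_rven;
  double q_lbo = (p_lbv - p_ra) / P.lb_rout;
  dy[iV_lba] = y[iQ_lb] - q_lbc;
  dy[iV_lbc] = q_lbc - q_lbv;
  dy[iV_lbv] = q_lbv - q_lbo;

  // pulmonary
  double p_pc = y[iV_pc] / P.c_pc, p_pv = y[iV_pv] / P.c_pvn;
  double q_pc  = (p_pa - p_pc) / P.p_rc;
  double q_pcv = (p_pc - p_pv) / P.p_rcv;
  double q_plo = (p_pv - p_la) / P.p_rout;
  dy[iV_pa] = q_pul - q_pc;
  dy[iV_pc] = q_pc - q_pcv;
  dy[iV_pv] = q_pcv - q_plo;

  // coronary branches; the ostia sit in the aortic root proximal to the
  // characteristic impedance, so their driving pressure carries the
  // forward-wave component of ejection
  double p_ost = p_ao + P.av_rbase * q_av;
  double q_in_lad[3], qv_lad, qv_lcx, qv_rca;
  double q_lad = branch_derivs(P.lad, P, y, dy, t, p_ost, p_ra, p_lv, p_rv,
                               iV_epi_lad, true, bd, q_in_lad, qv_lad);
  double q_lcx = branch_derivs(P.lcx, P, y, dy, t, p_ost, p_ra, p_lv, p_rv,
                               iV_epi_lcx, false, bd, nullptr, qv_lcx);
  double q_rca = branch_derivs(P.rca, P, y, dy, t, p_ost, p_ra, p_lv, p_rv,
                               iV_epi_rca, false, bd, nullptr, qv_rca);
  double q_cor_ven = qv_lad + qv_lcx + qv_rca;

  // chambers and aortic root
  dy[iV_la] = q_plo - q_mi;
  dy[iV_lv] = q_mi - q_av;
  dy[iV_ra] = q_ubo + q_lbo + q_cor_ven - q_tri;
  dy[iV_rv] = q_tri - q_pul;
  dy[iV_ao] = q_av - y[iQ_ub] - y[iQ_lb] - q_lad - q_lcx - q_rca;

  if (aux) {
    aux[aP_lv] = p_lv; aux[aP_la] = p_la; aux[aP_rv] = p_rv; aux[aP_ra] = p_ra;
    aux[aP_ao] = p_ao; aux[aQ_av] = q_av; aux[aEOA] = eoa_now;
    aux[aOPEN] = valve_open ? 1 : 0;
    aux[aQ_mi] = q_mi; aux[aQ_pul] = q_pul;
    aux[aQ_lad] = q_lad; aux[aQ_lcx] = q_lcx; aux[aQ_rca] = q_rca;
    aux[aP_epi_lad] = y[iV_epi_lad] / P.lad.cepi;
    aux[aP_epi_lcx] = y[iV_epi_lcx] / P.lcx.cepi;
    aux[aP_epi_rca] = y[iV_epi_rca] / P.rca.cepi;
    aux[aQ_lad_in1] = q_in_lad[0]; aux[aQ_lad_in2] = q_in_lad[1];
    aux[aQ_lad_in3] = q_in_lad[2];
    aux[aQ_cor_ven] = q_cor_ven;
    aux[aP_seg_in] = bd.coupled ? bd.p_in : NA_REAL;
    aux[aQ_seg_out] = bd.coupled ? bd.q_out : NA_REAL;
    // ascending-aorta pressure proximal to the characteristic impedance
    aux[aP_root] = p_ao + P.av_rbase * q_av;
  }
}

// ---------------------------------------------------------------------------
// aortic valve state machine, advanced once per time step
struct ValveSt { bool open; double eoa; };

static void valve_update(ValveSt& v, const Params& P, const double* y, double t,
                         double dt) {
  double p_lv = chamber_p(P.lv, y[iV_lv], t, P.T);
  double p_ao = y[iV_ao] / P.c_ao;
  if (!v.open && p_lv > p_ao + 0.05) v.open = true;
  else if (v.open && y[iQ_av] < 0.0 && p_lv < p_ao) {
    v.open = false;
    // a competent valve (diastolic EOA = 0) seals at the flow-reversal
    // trigger, where Q ~ 0 keeps the pressure drop continuous; a regurgitant
    // orifice is reached through the ramp instead
    if (P.av_eoa_d <= 0.0) { v.eoa = 0.0; return; }
  }
  double target = v.open ? P.av_eoa_s : P.av_eoa_d;
  double span = std::fabs(P.av_eoa_s - P.av_eoa_d);
  double step = (span / P.av_ramp) * dt;   // linear ramp over av_ramp seconds
  if (v.eoa < target) v.eoa = std::min(v.eoa + step, target);
  else if (v.eoa > target) v.eoa = std::max(v.eoa - step, target);
  if (v.eoa < 1e-12) v.eoa = 0.0;
}

// ---------------------------------------------------------------------------
// distributed segment: backward-Euler step of an N-node R-L chain with small
// nodal capacitance; inlet flow and outlet pressure imposed
struct SegSt {
  int n;
  std::vector<double> R, L, B, Cn, P, Q;
};

static SegSt seg_from_list(const List& s) {
  SegSt g;
  g.n = as<int>(s["n"]);
  NumericVector R = s["R"], L = s["L"], B = s["B"], Cn = s["Cn"],
                P = s["P"], Q = s["Q"];
  g.R.assign(R.begin(), R.end()); g.L.assign(L.begin(), L.end());
  g.B.assign(B.begin(), B.end()); g.Cn.assign(Cn.begin(), Cn.end());
  g.P.assign(P.begin(), P.end()); g.Q.assign(Q.begin(), Q.end());
  return g;
}

static List seg_to_list(const SegSt& g) {
  return List::create(_["n"] = g.n, _["R"] = wrap(g.R), _["L"] = wrap(g.L),
                      _["B"] = wrap(g.B), _["Cn"] = wrap(g.Cn),
                      _["P"] = wrap(g.P), _["Q"] = wrap(g.Q));
}

// one implicit (backward-Euler) step; returns the inlet pressure and outlet
// flow at t^{n+1}, plus the purely resistive (quasi-static) part of the
// inlet-to-outlet pressure drop evaluated at the new flows
static void seg_step(SegSt& g, double q_in, double p_out, double dt,
                     double& p_in, double& q_out, double& p_qs) {
  int n = g.n;
  std::vector<double> alpha(n), beta(n);
  for (int k = 0; k < n; ++k) {
    double reff = g.R[k] + g.B[k] * std::fabs(g.Q[k]);  // Picard-linearized loss
    double denom = g.L[k] / dt + reff;
    beta[k] = 1.0 / denom;
    alpha[k] = (g.L[k] / dt) * g.Q[k] * beta[k];
  }
  // tridiagonal system in nodal pressures
  std::vector<double> a(n), b(n), c(n), d(n);
  for (int k = 0; k < n; ++k) {
    double cd = g.Cn[k] / dt;
    a[k] = (k > 0) ? -beta[k - 1] : 0.0;
    b[k] = cd + beta[k] + ((k > 0) ? beta[k - 1] : 0.0);
    c[k] = (k < n - 1) ? -beta[k] : 0.0;
    d[k] = cd * g.P[k] - alpha[k] + ((k > 0) ? alpha[k - 1] : q_in);
    if (k == n - 1) d[k] += beta[k] * p_out;
  }
  // Thomas algorithm
  for (int k = 1; k < n; ++k) {
    double m = a[k] / b[k - 1];
    b[k] -= m * c[k - 1];
    d[k] -= m * d[k - 1];
  }
  g.P[n - 1] = d[n - 1] / b[n - 1];
  for (int k = n - 2; k >= 0; --k) g.P[k] = (d[k] - c[k] * g.P[k + 1]) / b[k];
  p_qs = p_out;
  for (int k = 0; k < n; ++k) {
    double p_dn = (k < n - 1) ? g.P[k + 1] : p_out;
    g.Q[k] = alpha[k] + beta[k] * (g.P[k] - p_dn);
    if (!std::isfinite(g.Q[k]))
      stop("segment solver produced non-finite flow at compartment %d", k + 1);
    p_qs += (g.R[k] + g.B[k] * std::fabs(g.Q[k])) * g.Q[k];
  }
  p_in = g.P[0];
  q_out = g.Q[n - 1];
}

// ---------------------------------------------------------------------------
// exported interface

// [[Rcpp::export]]
List cv_derivs_cpp(NumericVector state, double t, NumericVector params,
                   double eoa_now, bool valve_closed,
                   bool coupled = false, double seg_p_in = 0.0,
                   double seg_q_out = 0.0) {
  if (state.size() != NSTATE)
    stop("state vector must have length %d, got %d", NSTATE, (int) state.size());
  Params P = parse_params(params);
  Boundary bd{coupled, seg_p_in, seg_q_out};
  std::vector<double> dy(NSTATE, 0.0), aux(NAUX, 0.0);
  derivs(P, REAL(state), t, eoa_now, valve_closed, bd, dy.data(), aux.data(),
         !valve_closed);
  NumericVector dyv = wrap(dy), auxv = wrap(aux);
  dyv.names() = state.names();
  auxv.names() = CharacterVector::create(
      "p_lv", "p_la", "p_rv", "p_ra", "p_ao", "q_av", "eoa", "valve_open",
      "q_mi", "q_pul", "q_lad", "q_lcx", "q_rca",
      "p_epi_lad", "p_epi_lcx", "p_epi_rca",
      "q_lad_in1", "q_lad_in2", "q_lad_in3", "q_cor_ven",
      "p_seg_in", "q_seg_out", "p_ao_root");
  return List::create(_["dy"] = dyv, _["aux"] = auxv);
}

// [[Rcpp::export]]
NumericVector valve_rbl_cpp(double eoa_cm2, double ado_cm2, double l_cm,
                            double rho, double mu, double aR, double aB,
                            double aL) {
  double R, B, L;
  valve_rbl(eoa_cm2, ado_cm2, l_cm, rho, mu, aR, aB, aL, R, B, L);
  NumericVector out = NumericVector::create(_["R"] = R, _["B"] = B, _["L"] = L);
  return out;
}

// [[Rcpp::export]]
List seg_step_cpp(List seg, double q_in, double p_out, double dt) {
  SegSt g = seg_from_list(seg);
  double p_in, q_out, p_qs;
  seg_step(g, q_in, p_out, dt, p_in, q_out, p_qs);
  return List::create(_["p_in"] = p_in, _["q_out"] = q_out,
                      _["p_qs"] = p_qs, _["seg"] = seg_to_list(g));
}

// advance the model n_steps of size dt from time t0; records one row per step
// at the pre-step time (so n_steps = T/dt covers exactly one period)
// [[Rcpp::export]]
List cv_advance_cpp(NumericVector state, NumericVector params, List valve,
                    int n_steps, double dt, double t0,
                    bool coupled = false, Nullable<List> segment = R_NilValue,
                    bool record = true) {
  if (state.size() != NSTATE)
    stop("state vector must have length %d, got %d", NSTATE, (int) state.size());
  Params P = parse_params(params);
  ValveSt v{as<bool>(valve["open"]), as<double>(valve["eoa"])};
  SegSt g;
  bool has_seg = coupled;
  if (coupled) {
    if (segment.isNull()) stop("coupled run requires a segment state");
    g = seg_from_list(segment.get());
  }
  std::vector<double> y(REAL(state), REAL(state) + NSTATE);
  std::vector<double> dy(NSTATE), aux(NAUX);
  std::vector<double> k1(NSTATE), k2(NSTATE), k3(NSTATE), k4(NSTATE),
      ytmp(NSTATE);
  NumericMatrix trace = record ? NumericMatrix(n_steps, 1 + NSTATE + NAUX)
                               : NumericMatrix(0, 0);
  NumericMatrix iface = (record && coupled) ? NumericMatrix(n_steps, 5)
                                            : NumericMatrix(0, 0);
  NumericMatrix segq = (record && coupled) ? NumericMatrix(n_steps, g.n)
                                           : NumericMatrix(0, 0);
  Boundary bd{false, 0.0, 0.0};
  double p_epi_prev = std::numeric_limits<double>::quiet_NaN();
  double t = t0;

  for (int s = 0; s < n_steps; ++s) {
    valve_update(v, P, y.data(), t, dt);
    bool closed = (!v.open && v.eoa <= 0.0);
    if (closed) y[iQ_av] = 0.0;

    double q_in_seg = 0, p_out_seg = 0, p_in_raw = 0;
    if (coupled) {
      // step 1 (Fig. 2): impose 0D solution at t^n on the segment; the
      // outlet pressure is extrapolated half a step forward from its last
      // increment so the fast distal node does not lag the exchange
      q_in_seg = y[iQ_lad];
      double p_epi_now = y[iV_epi_lad] / P.lad.cepi;
      p_out_seg = (p_epi_prev == p_epi_prev)  // not NaN after the first step
                      ? p_epi_now + 0.5 * (p_epi_now - p_epi_prev)
                      : p_epi_now;
      p_epi_prev = p_epi_now;
      double p_in, q_out, p_qs;
      seg_step(g, q_in_seg, p_out_seg, dt, p_in, q_out, p_qs);
      p_in_raw = p_in;
      // the segment's series inertance lives inside the 0D momentum
      // equation (see branch_derivs), so the boundary pressure fed back is
      // the quasi-static (resistive) part of the segment drop
      bd = Boundary{true, p_qs, q_out};
    } else {
      bd = Boundary{false, 0.0, 0.0};
    }

    derivs(P, y.data(), t, v.eoa, closed, bd, k1.data(),
           record ? aux.data() : nullptr, v.open);
    if (record) {
      trace(s, 0) = t;
      for (int i = 0; i < NSTATE; ++i) trace(s, 1 + i) = y[i];
      for (int i = 0; i < NAUX; ++i) trace(s, 1 + NSTATE + i) = aux[i];
      if (coupled) {
        iface(s, 0) = t; iface(s, 1) = q_in_seg; iface(s, 2) = p_out_seg;
        iface(s, 3) = p_in_raw; iface(s, 4) = bd.q_out;
        for (int k = 0; k < g.n; ++k) segq(s, k) = g.Q[k];
      }
    }

    // step 2: classical RK4 update of the 0D system with boundary data held
    for (int i = 0; i < NSTATE; ++i) ytmp[i] = y[i] + 0.5 * dt * k1[i];
    derivs(P, ytmp.data(), t + 0.5 * dt, v.eoa, closed, bd, k2.data(), nullptr);
    for (int i = 0; i < NSTATE; ++i) ytmp[i] = y[i] + 0.5 * dt * k2[i];
    derivs(P, ytmp.data(), t + 0.5 * dt, v.eoa, closed, bd, k3.data(), nullptr);
    for (int i = 0; i < NSTATE; ++i) ytmp[i] = y[i] + dt * k3[i];
    derivs(P, ytmp.data(), t + dt, v.eoa, closed, bd, k4.data(), nullptr);
    for (int i = 0; i < NSTATE; ++i) {
      y[i] += (dt / 6.0) * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (!std::isfinite(y[i]))
        stop("integration failure: non-finite state %d at t = %.4f", i + 1, t);
    }
    if (closed) y[iQ_av] = 0.0;
    t = t0 + (s + 1) * dt;
    if (std::fabs(y[iV_ao] / P.c_ao) > 1000.0)
      stop("divergence: |aortic pressure| > 1000 mmHg at t = %.4f", t);
  }

  NumericVector yout = wrap(y);
  yout.names() = state.names();
  List out = List::create(
      _["state"] = yout, _["t"] = t,
      _["valve"] = List::create(_["open"] = v.open, _["eoa"] = v.eoa),
      _["trace"] = record ? (SEXP) trace : R_NilValue,
      _["iface"] = (record && coupled) ? (SEXP) iface : R_NilValue,
      _["seg_q"] = (record && coupled) ? (SEXP) segq : R_NilValue,
      _["segment"] = coupled ? (SEXP) seg_to_list(g) : R_NilValue);
  return out;
}
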