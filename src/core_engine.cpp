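#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fixed-step RK4 integration of the continuous part of the closed-loop
// model: 19 wall-segment pistons (fiber length + hydraulic flow), two
// ventricular cavity nodes, two Gaussian-driven atria and seven passive
// compliance chambers connected by resistive links and diode valves.
// Electrical activation times are precomputed by the discrete-event
// conduction model and enter through the per-segment drive function.
//
// State layout (49):
//   y[0..18]   l    segment fiber lengths (cm)
//   y[19..37]  q    segment piston flows (mL/s)
//   y[38]      Vc_lv  LV cavity node volume (mL)
//   y[39]      Vc_rv  RV cavity node volume
//   y[40] V_ra, y[41] V_la, y[42] V_ao, y[43] V_sa, y[44] V_sv,
//   y[45] V_vc, y[46] V_pa, y[47] V_pc, y[48] V_pu

struct Params {
  int nseg;
  std::vector<double> l0, area, k_act, t_delay, tau_c, tau_r, t_plat, t_max,
      k_p1, k_p2, r_h, l_h, u_norm;
  std::vector<int> type;  // 0 = LV free wall, 1 = LV septal, 2 = RV
  double lt_slope, lt_max;
  std::vector< std::vector<double> > act;  // activation onsets per segment
  std::vector<double> ra_act, la_act;
  double ra_emin, ra_emax, ra_v0, ra_mu, ra_sigma;
  double la_emin, la_emax, la_v0, la_mu, la_sigma;
  double e_lv, v0_lv, e_rv, v0_rv;
  double e_ch[7], v0_ch[7];  // ao, sa, sv, vc, pa, pc, pu
  double r_link[7];  // ao-sa, sa-sv, sv-vc, vc-ra, pa-pc, pc-pu, pu-la
  double r_mit, r_aov, r_tri, r_pul;
};

static inline double latest_onset(const std::vector<double>& a, double t,
                                  double t_delay) {
  // latest activation whose drive has started at time t
  double best = -1e300;
  for (int k = (int)a.size() - 1; k >= 0; --k) {
    if (t - a[k] - t_delay > 0) { best = a[k]; break; }
  }
  return best;
}

static inline double latest_before(const std::vector<double>& a, double t) {
  double best = -1e300;
  for (int k = (int)a.size() - 1; k >= 0; --k) {
    if (a[k] <= t) { best = a[k]; break; }
  }
  return best;
}

static void rhs(double t, const double* y, double* dy, const Params& P,
                double* aux) {
  const int n = P.nseg;
  const double* l = y;
  const double* q = y + n;
  double Vc_lv = y[2 * n], Vc_rv = y[2 * n + 1];
  const double* Vch = y + 2 * n + 2;  // ra, la, ao, sa, sv, vc, pa, pc, pu

  double p_lv = P.e_lv * (Vc_lv - P.v0_lv);
  double p_rv = P.e_rv * (Vc_rv - P.v0_rv);

  // atria: Gaussian-driven time-varying elastance
  double g_ra = 0, g_la = 0;
  double on = latest_before(P.ra_act, t);
  if (on > -1e299) {
    double d = t - on - P.ra_mu;
    g_ra = std::exp(-d * d / (2 * P.ra_sigma * P.ra_sigma));
  }
  on = latest_before(P.la_act, t);
  if (on > -1e299) {
    double d = t - on - P.la_mu;
    g_la = std::exp(-d * d / (2 * P.la_sigma * P.la_sigma));
  }
  double p_ra = (P.ra_emin + g_ra * (P.ra_emax - P.ra_emin)) * (Vch[0] - P.ra_v0);
  double p_la = (P.la_emin + g_la * (P.la_emax - P.la_emin)) * (Vch[1] - P.la_v0);

  double p_ch[7];
  for (int c = 0; c < 7; ++c) p_ch[c] = P.e_ch[c] * (Vch[c + 2] - P.v0_ch[c]);
  double p_ao = p_ch[0], p_sa = p_ch[1], p_sv = p_ch[2], p_vc = p_ch[3],
         p_pa = p_ch[4], p_pc = p_ch[5], p_pu = p_ch[6];

  // valves (perfect diodes)
  double q_mit = p_la > p_lv ? (p_la - p_lv) / P.r_mit : 0.0;
  double q_aov = p_lv > p_ao ? (p_lv - p_ao) / P.r_aov : 0.0;
  double q_tri = p_ra > p_rv ? (p_ra - p_rv) / P.r_tri : 0.0;
  double q_pul = p_rv > p_pa ? (p_rv - p_pa) / P.r_pul : 0.0;

  // resistive links
  double q_ao_sa = (p_ao - p_sa) / P.r_link[0];
  double q_sa_sv = (p_sa - p_sv) / P.r_link[1];
  double q_sv_vc = (p_sv - p_vc) / P.r_link[2];
  double q_vc_ra = (p_vc - p_ra) / P.r_link[3];
  double q_pa_pc = (p_pa - p_pc) / P.r_link[4];
  double q_pc_pu = (p_pc - p_pu) / P.r_link[5];
  double q_pu_la = (p_pu - p_la) / P.r_link[6];

  // wall segments
  double sum_q_lv = 0, sum_q_rv = 0;
  for (int s = 0; s < n; ++s) {
    double onset = latest_onset(P.act[s], t, P.t_delay[s]);
    double u = 0;
    if (onset > -1e299) {
      double sdt = t - onset - P.t_delay[s];
      u = sdt <= P.t_plat[s]
              ? (1 - std::exp(-sdt / P.tau_c[s])) / P.u_norm[s]
              : std::exp(-(sdt - P.t_plat[s]) / P.tau_r[s]);
    }
    double ratio = l[s] / P.l0[s];
    double lam = 1 + P.lt_slope * (ratio - 1);
    if (lam < 0) lam = 0;
    if (lam > P.lt_max) lam = P.lt_max;
    double Ta = P.k_act[s] * P.t_max[s] * u * lam;
    double eps = ratio - 1;
    double Tp = eps >= 0 ? P.k_p1[s] * (std::exp(P.k_p2[s] * eps) - 1)
                         : P.k_p1[s] * P.k_p2[s] * eps;
    double p_seg = (Ta + Tp) / P.area[s];
    double load = P.type[s] == 1 ? (p_lv - p_rv) : (P.type[s] == 2 ? p_rv : p_lv);
    dy[n + s] = (p_seg - load - P.r_h[s] * q[s]) / P.l_h[s];
    dy[s] = -q[s] / P.area[s];
    if (P.type[s] == 2) sum_q_rv += q[s]; else sum_q_lv += q[s];
    if (aux) { aux[2 + s] = p_seg; aux[2 + n + s] = u; }
  }

  dy[2 * n] = sum_q_lv + q_mit - q_aov;       // LV cavity node
  dy[2 * n + 1] = sum_q_rv + q_tri - q_pul;   // RV cavity node
  dy[2 * n + 2] = q_vc_ra - q_tri;            // RA
  dy[2 * n + 3] = q_pu_la - q_mit;            // LA
  dy[2 * n + 4] = q_aov - q_ao_sa;            // ao
  dy[2 * n + 5] = q_ao_sa - q_sa_sv;          // sys_art
  dy[2 * n + 6] = q_sa_sv - q_sv_vc;          // sys_ven
  dy[2 * n + 7] = q_sv_vc - q_vc_ra;          // vc
  dy[2 * n + 8] = q_pul - q_pa_pc;            // pa
  dy[2 * n + 9] = q_pa_pc - q_pc_pu;          // pul_cap
  dy[2 * n + 10] = q_pc_pu - q_pu_la;         // pu

  // time axis is ms; flows and hydraulic parameters are per-second
  for (int i = 0; i < 2 * n + 11; ++i) dy[i] *= 1e-3;

  if (aux) {
    aux[0] = p_lv; aux[1] = p_rv;
    double* a = aux + 2 + 2 * n;
    a[0] = p_ra; a[1] = p_la; a[2] = p_ao; a[3] = p_sa; a[4] = p_sv;
    a[5] = p_vc; a[6] = p_pa; a[7] = p_pc; a[8] = p_pu;
    a[9] = q_mit; a[10] = q_aov; a[11] = q_tri; a[12] = q_pul;
  }
}

// [[Rcpp::export(name = ".core_run")]]
List core_run(List seg, List act, List atria, List cavity, List chambers,
              NumericVector links, NumericVector valves, NumericVector y0,
              double dt, int n_steps, int record_every) {
  Params P;
  NumericVector l0 = seg["l0"];
  P.nseg = l0.size();
  const int n = P.nseg;
  auto getv = [&](const char* nm) {
    NumericVector v = seg[nm];
    return std::vector<double>(v.begin(), v.end());
  };
  P.l0 = getv("l0"); P.area = getv("area_w"); P.k_act = getv("k_act");
  P.t_delay = getv("t_delay"); P.tau_c = getv("tau_c"); P.tau_r = getv("tau_r");
  P.t_plat = getv("t_plat");
  P.t_max = getv("t_max"); P.k_p1 = getv("k_p1"); P.k_p2 = getv("k_p2");
  P.r_h = getv("r_h"); P.l_h = getv("l_h");
  IntegerVector ty = seg["type"];
  P.type = std::vector<int>(ty.begin(), ty.end());
  P.lt_slope = as<double>(seg["lt_slope"]);
  P.lt_max = as<double>(seg["lt_max"]);
  P.u_norm.resize(n);
  for (int s = 0; s < n; ++s) {
    P.u_norm[s] = 1 - std::exp(-P.t_plat[s] / P.tau_c[s]);
  }
  P.act.resize(n);
  for (int s = 0; s < n; ++s) {
    NumericVector a = act[s];
    P.act[s] = std::vector<double>(a.begin(), a.end());
  }
  NumericVector ra_a = atria["ra_act"], la_a = atria["la_act"];
  P.ra_act = std::vector<double>(ra_a.begin(), ra_a.end());
  P.la_act = std::vector<double>(la_a.begin(), la_a.end());
  List ra = atria["ra"], la = atria["la"];
  P.ra_emin = as<double>(ra["e_min"]); P.ra_emax = as<double>(ra["e_max"]);
  P.ra_v0 = as<double>(ra["v0"]); P.ra_mu = as<double>(ra["mu"]);
  P.ra_sigma = as<double>(ra["sigma"]);
  P.la_emin = as<double>(la["e_min"]); P.la_emax = as<double>(la["e_max"]);
  P.la_v0 = as<double>(la["v0"]); P.la_mu = as<double>(la["mu"]);
  P.la_sigma = as<double>(la["sigma"]);
  List cav_lv = cavity["lv"], cav_rv = cavity["rv"];
  P.e_lv = as<double>(cav_lv["e"]); P.v0_lv = as<double>(cav_lv["v0"]);
  P.e_rv = as<double>(cav_rv["e"]); P.v0_rv = as<double>(cav_rv["v0"]);
  double voff_lv = as<double>(cav_lv["v_offset"]);
  double voff_rv = as<double>(cav_rv["v_offset"]);
  NumericVector ce = chambers["e"], cv0 = chambers["v0"];
  for (int c = 0; c < 7; ++c) { P.e_ch[c] = ce[c]; P.v0_ch[c] = cv0[c]; }
  for (int c = 0; c < 7; ++c) P.r_link[c] = links[c];
  P.r_mit = valves[0]; P.r_aov = valves[1];
  P.r_tri = valves[2]; P.r_pul = valves[3];

  const int dim = 2 * n + 11;
  if (y0.size() != dim) stop("state vector has wrong length");
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), yt(dim);
  const int naux = 2 + 2 * n + 13;
  std::vector<double> aux(naux);

  int n_rec = n_steps / record_every + 1;
  // columns: time, p_lv, p_rv, p_ra..p_pu (9), v_lv, v_rv, v_ra..v_pu (9),
  //          q_mit, q_aov, q_tri, q_pul, l[n], q[n], u[n]
  const int ncol = 1 + 2 + 9 + 2 + 9 + 4 + 3 * n;
  NumericMatrix out(n_rec, ncol);

  auto record = [&](int row, double t) {
    rhs(t, y.data(), k1.data(), P, aux.data());
    double sum_Al_lv = 0, sum_Al_rv = 0;
    for (int s = 0; s < n; ++s) {
      if (P.type[s] == 2) sum_Al_rv += P.area[s] * y[s];
      else sum_Al_lv += P.area[s] * y[s];
    }
    int c = 0;
    out(row, c++) = t;
    out(row, c++) = aux[0];                     // p_lv
    out(row, c++) = aux[1];                     // p_rv
    for (int k = 0; k < 9; ++k) out(row, c++) = aux[2 + 2 * n + k];  // pressures
    out(row, c++) = y[2 * n] + sum_Al_lv - voff_lv;   // v_lv (reported)
    out(row, c++) = y[2 * n + 1] + sum_Al_rv - voff_rv;
    for (int k = 0; k < 9; ++k) out(row, c++) = y[2 * n + 2 + k];    // volumes
    for (int k = 0; k < 4; ++k) out(row, c++) = aux[2 + 2 * n + 9 + k];
    for (int s = 0; s < n; ++s) out(row, c++) = y[s];
    for (int s = 0; s < n; ++s) out(row, c++) = y[n + s];
    for (int s = 0; s < n; ++s) out(row, c++) = aux[2 + n + s];
  };

  record(0, 0.0);
  int row = 1;
  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    rhs(t, y.data(), k1.data(), P, nullptr);
    for (int i = 0; i < dim; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
    rhs(t + 0.5 * dt, yt.data(), k2.data(), P, nullptr);
    for (int i = 0; i < dim; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
    rhs(t + 0.5 * dt, yt.data(), k3.data(), P, nullptr);
    for (int i = 0; i < dim; ++i) yt[i] = y[i] + dt * k3[i];
    rhs(t + dt, yt.data(), k4.data(), P, nullptr);
    for (int i = 0; i < dim; ++i) {
      y[i] += dt / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
      if (!std::isfinite(y[i])) {
        stop("solver divergence at t = %.1f ms (state %d non-finite)",
             t + dt, i + 1);
      }
    }
    if ((step + 1) % record_every == 0) {
      record(row, (step + 1) * dt);
      ++row;
    }
  }
  return List::create(_["out"] = out, _["y_final"] = NumericVector(y.begin(), y.end()));
}
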