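// 18-state whole-body glucose-insulin-NEFA model: right-hand side, exogenous
// inputs (oral dose, TG drive, insulin infusion, state clamps) and an adaptive
// Dormand-Prince RK45 integrator with forced stops at output/breakpoint times.
//
// The parameter vector layout here must match .glunefa_param_names in
// R/parameters.R; glunefa_param_names() exports the C++ ordering so the two
// can be cross-checked at load/test time.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <sstream>

using namespace Rcpp;

// ---- parameter indices (canonical order) -----------------------------------
enum Par {
  // fixed: Dalla Man glucose/insulin core + bookkeeping
  P_VG = 0, P_k1, P_k2, P_VI, P_m1, P_m2, P_m4, P_m5, P_HEb,
  P_kmax, P_kabs, P_kgri, P_f_bio, P_b_empt, P_d_empt,
  P_Fcns, P_p2U, P_ki, P_Ksec, P_alpha_sec, P_beta_sec, P_gamma_sec,
  P_ke1, P_ke2, P_nd1_floor,
  // free (calibrated)
  P_pA, P_pB, P_pC, P_kegp2, P_kegp3, P_kegp4, P_gamma_inf, P_kegp5,
  P_kuid1, P_kuid3, P_Km_uid, P_kra3, P_kd2, P_kd3, P_kd7, P_kn1,
  P_c_lpl, P_K_lpl, P_spill_b, P_K_sp, P_D_oftt,
  // basal constants
  P_Gb, P_Ib, P_EGPb, P_NEFA0, P_TGb, P_V_NEFA, P_BW,
  // derived (basal closure)
  P_kegp1, P_Gpb, P_Gtb, P_Ipb, P_Ilb, P_Sb, P_Ipob, P_m3b, P_m6,
  N_PAR
};

static const char* PAR_NAMES[N_PAR] = {
  "VG", "k1", "k2", "VI", "m1", "m2", "m4", "m5", "HEb",
  "kmax", "kabs", "kgri", "f_bio", "b_empt", "d_empt",
  "Fcns", "p2U", "ki", "Ksec", "alpha_sec", "beta_sec", "gamma_sec",
  "ke1", "ke2", "nd1_floor",
  "pA", "pB", "pC", "kegp2", "kegp3", "kegp4", "gamma_inf", "kegp5",
  "kuid1", "kuid3", "Km_uid", "kra3", "kd2", "kd3", "kd7", "kn1",
  "c_lpl", "K_lpl", "spill_b", "K_sp", "D_oftt",
  "Gb", "Ib", "EGPb", "NEFA0", "TGb", "V_NEFA", "BW",
  "kegp1", "Gpb", "Gtb", "Ipb", "Ilb", "Sb", "Ipob", "m3b", "m6"
};

// ---- state indices ----------------------------------------------------------
enum St {
  S_Qsto1 = 0, S_Qsto2, S_Qgut, S_Gp, S_Gt, S_Ip, S_Il, S_I1, S_Id,
  S_Ipo, S_Y, S_X, S_Id2, S_Id3, S_Id7, S_Nd1, S_NEFA, S_Qing,
  N_STATE
};

static const char* STATE_NAMES[N_STATE] = {
  "Qsto1", "Qsto2", "Qgut", "Gp", "Gt", "Ip", "Il", "I1", "Id",
  "Ipo", "Y", "X", "Id2", "Id3", "Id7", "Nd1", "NEFA", "Qing"
};

// flux record columns
enum Fl {
  F_EGP = 0, F_Ra, F_Uii, F_Uid, F_E, F_JA, F_JB, F_JC, F_JD,
  F_Jlpl, F_spill, F_ins_inf, F_TG, F_S,
  N_FLUX
};

static const char* FLUX_NAMES[N_FLUX] = {
  "EGP", "Ra", "U_ii", "U_id", "E", "J_A", "J_B", "J_C", "J_D",
  "J_lpl", "spill", "ins_inf", "TG", "S"
};

// ---- exogenous inputs -------------------------------------------------------
struct Signal {           // piecewise interpolation table
  std::vector<double> t, v;
  int type;               // 0 = linear (constant outside), 1 = step (left value)
  double at(double tt) const {
    const size_t n = t.size();
    if (n == 0) return NA_REAL;
    if (tt <= t[0]) return v[0];
    if (tt >= t[n - 1]) return v[n - 1];
    size_t hi = std::upper_bound(t.begin(), t.end(), tt) - t.begin();
    size_t lo = hi - 1;
    if (type == 1) return v[lo];
    double w = (tt - t[lo]) / (t[hi] - t[lo]);
    return v[lo] + w * (v[hi] - v[lo]);
  }
  double slope(double tt) const {
    const size_t n = t.size();
    if (type == 1 || n < 2 || tt <= t[0] || tt >= t[n - 1]) return 0.0;
    size_t hi = std::upper_bound(t.begin(), t.end(), tt) - t.begin();
    size_t lo = hi - 1;
    return (v[hi] - v[lo]) / (t[hi] - t[lo]);
  }
};

struct Inputs {
  double dose;                 // oral glucose mass in Qsto1 at t=0, mg
  Signal tg;                   // plasma TG concentration, umol/L
  Signal inf;                  // insulin infusion rate, pmol/kg/min (step)
  bool has_tg, has_inf;
  // clamps: parallel vectors of state index + signal
  std::vector<int> clamp_state;
  std::vector<Signal> clamp_sig;

  double tg_at(double t, const double* p) const {
    double x = has_tg ? tg.at(t) : p[P_TGb];
    return x > 0.0 ? x : 0.0;
  }
  double inf_at(double t) const {
    if (!has_inf) return 0.0;
    double x = inf.at(t);
    return x > 0.0 ? x : 0.0;
  }
};

static Signal parse_signal(List s) {
  Signal out;
  NumericVector t = s["t"], v = s["v"];
  out.t.assign(t.begin(), t.end());
  out.v.assign(v.begin(), v.end());
  out.type = s.containsElementNamed("type") ? as<int>(s["type"]) : 0;
  return out;
}

static Inputs parse_inputs(List in) {
  Inputs x;
  x.dose = in.containsElementNamed("dose") ? as<double>(in["dose"]) : 0.0;
  x.has_tg = in.containsElementNamed("tg") && !Rf_isNull(in["tg"]);
  if (x.has_tg) x.tg = parse_signal(in["tg"]);
  x.has_inf = in.containsElementNamed("ins_inf") && !Rf_isNull(in["ins_inf"]);
  if (x.has_inf) { x.inf = parse_signal(in["ins_inf"]); x.inf.type = 1; }
  if (in.containsElementNamed("clamps") && !Rf_isNull(in["clamps"])) {
    List cl = in["clamps"];
    for (int i = 0; i < cl.size(); ++i) {
      List ci = cl[i];
      x.clamp_state.push_back(as<int>(ci["state"]));
      x.clamp_sig.push_back(parse_signal(ci));
    }
  }
  return x;
}

// ---- model right-hand side --------------------------------------------------
// Evaluates derivatives and instantaneous fluxes at (t, y). Clamped states are
// overridden by their exogenous signal before evaluation; their derivatives
// are set to the signal slope so the stored trajectory follows the clamp.
static void rhs(double t, const double* y_in, const double* p,
                const Inputs& in, double* dy, double* fx) {
  double y[N_STATE];
  std::copy(y_in, y_in + N_STATE, y);

  // apply clamps and remember forced derivatives
  double forced_dy[N_STATE];
  bool is_clamped[N_STATE] = {false};
  for (size_t k = 0; k < in.clamp_state.size(); ++k) {
    int s = in.clamp_state[k];
    y[s] = in.clamp_sig[k].at(t);
    forced_dy[s] = in.clamp_sig[k].slope(t);
    is_clamped[s] = true;
  }

  const double G = y[S_Gp] / p[P_VG];      // plasma glucose, mg/dL
  const double I = y[S_Ip] / p[P_VI];      // plasma insulin, pmol/L
  const double ins_inf = in.inf_at(t);
  const double TG = in.tg_at(t, p);

  // --- gastro-intestinal glucose transit (nonlinear stomach emptying) ---
  double kempt = p[P_kmax];
  if (in.dose > 0.0) {
    const double Qsto = y[S_Qsto1] + y[S_Qsto2];
    const double aa = 5.0 / (2.0 * in.dose * (1.0 - p[P_b_empt]));
    const double bb = 5.0 / (2.0 * in.dose * p[P_d_empt]);
    kempt = p[P_kra3] + (p[P_kmax] - p[P_kra3]) / 2.0 *
      (std::tanh(aa * (Qsto - p[P_b_empt] * in.dose)) -
       std::tanh(bb * (Qsto - p[P_d_empt] * in.dose)) + 2.0);
  }
  dy[S_Qsto1] = -p[P_kgri] * y[S_Qsto1];
  dy[S_Qsto2] = -kempt * y[S_Qsto2] + p[P_kgri] * y[S_Qsto1];
  dy[S_Qgut]  = -p[P_kabs] * y[S_Qgut] + kempt * y[S_Qsto2];
  const double Ra = p[P_f_bio] * p[P_kabs] * y[S_Qgut] / p[P_BW];
  dy[S_Qing]  = Ra * p[P_BW];

  // --- endogenous glucose production (NEFA-modified) ---
  double EGP = p[P_kegp1] - p[P_kegp2] * y[S_Gp] - p[P_kegp3] * y[S_Id2]
    - p[P_kegp4] * (y[S_Ipo] + ins_inf / p[P_gamma_inf])
    + p[P_kegp5] * y[S_Nd1];
  if (EGP < 0.0) EGP = 0.0;

  // --- glucose utilization and excretion ---
  const double Uii = p[P_Fcns];
  const double Nd1f = std::max(y[S_Nd1], p[P_nd1_floor]);
  double Vmax = p[P_kuid1] + p[P_kuid3] * y[S_Id3] / Nd1f;
  if (Vmax < 0.0) Vmax = 0.0;
  const double Gt_pos = std::max(y[S_Gt], 0.0);
  const double Uid = Vmax * Gt_pos / (p[P_Km_uid] + Gt_pos);
  const double E = p[P_ke1] * std::max(y[S_Gp] - p[P_ke2], 0.0);

  dy[S_Gp] = EGP + Ra - Uii - E - p[P_k1] * y[S_Gp] + p[P_k2] * y[S_Gt];
  dy[S_Gt] = -Uid + p[P_k1] * y[S_Gp] - p[P_k2] * y[S_Gt];

  // --- insulin kinetics (dynamic hepatic extraction) ---
  const double S = p[P_gamma_sec] * y[S_Ipo];     // portal secretion, pmol/kg/min
  double HE = -p[P_m5] * S + p[P_m6];
  if (HE > 0.9) HE = 0.9;
  if (HE < 0.0) HE = 0.0;
  const double m3 = HE * p[P_m1] / (1.0 - HE);
  dy[S_Il] = -(p[P_m1] + m3) * y[S_Il] + p[P_m2] * y[S_Ip] + S;
  dy[S_Ip] = -(p[P_m2] + p[P_m4]) * y[S_Ip] + p[P_m1] * y[S_Il] + ins_inf;

  // --- beta-cell secretion ---
  const double dG = (is_clamped[S_Gp] ? forced_dy[S_Gp] : dy[S_Gp]) / p[P_VG];
  double Spo = y[S_Y] + p[P_Sb];
  if (dG > 0.0) Spo += p[P_Ksec] * dG;
  if (Spo < 0.0) Spo = 0.0;
  dy[S_Ipo] = -p[P_gamma_sec] * y[S_Ipo] + Spo;
  const double ytarget = p[P_beta_sec] * (G - p[P_Gb]);
  if (ytarget >= -p[P_Sb])
    dy[S_Y] = -p[P_alpha_sec] * (y[S_Y] - ytarget);
  else
    dy[S_Y] = -p[P_alpha_sec] * (y[S_Y] + p[P_Sb]);

  // --- delayed signals ---
  dy[S_X]   = -p[P_p2U] * y[S_X] + p[P_p2U] * (I - p[P_Ib]);
  dy[S_I1]  = -p[P_ki]  * (y[S_I1]  - I);
  dy[S_Id]  = -p[P_ki]  * (y[S_Id]  - y[S_I1]);
  dy[S_Id2] = -p[P_kd2] * (y[S_Id2] - y[S_Id]);
  dy[S_Id3] = -p[P_kd3] * (y[S_Id3] - I);
  dy[S_Id7] = -p[P_kd7] * (y[S_Id7] - I);
  dy[S_Nd1] = -p[P_kn1] * (y[S_Nd1] - y[S_NEFA]);

  // --- plasma NEFA kinetics ---
  const double Id7_pos = std::max(y[S_Id7], 0.0);
  const double Jlpl = p[P_c_lpl] * TG * Id7_pos / (p[P_K_lpl] + Id7_pos);
  double smax = p[P_spill_b] * (p[P_K_sp] + p[P_Ib]) / p[P_K_sp];
  if (smax > 1.0) smax = 1.0;
  double spill = smax * p[P_K_sp] / (p[P_K_sp] + Id7_pos);
  if (spill < 0.0) spill = 0.0;
  const double JA = p[P_pA] * y[S_NEFA];
  const double JB = p[P_pB] * (y[S_Id7] - p[P_Ib]) * y[S_NEFA];
  const double JC = p[P_pC];
  const double JD = spill * Jlpl / p[P_V_NEFA];
  dy[S_NEFA] = -JA - JB + JC + JD;

  // clamped states follow their signal exactly
  for (int s = 0; s < N_STATE; ++s)
    if (is_clamped[s]) dy[s] = forced_dy[s];

  if (fx) {
    fx[F_EGP] = EGP; fx[F_Ra] = Ra; fx[F_Uii] = Uii; fx[F_Uid] = Uid;
    fx[F_E] = E; fx[F_JA] = JA; fx[F_JB] = JB; fx[F_JC] = JC; fx[F_JD] = JD;
    fx[F_Jlpl] = Jlpl; fx[F_spill] = spill; fx[F_ins_inf] = ins_inf;
    fx[F_TG] = TG; fx[F_S] = S;
  }
}

// overwrite y with the clamp-effective state (for recording)
static void effective_state(double t, double* y, const Inputs& in) {
  for (size_t k = 0; k < in.clamp_state.size(); ++k)
    y[in.clamp_state[k]] = in.clamp_sig[k].at(t);
}

// ---- Dormand-Prince RK45 ----------------------------------------------------
static const double DP_C[7] = {0., 1. / 5, 3. / 10, 4. / 5, 8. / 9, 1., 1.};
static const double DP_A[7][6] = {
  {0, 0, 0, 0, 0, 0},
  {1. / 5, 0, 0, 0, 0, 0},
  {3. / 40, 9. / 40, 0, 0, 0, 0},
  {44. / 45, -56. / 15, 32. / 9, 0, 0, 0},
  {19372. / 6561, -25360. / 2187, 64448. / 6561, -212. / 729, 0, 0},
  {9017. / 3168, -355. / 33, 46732. / 5247, 49. / 176, -5103. / 18656, 0},
  {35. / 384, 0, 500. / 1113, 125. / 192, -2187. / 6784, 11. / 84}
};
static const double DP_B5[7] =
  {35. / 384, 0, 500. / 1113, 125. / 192, -2187. / 6784, 11. / 84, 0};
static const double DP_B4[7] =
  {5179. / 57600, 0, 7571. / 16695, 393. / 640,
   -92097. / 339200, 187. / 2100, 1. / 40};

struct StateDumpError : public std::runtime_error {
  explicit StateDumpError(const std::string& m) : std::runtime_error(m) {}
};

static std::string dump_state(double t, const double* y) {
  std::ostringstream ss;
  ss << "non-finite derivative at t = " << t << "; state:";
  for (int i = 0; i < N_STATE; ++i)
    ss << " " << STATE_NAMES[i] << "=" << y[i];
  return ss.str();
}

// [[Rcpp::export]]
List cpp_simulate(NumericVector par, List inputs, NumericVector t_grid,
                  NumericVector y0, double rtol, double atol) {
  if (par.size() != N_PAR) stop("parameter vector has wrong length");
  if (y0.size() != N_STATE) stop("state vector has wrong length");
  Inputs in = parse_inputs(inputs);
  const double* p = REAL(par);
  const int nt = t_grid.size();

  // forced stop times: output grid plus input breakpoints
  std::vector<double> stops(t_grid.begin(), t_grid.end());
  const double t0 = stops.front(), tend = stops.back();
  if (in.has_inf)
    for (double tb : in.inf.t) if (tb > t0 && tb < tend) stops.push_back(tb);
  for (const Signal& s : in.clamp_sig)
    for (double tb : s.t) if (tb > t0 && tb < tend) stops.push_back(tb);
  std::sort(stops.begin(), stops.end());
  stops.erase(std::unique(stops.begin(), stops.end(),
                          [](double a, double b) { return std::abs(a - b) < 1e-12; }),
              stops.end());

  NumericMatrix states(nt, N_STATE), fluxes(nt, N_FLUX);
  double y[N_STATE], k[7][N_STATE], ytmp[N_STATE], ynew[N_STATE], fx[N_FLUX];
  std::copy(y0.begin(), y0.end(), y);

  int igrid = 0;
  auto record = [&](double t) {
    double yr[N_STATE];
    std::copy(y, y + N_STATE, yr);
    effective_state(t, yr, in);
    double dtmp[N_STATE];
    rhs(t, yr, p, in, dtmp, fx);
    for (int j = 0; j < N_STATE; ++j) states(igrid, j) = yr[j];
    for (int j = 0; j < N_FLUX; ++j) fluxes(igrid, j) = fx[j];
    ++igrid;
  };

  double t = t0;
  if (std::abs(t_grid[0] - t) < 1e-12) record(t);

  double h = 1.0;           // initial step, min
  size_t istop = 0;
  while (istop < stops.size() && stops[istop] <= t + 1e-12) ++istop;

  rhs(t, y, p, in, k[0], nullptr);   // FSAL seed
  for (int j = 0; j < N_STATE; ++j)
    if (!std::isfinite(k[0][j])) throw StateDumpError(dump_state(t, y));

  while (istop < stops.size()) {
    const double tstop = stops[istop];
    bool hit = false;
    if (t + h >= tstop - 1e-12) { h = tstop - t; hit = true; }
    if (h <= 0) { ++istop; continue; }

    // stages (k[0] carried over, FSAL)
    for (int s = 1; s < 7; ++s) {
      for (int j = 0; j < N_STATE; ++j) {
        double acc = 0.0;
        for (int q = 0; q < s; ++q) acc += DP_A[s][q] * k[q][j];
        ytmp[j] = y[j] + h * acc;
      }
      rhs(t + DP_C[s] * h, ytmp, p, in, k[s], nullptr);
    }
    double err = 0.0;
    for (int j = 0; j < N_STATE; ++j) {
      double acc5 = 0.0, acc4 = 0.0;
      for (int s = 0; s < 7; ++s) { acc5 += DP_B5[s] * k[s][j]; acc4 += DP_B4[s] * k[s][j]; }
      ynew[j] = y[j] + h * acc5;
      const double sc = atol + rtol * std::max(std::abs(y[j]), std::abs(ynew[j]));
      const double e = h * (acc5 - acc4) / sc;
      err += e * e;
    }
    err = std::sqrt(err / N_STATE);

    if (err <= 1.0) {      // accept
      t = hit ? tstop : t + h;
      std::copy(ynew, ynew + N_STATE, y);
      std::copy(k[6], k[6] + N_STATE, k[0]);   // FSAL
      for (int j = 0; j < N_STATE; ++j)
        if (!std::isfinite(y[j])) throw StateDumpError(dump_state(t, y));
      if (hit) {
        // re-evaluate at the stop (input may be discontinuous there)
        rhs(t, y, p, in, k[0], nullptr);
        if (igrid < nt && std::abs(t_grid[igrid] - t) < 1e-9) record(t);
        ++istop;
      }
    }
    double fac = err > 0.0 ? 0.9 * std::pow(err, -0.2) : 5.0;
    fac = std::min(5.0, std::max(0.2, fac));
    h = std::abs(h) * fac;
    if (h < 1e-10 * std::max(1.0, std::abs(t)))
      stop("integration failure: step size underflow at t = %f", t);
    if (h > 30.0) h = 30.0;
  }
  if (igrid != nt)
    stop("integration failure: reached t = %f with %d of %d outputs recorded",
         t, igrid, nt);

  colnames(states) = CharacterVector(STATE_NAMES, STATE_NAMES + N_STATE);
  colnames(fluxes) = CharacterVector(FLUX_NAMES, FLUX_NAMES + N_FLUX);
  return List::create(_["time"] = t_grid, _["states"] = states,
                      _["fluxes"] = fluxes);
}

// [[Rcpp::export]]
List cpp_rhs(double t, NumericVector y, NumericVector par, List inputs) {
  if (par.size() != N_PAR) stop("parameter vector has wrong length");
  if (y.size() != N_STATE) stop("state vector has wrong length");
  Inputs in = parse_inputs(inputs);
  double dy[N_STATE], fx[N_FLUX];
  double yy[N_STATE];
  std::copy(y.begin(), y.end(), yy);
  rhs(t, yy, REAL(par), in, dy, fx);
  NumericVector dyv(dy, dy + N_STATE), fxv(fx, fx + N_FLUX);
  dyv.names() = CharacterVector(STATE_NAMES, STATE_NAMES + N_STATE);
  fxv.names() = CharacterVector(FLUX_NAMES, FLUX_NAMES + N_FLUX);
  return List::create(_["dy"] = dyv, _["fluxes"] = fxv);
}

// [[Rcpp::export]]
CharacterVector cpp_param_names() {
  return CharacterVector(PAR_NAMES, PAR_NAMES + N_PAR);
}

// [[Rcpp::export]]
CharacterVector cpp_state_names() {
  return CharacterVector(STATE_NAMES, STATE_NAMES + N_STATE);
}
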