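// Fast path for the operator-split moving-mesh integrator.  Mirrors the R
// reference implementation (step_implicit_split) operation for operation;
// the R engine remains the readable specification and the two are
// cross-checked in the test suite.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int NF = 17;
enum Field { iTF, iV, iP, iuPR, iuPi, iuPa, iPA, iq, ip,
             iM, iE, ifib, iC, iw, iQ, iQr, irho };

struct Pars {
  double D[NF];
  double A_T, lambda_TC, lambda_VC, lambda_VT, lambda_VM, lambda_P,
      lambda_Pu, lambda_uPRM, lambda_uPRC, lambda_uf, lambda_u, lambda_PC,
      lambda_Pf, lambda_PM, lambda_qC, lambda_p, lambda_E, A_f, lambda_fC,
      beta, lambda_Cf, lambda_CuP, lambda_wC, lambda_w, lambda_QM,
      lambda_QP, lambda_QrM, lambda_rhof;
  double d_T, d_V, d_P, d_uPR, d_uPa, d_uPi, d_PA, d_q, d_p, d_M, d_E, d_f,
      d_C, d_wM, d_wC, d_wf, d_QQr, d_Q, d_QrQ, d_Qr, d_rho, d_rhoQ;
  double K_T, K_PA, K_uPR, K_p, K_E, K_C, K_f, K_P, K_V, M0, V0, C0, q0,
      w0, E0, rho0, chi_C, w_h, alpha_w_tilde, alpha_E_tilde;
};

static Pars unpack(const NumericVector& pv) {
  Pars p;
  CharacterVector nms = pv.names();
  std::map<std::string, double> m;
  for (int i = 0; i < pv.size(); ++i) m[as<std::string>(nms[i])] = pv[i];
  auto g = [&](const char* k) {
    auto it = m.find(k);
    if (it == m.end()) stop("missing parameter %s", k);
    return it->second;
  };
  p.D[iTF] = g("D_T");  p.D[iV] = g("D_V");   p.D[iP] = g("D_P");
  p.D[iuPR] = g("D_uPR"); p.D[iuPi] = g("D_uP"); p.D[iuPa] = g("D_uP");
  p.D[iPA] = g("D_PA"); p.D[iq] = g("D_q");   p.D[ip] = g("D_p");
  p.D[iM] = g("D_M");   p.D[iE] = g("D_E");   p.D[ifib] = g("D_f");
  p.D[iC] = g("D_C");   p.D[iw] = g("D_w");   p.D[iQ] = g("D_Q");
  p.D[iQr] = g("D_Qr"); p.D[irho] = 0.0;
  p.A_T = g("A_T"); p.lambda_TC = g("lambda_TC"); p.lambda_VC = g("lambda_VC");
  p.lambda_VT = g("lambda_VT"); p.lambda_VM = g("lambda_VM");
  p.lambda_P = g("lambda_P"); p.lambda_Pu = g("lambda_Pu");
  p.lambda_uPRM = g("lambda_uPRM"); p.lambda_uPRC = g("lambda_uPRC");
  p.lambda_uf = g("lambda_uf"); p.lambda_u = g("lambda_u");
  p.lambda_PC = g("lambda_PC"); p.lambda_Pf = g("lambda_Pf");
  p.lambda_PM = g("lambda_PM"); p.lambda_qC = g("lambda_qC");
  p.lambda_p = g("lambda_p"); p.lambda_E = g("lambda_E"); p.A_f = g("A_f");
  p.lambda_fC = g("lambda_fC"); p.beta = g("beta");
  p.lambda_Cf = g("lambda_Cf"); p.lambda_CuP = g("lambda_CuP");
  p.lambda_wC = g("lambda_wC"); p.lambda_w = g("lambda_w");
  p.lambda_QM = g("lambda_QM"); p.lambda_QP = g("lambda_QP");
  p.lambda_QrM = g("lambda_QrM"); p.lambda_rhof = g("lambda_rhof");
  p.d_T = g("d_T"); p.d_V = g("d_V"); p.d_P = g("d_P"); p.d_uPR = g("d_uPR");
  p.d_uPa = g("d_uPa"); p.d_uPi = g("d_uPi"); p.d_PA = g("d_PA");
  p.d_q = g("d_q"); p.d_p = g("d_p"); p.d_M = g("d_M"); p.d_E = g("d_E");
  p.d_f = g("d_f"); p.d_C = g("d_C"); p.d_wM = g("d_wM"); p.d_wC = g("d_wC");
  p.d_wf = g("d_wf"); p.d_QQr = g("d_QQr"); p.d_Q = g("d_Q");
  p.d_QrQ = g("d_QrQ"); p.d_Qr = g("d_Qr"); p.d_rho = g("d_rho");
  p.d_rhoQ = g("d_rhoQ");
  p.K_T = g("K_T"); p.K_PA = g("K_PA"); p.K_uPR = g("K_uPR");
  p.K_p = g("K_p"); p.K_E = g("K_E"); p.K_C = g("K_C"); p.K_f = g("K_f");
  p.K_P = g("K_P"); p.K_V = g("K_V"); p.M0 = g("M0"); p.V0 = g("V0");
  p.C0 = g("C0"); p.q0 = g("q0"); p.w0 = g("w0"); p.E0 = g("E0");
  p.rho0 = g("rho0"); p.chi_C = g("chi_C"); p.w_h = g("w_h");
  p.alpha_w_tilde = g("alpha_w_tilde"); p.alpha_E_tilde = g("alpha_E_tilde");
  return p;
}

typedef std::vector<double> vec;

struct Geom {              // finite-volume faces / volumes (per 4*pi)
  vec face, vol, dr;
  void update(const vec& r) {
    int n = (int)r.size();
    face.resize(n + 1); vol.resize(n); dr.resize(n - 1);
    face[0] = 0.0; face[n] = r[n - 1];
    for (int i = 0; i < n - 1; ++i) {
      face[i + 1] = 0.5 * (r[i] + r[i + 1]);
      dr[i] = r[i + 1] - r[i];
    }
    face[n] = r[n - 1];
    for (int i = 0; i < n; ++i)
      vol[i] = (std::pow(face[i + 1], 3) - std::pow(face[i], 3)) / 3.0;
  }
};

// Conservative Laplacian with zero outer flux.
static void fv_lap(const vec& x, const Geom& g, vec& out) {
  int n = (int)x.size();
  double fl_prev = 0.0;
  for (int i = 0; i < n; ++i) {
    double fl_next = 0.0;
    if (i < n - 1)
      fl_next = g.face[i + 1] * g.face[i + 1] * (x[i + 1] - x[i]) / g.dr[i];
    out[i] = (fl_next - fl_prev) / g.vol[i];
    fl_prev = fl_next;
  }
}

static void thomas(vec& lo, vec& di, vec& up, vec& d, vec& x) {
  int n = (int)d.size();
  for (int i = 1; i < n; ++i) {
    double mlt = lo[i] / di[i - 1];
    di[i] -= mlt * up[i - 1];
    d[i] -= mlt * d[i - 1];
  }
  x[n - 1] = d[n - 1] / di[n - 1];
  for (int i = n - 2; i >= 0; --i)
    x[i] = (d[i] - up[i] * x[i + 1]) / di[i];
}

// (I - tau*D*L) x = rhs with optional Robin outer flux (alpha >= 0;
// alpha < 0 means no-flux).
static void implicit_diff(const vec& rhs, const Geom& g, double D,
                          double tau, double alpha, double X0, vec& x,
                          vec& lo, vec& di, vec& up, vec& d) {
  int n = (int)rhs.size();
  if (D == 0.0) { x = rhs; return; }
  for (int i = 0; i < n; ++i) {
    double ap = (i < n - 1) ?
      g.face[i + 1] * g.face[i + 1] / g.dr[i] / g.vol[i] : 0.0;
    double am = (i > 0) ?
      g.face[i] * g.face[i] / g.dr[i - 1] / g.vol[i] : 0.0;
    di[i] = 1.0 + tau * D * (ap + am);
    up[i] = (i < n - 1) ? -tau * D * ap : 0.0;
    lo[i] = (i > 0) ? -tau * D * am : 0.0;
    d[i] = rhs[i];
  }
  if (alpha >= 0.0) {
    double b = g.face[n] * g.face[n] * alpha / g.vol[n - 1];
    di[n - 1] += tau * D * b;
    d[n - 1] += tau * D * b * X0;
  }
  thomas(lo, di, up, d, x);
}

static double hyp(double w, double plateau, double w_h) {
  double f = w / w_h;
  return plateau * (f < 1.0 ? f : 1.0);
}

static void reactions(const std::vector<vec>& X, const Pars& P,
                      bool normalize_EV, std::vector<vec>& F) {
  int n = (int)X[0].size();
  for (int i = 0; i < n; ++i) {
    double TF = X[iTF][i], V = X[iV][i], Pl = X[iP][i], uPR = X[iuPR][i],
        uPi = X[iuPi][i], uPa = X[iuPa][i], PA = X[iPA][i], q = X[iq][i],
        pp = X[ip][i], M = X[iM][i], E = X[iE][i], f = X[ifib][i],
        C = X[iC][i], w = X[iw][i], Q = X[iQ][i], Qr = X[iQr][i],
        rho = X[irho][i];
    double Vfac = V - P.V0; if (Vfac < 0) Vfac = 0;
    if (normalize_EV) Vfac /= P.K_V;
    double uPa_eff = uPa / (P.K_PA + PA);
    double uPR_eff = uPR / (P.K_uPR + uPR);
    F[iTF][i] = P.A_T + P.lambda_TC * C - P.d_T * TF;
    F[iV][i] = P.lambda_VC * C * (1 + P.lambda_VT * TF / (P.K_T + TF)) +
        P.lambda_VM * M - P.d_V * V;
    F[iP][i] = P.lambda_P * (1 + P.lambda_Pu * uPa_eff) - P.d_P * Pl;
    F[iuPR][i] = P.lambda_uPRM * M + P.lambda_uPRC * C - P.d_uPR * uPR;
    F[iuPi][i] = P.lambda_uf * f - P.d_uPi * uPi;
    F[iuPa][i] = P.lambda_u * uPi * uPR_eff - P.d_uPa * uPa;
    F[iPA][i] = P.lambda_PC * C + P.lambda_Pf * f + P.lambda_PM * M -
        P.d_PA * PA;
    F[iq][i] = P.lambda_qC * C - P.d_q * q;
    F[ip][i] = hyp(w, P.lambda_p, P.w_h) * q / (P.q0 + q) * M - P.d_p * pp;
    F[iM][i] = P.beta * pp / (P.K_p + pp) * P.M0 - P.d_M * M;
    F[iE][i] = P.lambda_E * E * (1 - E / P.K_E) * Vfac - P.d_E * E;
    F[ifib][i] = P.A_f + P.lambda_fC * f * C / (P.K_C + C) - P.d_f * f;
    F[iC][i] = (hyp(w, P.lambda_wC, P.w_h) +
                P.lambda_Cf * f / (P.K_f + f) +
                P.lambda_CuP * uPa_eff * uPR_eff) * C * (1 - C / P.C0) -
        P.d_C * C;
    F[iw][i] = P.lambda_w * E - (P.d_wM * M + P.d_wC * C + P.d_wf * f) * w;
    F[iQ][i] = P.lambda_QM * M * (1 + P.lambda_QP * Pl / (P.K_P + Pl)) -
        P.d_QQr * Qr * Q - P.d_Q * Q;
    F[iQr][i] = P.lambda_QrM * M - P.d_QrQ * Q * Qr - P.d_Qr * Qr;
    double cap = 1 - rho / P.rho0; if (cap < 0) cap = 0;
    F[irho][i] = P.lambda_rhof * f * cap - P.d_rho * rho -
        P.d_rhoQ * Q * rho;
  }
}

// Printed nonuniform first-derivative stencil (interior); symmetric zero at
// the origin, one-sided at the boundary.
static void gradient(const vec& x, const vec& r, vec& g) {
  int n = (int)x.size();
  g[0] = 0.0;
  for (int i = 1; i < n - 1; ++i) {
    double hm = r[i - 1] - r[i], hp = r[i + 1] - r[i];
    g[i] = (hm * hm * x[i + 1] - hp * hp * x[i - 1] +
            (hp * hp - hm * hm) * x[i]) / (hp * (hm * hm - hp * hm));
  }
  g[n - 1] = (x[n - 1] - x[n - 2]) / (r[n - 1] - r[n - 2]);
}

static void lin_interp(const vec& xg, const vec& yg, const vec& xo, vec& yo) {
  int n = (int)xg.size(), m = (int)xo.size();
  int j = 0;
  for (int i = 0; i < m; ++i) {
    double x = xo[i];
    if (x <= xg[0]) { yo[i] = yg[0]; continue; }
    if (x >= xg[n - 1]) { yo[i] = yg[n - 1]; continue; }
    while (xg[j + 1] < x) ++j;
    double t = (x - xg[j]) / (xg[j + 1] - xg[j]);
    yo[i] = (1 - t) * yg[j] + t * yg[j + 1];
  }
}

static double trapz_r2(const vec& x, const vec& r) {
  double s = 0.0;
  for (size_t i = 1; i < r.size(); ++i)
    s += 0.5 * (x[i] * r[i] * r[i] + x[i - 1] * r[i - 1] * r[i - 1]) *
        (r[i] - r[i - 1]);
  return s;
}

// [[Rcpp::export]]
List pas_simulate_cpp(NumericMatrix init, NumericVector r0,
                      NumericVector params, double tau, int nsteps,
                      int stride, int regrid_every, double theta,
                      bool transport, bool do_reactions, bool normalize_EV,
                      bool clamp,
                      double blowup_limit, double R_min,
                      bool keep_snapshots) {
  Pars P = unpack(params);
  int n = init.nrow();
  if (init.ncol() != NF) stop("state matrix must have %d columns", NF);
  std::vector<vec> X(NF, vec(n)), F(NF, vec(n)), pred(NF, vec(n));
  for (int j = 0; j < NF; ++j)
    for (int i = 0; i < n; ++i) X[j][i] = init(i, j);
  vec r(r0.begin(), r0.end());
  Geom g; g.update(r);
  vec lap(n), S(n), u(n), divv(n), grad(n), tmp(n);
  vec lo(n), di(n), up(n), d(n);
  std::vector<double> times, Rs;
  std::vector<vec> massrec, averec;
  List snaps, meshes;
  long clamped = 0; bool aborted = false, eliminated = false;

  auto record = [&](double t) {
    times.push_back(t);
    Rs.push_back(r[n - 1]);
    vec m(NF), a(NF);
    double R3 = std::pow(r[n - 1], 3);
    for (int j = 0; j < NF; ++j) {
      double I = trapz_r2(X[j], r);
      m[j] = 4.0 * M_PI * I;
      a[j] = I / R3;
    }
    massrec.push_back(m); averec.push_back(a);
    if (keep_snapshots) {
      NumericMatrix snap(n, NF);
      for (int j = 0; j < NF; ++j)
        for (int i = 0; i < n; ++i) snap(i, j) = X[j][i];
      snaps.push_back(snap);
      meshes.push_back(NumericVector(r.begin(), r.end()));
    }
  };
  auto bad = [&]() {
    if (!std::isfinite(r[n - 1]) || r[n - 1] <= 0) return true;
    for (int j = 0; j < NF; ++j)
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(X[j][i]) || std::fabs(X[j][i]) > blowup_limit)
          return true;
    return false;
  };

  record(0.0);
  for (int k = 1; k <= nsteps; ++k) {
    if (eliminated) {                 // tumor eliminated: state frozen
      if (k % stride == 0 || k == nsteps) record(k * tau);
      continue;
    }
    if (do_reactions) reactions(X, P, normalize_EV, F);
    else for (int j = 0; j < NF; ++j) std::fill(F[j].begin(), F[j].end(), 0.0);
    bool moving = false;
    if (transport && do_reactions) {
      fv_lap(X[ip], g, lap);
      for (int i = 0; i < n; ++i) F[iM][i] -= P.chi_C * lap[i];
      fv_lap(X[iV], g, lap);
      for (int i = 0; i < n; ++i) F[iE][i] -= P.chi_C * lap[i];
      fv_lap(X[irho], g, lap);
      for (int i = 0; i < n; ++i)
        S[i] = (F[iM][i] + F[iE][i] + F[ifib][i] + F[iC][i] + F[irho][i] -
                P.D[iM] * lap[i]) / theta;
      // u = (1/r^2) int_0^r s^2 S ds, shell-weighted trapezoid
      u[0] = 0.0;
      double cum = 0.0;
      for (int i = 1; i < n; ++i) {
        cum += 0.5 * (S[i] + S[i - 1]) *
            (std::pow(r[i], 3) - std::pow(r[i - 1], 3)) / 3.0;
        u[i] = cum / (r[i] * r[i]);
        if (u[i] != 0.0) moving = true;
      }
    }
    if (moving) {
      gradient(u, r, grad);
      divv[0] = 3.0 * u[1] / r[1];
      for (int i = 1; i < n - 1; ++i) divv[i] = grad[i] + 2.0 * u[i] / r[i];
      divv[n - 1] = grad[n - 1] + 2.0 * u[n - 1] / r[n - 1];
    }
    for (int j = 0; j < NF; ++j) {
      bool adv = (j == iM || j == iE || j == ifib || j == iC || j == irho);
      if (!moving) {
        for (int i = 0; i < n; ++i) pred[j][i] = X[j][i] + tau * F[j][i];
      } else if (adv) {
        for (int i = 0; i < n; ++i)
          pred[j][i] = X[j][i] + tau * (F[j][i] - divv[i] * X[j][i]);
      } else {
        gradient(X[j], r, tmp);
        for (int i = 0; i < n; ++i)
          pred[j][i] = X[j][i] + tau * (F[j][i] + u[i] * tmp[i]);
      }
    }
    if (moving) {
      for (int i = 0; i < n; ++i) r[i] += tau * u[i];
      g.update(r);
      if (r[n - 1] < R_min) eliminated = true;
    }
    if (transport) {
      for (int j = 0; j < NF; ++j) {
        if (P.D[j] == 0.0) { X[j] = pred[j]; continue; }
        double alpha = -1.0, X0 = 0.0;
        if (j == iw && pred[iw][n - 1] > P.w0) {
          double Eb = pred[iE][n - 1];
          alpha = P.alpha_w_tilde * Eb / (P.K_E + Eb); X0 = P.w0;
        } else if (j == iE && pred[iE][n - 1] > P.E0) {
          double Vb = pred[iV][n - 1];
          alpha = P.alpha_E_tilde * Vb / (P.K_V + Vb); X0 = P.E0;
        }
        implicit_diff(pred[j], g, P.D[j], tau, alpha, X0, X[j],
                      lo, di, up, d);
      }
    } else {
      for (int j = 0; j < NF; ++j) X[j] = pred[j];
    }
    if (clamp) {
      for (int j = 0; j < NF; ++j)
        for (int i = 0; i < n; ++i)
          if (X[j][i] < 0) { X[j][i] = 0.0; ++clamped; }
    }
    if (!eliminated && transport && regrid_every > 0 &&
        k % regrid_every == 0) {
      vec rn(n);
      double R = r[n - 1];
      for (int i = 0; i < n; ++i) rn[i] = R * i / (double)(n - 1);
      for (int j = 0; j < NF; ++j) {
        lin_interp(r, X[j], rn, tmp);
        X[j] = tmp;
      }
      r = rn; g.update(r);
    }
    if (k % stride == 0 || k == nsteps) {
      if (bad()) { aborted = true; record(k * tau); break; }
      record(k * tau);
    }
  }

  int nt = (int)times.size();
  NumericMatrix mass(nt, NF), ave(nt, NF);
  for (int t = 0; t < nt; ++t)
    for (int j = 0; j < NF; ++j) {
      mass(t, j) = massrec[t][j];
      ave(t, j) = averec[t][j];
    }
  return List::create(
      _["times"] = NumericVector(times.begin(), times.end()),
      _["R"] = NumericVector(Rs.begin(), Rs.end()),
      _["mass"] = mass, _["ave"] = ave,
      _["snapshots"] = snaps, _["mesh"] = meshes,
      _["clamped"] = (double)clamped, _["aborted"] = aborted,
      _["eliminated"] = eliminated);
}
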