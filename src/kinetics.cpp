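// Compiled kinetic core: rate-law templates, ODE right-hand side, and a
// stiff Rosenbrock(2,3) integrator of the ode23s family (Shampine-Reichelt).
// The R side compiles a NetworkModel + ParameterSet into index vectors; all
// hot loops run here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

enum Form { GENERIC = 1, FAC_TRANS = 2, MASS_ACTION = 3 };

struct Reaction {
  int form;
  int rev;          // has reverse term
  int constrained;  // Vr replaced by Vf/Keq
  arma::ivec sub_idx, prod_idx;   // 0-based into full concentration vector
  arma::vec  sub_st, prod_st;     // absolute stoichiometries in the rate law
  arma::ivec sub_km, prod_km;     // 0-based param indices, -1 = absent
  int vf, vr, keq;                // param indices, -1 = absent
  int hill;                       // param idx of Hill exponent on substrate 1
  int kia, kib, kiq;              // dead-end complex constants
  int act_idx, act_ka;            // activating modifier (species, Ka)
  int inh_idx, inh_ki;            // non-competitive inhibitor (species, Ki)
};

struct Model {
  int n_dyn, n_full, nr;
  arma::mat M;                    // n_dyn x nr volume-scaled stoichiometry
  std::vector<Reaction> rx;
};

int geti(const List& L, const char* nm) { return as<int>(L[nm]); }

arma::ivec idxvec(const List& L, const char* nm) {
  IntegerVector v = L[nm];
  arma::ivec out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i] - 1;  // to 0-based, -1 = absent
  return out;
}

Model parse_model(const List& compiled) {
  Model m;
  m.n_dyn  = geti(compiled, "n_dyn");
  m.n_full = geti(compiled, "n_full");
  m.M      = as<arma::mat>(compiled["M"]);
  List rl  = compiled["reactions"];
  m.nr = rl.size();
  m.rx.resize(m.nr);
  for (int j = 0; j < m.nr; ++j) {
    List r = rl[j];
    Reaction& q = m.rx[j];
    q.form = geti(r, "form");
    q.rev = geti(r, "rev");
    q.constrained = geti(r, "constrained");
    q.sub_idx = idxvec(r, "sub_idx");  q.prod_idx = idxvec(r, "prod_idx");
    q.sub_st  = as<arma::vec>(r["sub_st"]);
    q.prod_st = as<arma::vec>(r["prod_st"]);
    q.sub_km  = idxvec(r, "sub_km");   q.prod_km = idxvec(r, "prod_km");
    q.vf  = geti(r, "vf") - 1;  q.vr = geti(r, "vr") - 1;
    q.keq = geti(r, "keq") - 1; q.hill = geti(r, "hill") - 1;
    q.kia = geti(r, "kia") - 1; q.kib = geti(r, "kib") - 1; q.kiq = geti(r, "kiq") - 1;
    q.act_idx = geti(r, "act_idx") - 1; q.act_ka = geti(r, "act_ka") - 1;
    q.inh_idx = geti(r, "inh_idx") - 1; q.inh_ki = geti(r, "inh_ki") - 1;
  }
  return m;
}

// saturation denominator factor for a species with reduced concentration a
// and integer stoichiometry s (1 + a + ... + a^s); Hill exponents use 1 + a^h
double sat_factor(double a, double st, bool hillp, double h) {
  if (hillp) return 1.0 + std::pow(a, h);
  int s = (int) std::lround(st);
  double f = 1.0, ak = 1.0;
  for (int k = 1; k <= s; ++k) { ak *= a; f += ak; }
  return f;
}

double rate_one(const Reaction& q, const arma::vec& C, const arma::vec& p) {
  const int ns = q.sub_idx.n_elem, np = q.prod_idx.n_elem;
  double v = 0.0;
  if (q.form == MASS_ACTION) {
    double vf = p[q.vf], fwd = vf;
    for (int i = 0; i < ns; ++i) fwd *= std::pow(C[q.sub_idx[i]], q.sub_st[i]);
    double bwd = 0.0;
    if (q.rev && q.vr >= 0) {
      bwd = p[q.vr];
      for (int i = 0; i < np; ++i) bwd *= std::pow(C[q.prod_idx[i]], q.prod_st[i]);
    }
    v = fwd - bwd;
  } else if (q.form == FAC_TRANS) {
    double km = p[q.sub_km[0]];
    double s = C[q.sub_idx[0]], pr = C[q.prod_idx[0]];
    v = p[q.vf] * (s / (km + s) - pr / (km + pr));
  } else {  // GENERIC reversible/irreversible Michaelis-Menten family
    double numf = p[q.vf], Ds = 1.0;
    for (int i = 0; i < ns; ++i) {
      double a = C[q.sub_idx[i]] / p[q.sub_km[i]];
      bool hillp = (i == 0 && q.hill >= 0);
      double h = hillp ? p[q.hill] : q.sub_st[i];
      numf *= std::pow(a, h);
      Ds *= sat_factor(a, q.sub_st[i], hillp, h);
    }
    double numr = 0.0, Dp = 1.0;
    if (q.rev) numr = q.constrained ? p[q.vf] / p[q.keq] : p[q.vr];
    for (int i = 0; i < np; ++i) {
      if (q.prod_km[i] < 0) continue;  // product absent from the rate law
      double b = C[q.prod_idx[i]] / p[q.prod_km[i]];
      if (q.rev) numr *= std::pow(b, q.prod_st[i]);
      Dp *= sat_factor(b, q.prod_st[i], false, 0.0);
    }
    double D = Ds + Dp - 1.0;
    if (q.kia >= 0 && q.kiq >= 0)
      D += (C[q.sub_idx[0]] / p[q.kia]) * (C[q.prod_idx[np - 1]] / p[q.kiq]);
    if (q.kib >= 0 && ns > 1) D += C[q.sub_idx[1]] / p[q.kib];
    v = (numf - numr) / D;
  }
  if (q.act_idx >= 0) {
    double mC = C[q.act_idx];
    v *= mC / (p[q.act_ka] + mC);
  }
  if (q.inh_idx >= 0) v /= (1.0 + C[q.inh_idx] / p[q.inh_ki]);
  return v;
}

arma::vec all_rates(const Model& m, const arma::vec& Cfull, const arma::vec& p) {
  arma::vec Cc = Cfull;
  for (arma::uword i = 0; i < Cc.n_elem; ++i) if (Cc[i] < 0) Cc[i] = 0.0;
  arma::vec v(m.nr);
  for (int j = 0; j < m.nr; ++j) v[j] = rate_one(m.rx[j], Cc, p);
  return v;
}

// dy/dt for the dynamic species; bvals are the clamped boundary concentrations
arma::vec rhs(const Model& m, const arma::vec& y, const arma::vec& bvals,
              const arma::vec& p) {
  arma::vec Cfull(m.n_full);
  Cfull.head(m.n_dyn) = y;
  if (m.n_full > m.n_dyn) Cfull.tail(m.n_full - m.n_dyn) = bvals;
  return m.M * all_rates(m, Cfull, p);
}

}  // namespace

// [[Rcpp::export]]
arma::vec cpp_rates(List compiled, arma::vec Cfull, arma::vec pars) {
  Model m = parse_model(compiled);
  return all_rates(m, Cfull, pars);
}

// [[Rcpp::export]]
arma::vec cpp_rhs(List compiled, arma::vec y, arma::vec bvals, arma::vec pars) {
  Model m = parse_model(compiled);
  return rhs(m, y, bvals, pars);
}

// Adaptive Rosenbrock(2,3): L-stable, Jacobian refreshed every step by finite
// differences. Output exactly on `times` (integration steps land on grid
// points). Returns concentrations and instantaneous fluxes on the grid.
// [[Rcpp::export]]
List cpp_simulate(List compiled, arma::vec pars, arma::vec y0, arma::vec bvals,
                  arma::vec times, double rtol, double atol, double hmax) {
  Model m = parse_model(compiled);
  const int n = m.n_dyn, nt = times.n_elem;
  const double d = 1.0 / (2.0 + std::sqrt(2.0));
  const double e32 = 6.0 + std::sqrt(2.0);
  const double hmin = 1e-12;
  const long max_steps = 20000000L;

  arma::mat conc(nt, n), flux(nt, m.nr);
  arma::vec y = y0;
  double t = times[0];
  int nclamp = 0, status = 0;
  long steps = 0;

  auto record = [&](int k) {
    conc.row(k) = y.t();
    arma::vec Cfull(m.n_full);
    Cfull.head(n) = y;
    if (m.n_full > n) Cfull.tail(m.n_full - n) = bvals;
    flux.row(k) = all_rates(m, Cfull, pars).t();
  };
  record(0);

  double h = std::min(hmax, times[nt - 1] > t ? (times[nt - 1] - t) * 1e-4 : 1e-4);
  if (h <= 0) h = 1e-6;
  int k = 1;
  arma::mat I = arma::eye(n, n);

  while (k < nt) {
    double t_target = times[k];
    if (t >= t_target) { record(k); ++k; continue; }
    if (++steps > max_steps) { status = 2; break; }
    if (h > t_target - t) h = t_target - t;
    if (h < hmin) { status = 1; break; }

    arma::vec f0 = rhs(m, y, bvals, pars);
    if (!f0.is_finite()) { status = 3; break; }

    // finite-difference Jacobian at y
    arma::mat J(n, n);
    const double sq = std::sqrt(std::numeric_limits<double>::epsilon());
    for (int j = 0; j < n; ++j) {
      double dy = sq * std::max(std::abs(y[j]), 1e-5);
      arma::vec yp = y; yp[j] += dy;
      J.col(j) = (rhs(m, yp, bvals, pars) - f0) / dy;
    }

    bool accepted = false;
    while (!accepted) {
      if (h < hmin) { status = 1; break; }
      arma::mat W = I - (h * d) * J;
      arma::vec k1, k2, k3;
      bool ok = arma::solve(k1, W, f0, arma::solve_opts::fast);
      if (!ok || !k1.is_finite()) { h *= 0.25; continue; }
      arma::vec f1 = rhs(m, y + 0.5 * h * k1, bvals, pars);
      if (!f1.is_finite()) { h *= 0.25; continue; }
      arma::solve(k2, W, f1 - k1, arma::solve_opts::fast);
      k2 += k1;
      arma::vec ynew = y + h * k2;
      arma::vec f2 = rhs(m, ynew, bvals, pars);
      if (!f2.is_finite() || !ynew.is_finite()) { h *= 0.25; continue; }
      arma::solve(k3, W, f2 - e32 * (k2 - f1) - 2.0 * (k1 - f0),
                  arma::solve_opts::fast);
      arma::vec err = (h / 6.0) * (k1 - 2.0 * k2 + k3);
      double est = 0.0;
      for (int i = 0; i < n; ++i) {
        double sc = atol + rtol * std::max(std::abs(y[i]), std::abs(ynew[i]));
        est = std::max(est, std::abs(err[i]) / sc);
      }
      if (est <= 1.0) {
        // negativity policy: tiny excursions clamped, larger ones retried
        bool bad = false;
        for (int i = 0; i < n; ++i) {
          if (ynew[i] < -1e-9) { bad = true; break; }
          if (ynew[i] < 0) { ynew[i] = 0.0; ++nclamp; }
        }
        if (bad) { h *= 0.25; continue; }
        t += h; y = ynew;
        accepted = true;
        double fac = 0.8 * std::pow(std::max(est, 1e-10), -1.0 / 3.0);
        h = std::min(hmax, h * std::min(5.0, std::max(0.2, fac)));
      } else {
        double fac = 0.8 * std::pow(est, -1.0 / 3.0);
        h *= std::min(0.9, std::max(0.1, fac));
      }
    }
    if (status != 0) break;
    if (t >= t_target - 1e-12) { record(k); ++k; }
  }

  return List::create(_["times"] = times, _["conc"] = conc, _["flux"] = flux,
                      _["nclamp"] = nclamp, _["status"] = status,
                      _["t_last"] = t);
}
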