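// Ecosystem right-hand side and adaptive Dormand-Prince 5(4) integrator.
//
// State layout (length 5 + n_pools + n_grazers + 3):
//   y[0..4]  dissolved NH4, NO2, NO3 (uM N), PO4 (uM P), Fe (nM)
//   y[5..]   phytoplankton pools (uM P), order given by pool_type/pool_class
//   then     grazer pools (uM P)
//   then     detritus det_P (uM P), det_N (uM N), det_Fe (nM)
//
// Units: days, uM N/P, nM Fe, W m-2, m.  Phosphorus is the model currency;
// biomass N is Redfield (R_NP) and biomass Fe is R_FeP per unit P.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double YEAR_DAYS = 365.0;
static const double TWO_PI = 6.283185307179586476925286766559;

// ---- elementary rate laws (kept identical to the exported R ops) ---------

static inline double gauss_temp(double sst, double topt, double twidth) {
  double z = (sst - topt) / twidth;
  return std::exp(-z * z);
}

// peak value of (1 - exp(-I/Iopt)) * exp(-kinh*I), used to normalise to 1
static inline double light_peak(double iopt, double kinh) {
  if (kinh <= 0.0) return 1.0;
  double istar = iopt * std::log(1.0 + 1.0 / (kinh * iopt));
  return (1.0 - std::exp(-istar / iopt)) * std::exp(-kinh * istar);
}

static inline double light_resp(double I, double iopt, double kinh,
                                double peak) {
  if (I <= 0.0) return 0.0;
  return (1.0 - std::exp(-I / iopt)) * std::exp(-kinh * I) / peak;
}

static inline double monod(double s, double k) {
  return (s <= 0.0) ? 0.0 : s / (k + s);
}

static inline double pos(double x) { return x > 0.0 ? x : 0.0; }

// ---- model container -----------------------------------------------------

struct Model {
  int n_types, n_pools, n_graz, n_state;
  // per-type traits
  std::vector<double> mu_max, T_opt, T_width, I_opt, k_inhib,
      K_NH4, K_NO2, K_NO3, K_PO4, K_Fe, psi, R_FeP, mort, pal, lpeak;
  std::vector<int> small, can_NO3, can_NO2;
  // pools
  std::vector<int> pool_type, pool_class;   // 0-based type; class 0..3
  std::vector<int> mut_index;               // n_types*3, pool index or -1
  // grazers: prey_small flag + params
  std::vector<int> g_small;
  std::vector<double> g_max, g_K, g_assim, g_mort, g_exp;
  // biogeochemistry
  double k_n1, k_n2, remin, exportr, R_NP;
  // mutation
  double lambda, onset;
  int mut_enabled;
  // forcing
  double mld_mean, mld_amp, mld_phase, sst_mean, sst_amp, sst_phase,
      par_mean, par_amp, par_phase, atten_k, bg_exch, nutricline_depth,
      nutricline_width;
  double deep[5];
  int fixed_nutrients;
};

static Model parse_model(const List& pars) {
  Model m;
  NumericMatrix tr = pars["traits"];
  m.n_types = tr.nrow();
  // column order fixed by the R side (see .traits_matrix)
  for (int k = 0; k < m.n_types; ++k) {
    m.mu_max.push_back(tr(k, 0));
    m.T_opt.push_back(tr(k, 1));
    m.T_width.push_back(tr(k, 2));
    m.I_opt.push_back(tr(k, 3));
    m.k_inhib.push_back(tr(k, 4));
    m.K_NH4.push_back(tr(k, 5));
    m.K_NO2.push_back(tr(k, 6));
    m.K_NO3.push_back(tr(k, 7));
    m.K_PO4.push_back(tr(k, 8));
    m.K_Fe.push_back(tr(k, 9));
    m.psi.push_back(tr(k, 10));
    m.R_FeP.push_back(tr(k, 11));
    m.mort.push_back(tr(k, 12));
    m.pal.push_back(tr(k, 13));
    m.small.push_back((int)tr(k, 14));
    m.can_NO3.push_back((int)tr(k, 15));
    m.can_NO2.push_back((int)tr(k, 16));
    m.lpeak.push_back(light_peak(tr(k, 3), tr(k, 4)));
  }
  IntegerVector pt = pars["pool_type"], pc = pars["pool_class"];
  m.n_pools = pt.size();
  for (int i = 0; i < m.n_pools; ++i) {
    m.pool_type.push_back(pt[i]);
    m.pool_class.push_back(pc[i]);
  }
  IntegerMatrix mi = pars["mut_index"];
  for (int k = 0; k < m.n_types; ++k)
    for (int j = 0; j < 3; ++j) m.mut_index.push_back(mi(k, j));
  NumericMatrix gz = pars["grazers"];
  m.n_graz = gz.nrow();
  for (int g = 0; g < m.n_graz; ++g) {
    m.g_small.push_back((int)gz(g, 0));
    m.g_max.push_back(gz(g, 1));
    m.g_K.push_back(gz(g, 2));
    m.g_assim.push_back(gz(g, 3));
    m.g_mort.push_back(gz(g, 4));
    m.g_exp.push_back(gz.ncol() > 5 ? gz(g, 5) : 1.0);
  }
  NumericVector bg = pars["biogeo"];
  m.k_n1 = bg[0]; m.k_n2 = bg[1]; m.remin = bg[2]; m.exportr = bg[3];
  m.R_NP = bg[4];
  NumericVector mu = pars["mutation"];
  m.lambda = mu[0]; m.onset = mu[1]; m.mut_enabled = (int)mu[2];
  NumericVector fo = pars["forcing"];
  m.mld_mean = fo[0]; m.mld_amp = fo[1]; m.mld_phase = fo[2];
  m.sst_mean = fo[3]; m.sst_amp = fo[4]; m.sst_phase = fo[5];
  m.par_mean = fo[6]; m.par_amp = fo[7]; m.par_phase = fo[8];
  m.atten_k = fo[9]; m.bg_exch = fo[10];
  m.nutricline_depth = fo.size() > 11 ? fo[11] : 0.0;
  m.nutricline_width = fo.size() > 12 ? fo[12] : 25.0;
  NumericVector dp = pars["deep"];
  for (int j = 0; j < 5; ++j) m.deep[j] = dp[j];
  NumericVector fl = pars["flags"];
  m.fixed_nutrients = (int)fl[0];
  m.n_state = 5 + m.n_pools + m.n_graz + 3;
  return m;
}

// ---- right-hand side -----------------------------------------------------

static void deriv(const Model& m, double t, const double* y, double* dy) {
  const int NP = m.n_pools, NG = m.n_graz;
  const int iP0 = 5, iZ0 = 5 + NP, iDP = 5 + NP + NG, iDN = iDP + 1,
            iDF = iDP + 2;

  // forcing
  double am = TWO_PI * (t - m.mld_phase) / YEAR_DAYS;
  double h = m.mld_mean + m.mld_amp * std::cos(am);
  double dhdt = -m.mld_amp * std::sin(am) * TWO_PI / YEAR_DAYS;
  double sst = m.sst_mean +
               m.sst_amp * std::cos(TWO_PI * (t - m.sst_phase) / YEAR_DAYS);
  double i0 = m.par_mean +
              m.par_amp * std::cos(TWO_PI * (t - m.par_phase) / YEAR_DAYS);
  if (i0 < 0.0) i0 = 0.0;
  double kh = m.atten_k * h;
  double ibar = (kh > 1e-12) ? i0 * (1.0 - std::exp(-kh)) / kh : i0;
  double exch = pos(dhdt) / h + m.bg_exch;   // entrainment + background

  double NH4 = pos(y[0]), NO2 = pos(y[1]), NO3 = pos(y[2]),
         PO4 = pos(y[3]), Fe = pos(y[4]);

  for (int s = 0; s < m.n_state; ++s) dy[s] = 0.0;

  // mixed-layer exchange: nutrients relax toward sub-layer values,
  // particulate pools (assumed zero below the layer) are diluted. The
  // nitracline/nutricline profile scales the sub-layer NO2/NO3/PO4 seen at
  // the current layer depth: shallow entrainment taps nutrient-poor water,
  // deep winter mixing reaches the full reservoir.
  double ncl = 1.0;
  if (m.nutricline_depth > 0.0)
    ncl = 1.0 / (1.0 + std::exp(-(h - m.nutricline_depth) /
                                m.nutricline_width));
  dy[0] += exch * (m.deep[0] - NH4);
  dy[1] += exch * (ncl * m.deep[1] - NO2);
  dy[2] += exch * (ncl * m.deep[2] - NO3);
  dy[3] += exch * (ncl * m.deep[3] - PO4);
  dy[4] += exch * (m.deep[4] - Fe);

  // nitrification NH4 -> NO2 -> NO3 (first order)
  double f1 = m.k_n1 * NH4, f2 = m.k_n2 * NO2;
  dy[0] -= f1; dy[1] += f1 - f2; dy[2] += f2;

  // detritus: remineralization (N returns as NH4), export, dilution
  double dP = pos(y[iDP]), dN = pos(y[iDN]), dF = pos(y[iDF]);
  dy[3] += m.remin * dP; dy[0] += m.remin * dN; dy[4] += m.remin * dF;
  dy[iDP] -= (m.remin + m.exportr) * dP + exch * dP;
  dy[iDN] -= (m.remin + m.exportr) * dN + exch * dN;
  dy[iDF] -= (m.remin + m.exportr) * dF + exch * dF;

  // phytoplankton pools
  bool mut_on = m.mut_enabled && t >= m.onset && m.lambda > 0.0;
  for (int i = 0; i < NP; ++i) {
    int k = m.pool_type[i], cls = m.pool_class[i];
    double B = pos(y[iP0 + i]);
    double gT = gauss_temp(sst, m.T_opt[k], m.T_width[k]);
    double gI = light_resp(ibar, m.I_opt[k], m.k_inhib[k], m.lpeak[k]);
    int cNO3 = (cls <= 1) ? m.can_NO3[k] : 0;
    int cNO2 = (cls <= 2) ? m.can_NO2[k] : 0;
    double inh = std::exp(-m.psi[k] * NH4);
    double uNH4 = monod(NH4, m.K_NH4[k]);
    double uNO2 = cNO2 ? monod(NO2, m.K_NO2[k]) * inh : 0.0;
    double uNO3 = cNO3 ? monod(NO3, m.K_NO3[k]) * inh : 0.0;
    double usum = uNH4 + uNO2 + uNO3;
    double gN = usum < 1.0 ? usum : 1.0;
    double gnut = gN;
    double mP = monod(PO4, m.K_PO4[k]); if (mP < gnut) gnut = mP;
    double mF = monod(Fe, m.K_Fe[k]);  if (mF < gnut) gnut = mF;
    double mu = m.mu_max[k] * gT * gI * gnut;
    double gross = mu * B;            // uM P / day
    // nutrient drawdown in Redfield proportions, split by source fractions
    if (usum > 0.0 && gross > 0.0) {
      double nup = m.R_NP * gross / usum;
      dy[0] -= nup * uNH4; dy[1] -= nup * uNO2; dy[2] -= nup * uNO3;
    }
    dy[3] -= gross;
    dy[4] -= m.R_FeP[k] * gross;
    double mrt = m.mort[k] * B;
    dy[iP0 + i] += gross - mrt - exch * B;
    dy[iDP] += mrt;
    dy[iDN] += m.R_NP * mrt;
    dy[iDF] += m.R_FeP[k] * mrt;
    // mutation: parents of small types spawn the three mutant classes at
    // rate lambda per division; debit conserves mass
    if (mut_on && cls == 0 && m.small[k]) {
      int j0 = 3 * k;
      if (m.mut_index[j0] >= 0) {
        double mf = m.lambda * gross;
        dy[iP0 + i] -= 3.0 * mf;
        dy[iP0 + m.mut_index[j0]]     += mf;
        dy[iP0 + m.mut_index[j0 + 1]] += mf;
        dy[iP0 + m.mut_index[j0 + 2]] += mf;
      }
    }
  }

  // grazing: one Holling-II grazer per size class on palatability-weighted
  // total prey; mutants share the parent's palatability and size class
  for (int g = 0; g < NG; ++g) {
    double btot = 0.0;
    for (int i = 0; i < NP; ++i) {
      int k = m.pool_type[i];
      if (m.small[k] == m.g_small[g]) btot += m.pal[k] * pos(y[iP0 + i]);
    }
    double Z = pos(y[iZ0 + g]);
    double zm = m.g_mort[g] * Z;
    double ing = 0.0;
    if (btot > 0.0) {
      // saturation exponent 1 = Holling II, 2 = Holling III (prey refuge)
      double bn = std::pow(btot, m.g_exp[g]), kn = std::pow(m.g_K[g],
                                                            m.g_exp[g]);
      ing = m.g_max[g] * bn / (kn + bn) * Z;
      for (int i = 0; i < NP; ++i) {
        int k = m.pool_type[i];
        if (m.small[k] != m.g_small[g]) continue;
        double loss = ing * m.pal[k] * pos(y[iP0 + i]) / btot;
        dy[iP0 + i] -= loss;
        dy[iDF] += m.R_FeP[k] * loss;   // grazers carry no iron
      }
    }
    dy[iZ0 + g] += m.g_assim[g] * ing - zm - exch * Z;
    double spill = (1.0 - m.g_assim[g]) * ing + zm;
    dy[iDP] += spill;
    dy[iDN] += m.R_NP * spill;
  }

  if (m.fixed_nutrients)
    for (int j = 0; j < 5; ++j) dy[j] = 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_derivative(double t, NumericVector y, List pars) {
  Model m = parse_model(pars);
  if ((int)y.size() != m.n_state)
    stop("state length %d does not match model (%d)", (int)y.size(),
         m.n_state);
  NumericVector dy(m.n_state);
  deriv(m, t, REAL(y), REAL(dy));
  dy.attr("names") = y.attr("names");
  return dy;
}

// ---- Dormand-Prince 5(4) with step control and positivity clipping -------

// [[Rcpp::export]]
List cpp_integrate(NumericVector y0, NumericVector times, List pars,
                   double rtol, double atol, double hmax, double hini) {
  Model m = parse_model(pars);
  const int n = m.n_state;
  if ((int)y0.size() != n) stop("y0 length does not match model");
  const int nt = times.size();
  NumericMatrix out(nt, n);
  std::vector<double> y(REAL(y0), REAL(y0) + n), ynew(n), yerr(n);
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n);

  static const double
      a21 = 1.0 / 5,
      a31 = 3.0 / 40, a32 = 9.0 / 40,
      a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9,
      a51 = 19372.0 / 6561, a52 = -25360.0 / 2187, a53 = 64448.0 / 6561,
      a54 = -212.0 / 729,
      a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
      a64 = 49.0 / 176, a65 = -5103.0 / 18656,
      b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
      b5 = -2187.0 / 6784, b6 = 11.0 / 84,
      e1 = 35.0 / 384 - 5179.0 / 57600, e3 = 500.0 / 1113 - 7571.0 / 16695,
      e4 = 125.0 / 192 - 393.0 / 640,
      e5 = -2187.0 / 6784 + 92097.0 / 339200,
      e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

  double t = times[0];
  for (int j = 0; j < n; ++j) out(0, j) = y[j];
  double h = hini;
  long n_acc = 0, n_rej = 0, n_clip = 0;
  double max_clip = 0.0;
  const long max_steps = 50000000L;
  long steps = 0;
  std::vector<double> ytmp(n);

  for (int it = 1; it < nt; ++it) {
    double tend = times[it];
    while (t < tend) {
      if (++steps > max_steps) stop("integration exceeded step budget");
      if (h > hmax) h = hmax;
      if (t + h > tend) h = tend - t;
      // do not straddle the mutation onset discontinuity
      if (m.mut_enabled && t < m.onset && t + h > m.onset) h = m.onset - t;
      if (h < 1e-12)
        stop("step size underflow at t = %f", t);

      deriv(m, t, y.data(), k1.data());
      for (int j = 0; j < n; ++j) ytmp[j] = y[j] + h * a21 * k1[j];
      deriv(m, t + h / 5.0, ytmp.data(), k2.data());
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
      deriv(m, t + 3.0 * h / 10.0, ytmp.data(), k3.data());
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
      deriv(m, t + 4.0 * h / 5.0, ytmp.data(), k4.data());
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                              a54 * k4[j]);
      deriv(m, t + 8.0 * h / 9.0, ytmp.data(), k5.data());
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                              a64 * k4[j] + a65 * k5[j]);
      deriv(m, t + h, ytmp.data(), k6.data());
      for (int j = 0; j < n; ++j)
        ynew[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                              b5 * k5[j] + b6 * k6[j]);
      deriv(m, t + h, ynew.data(), k7.data());
      double errn = 0.0;
      for (int j = 0; j < n; ++j) {
        double e = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] + e5 * k5[j] +
                        e6 * k6[j] + e7 * k7[j]);
        double ay = std::fabs(y[j]), an = std::fabs(ynew[j]);
        double sc = atol + rtol * (ay > an ? ay : an);
        double q = e / sc;
        errn += q * q;
      }
      errn = std::sqrt(errn / n);
      double fac = 0.9 * std::pow(errn > 1e-300 ? errn : 1e-300, -0.2);
      if (fac > 5.0) fac = 5.0;
      if (fac < 0.2) fac = 0.2;
      if (errn <= 1.0) {
        t += h;
        for (int j = 0; j < n; ++j) {
          double v = ynew[j];
          if (v < 0.0) {            // positivity floor; undershoots only
            if (-v > max_clip) max_clip = -v;
            ++n_clip;
            v = 0.0;
          }
          y[j] = v;
        }
        ++n_acc;
        h *= fac;
      } else {
        ++n_rej;
        h *= (fac < 1.0 ? fac : 0.9);
      }
    }
    for (int j = 0; j < n; ++j) out(it, j) = y[j];
  }

  return List::create(_["y"] = out, _["n_accept"] = (double)n_acc,
                      _["n_reject"] = (double)n_rej,
                      _["n_clip"] = (double)n_clip,
                      _["max_clip"] = max_clip);
}
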