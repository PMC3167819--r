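// Compiled tissue-simulation engine.
//
// This mirrors the pure-R reference implementation (tissue_step / run_tissue)
// exactly: identical arithmetic (R_pow, same expression grouping as the
// vectorized R code) and identical consumption of the R random-number
// stream (R::runif for stem visiting keys and daughter-site choice), so a
// run from the same seed is bit-identical between the two engines.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Flattened sc_params layout; must match params_to_vector() in R/params.R.
enum {
  P_SW_V = 0, P_SW_K, P_SW_N,          // wnt_signal_curve (up)
  P_ID_V, P_ID_K, P_ID_N,              // dkk_inhibition_curve (down)
  P_AK_V, P_AK_K, P_AK_N,              // dkk_synth_curve (up)
  P_DKK_DEG,
  P_GE_V, P_GE_K, P_GE_N,              // lef_ecad_curve (down)
  P_LEF_DEG,
  P_AE_V, P_AE_K, P_AE_N,              // ecad_synth_curve (down)
  P_ECAD_DEG, P_KAPPA,
  P_AP_V, P_AP_K, P_AP_N,              // pf_synth_curve (up)
  P_PF_DEG,
  P_NOTCH_SYNTH,
  P_DN_V, P_DN_K, P_DN_N,              // notch_deg_curve (down)
  P_AH_V, P_AH_K, P_AH_N,              // hes_synth_curve (up)
  P_HES_DEG,
  P_AD_V, P_AD_K, P_AD_N,              // df_synth_curve (down)
  P_DF_DEG,
  P_CP, P_CM, P_TAU, P_PHI, P_DSL, P_WNT_EXT, P_NG_PER_UNIT,
  P_LEN
};

// State column layout (matches state_names() in R/lattice.R).
enum { S_K = 0, S_L, S_E, S_P, S_N, S_H, S_D, S_TDIV };

// Hill curve with precomputed K^n. The n == 2 fast path (x * x) is exactly
// pow(x, 2) under a correctly rounded libm, so it matches R's ^ bitwise;
// the engine-parity unit test guards this.
struct Curve { double vmax, kn, n; bool sq; };

static inline Curve make_curve(const double *p) {
  Curve c;
  c.vmax = p[0];
  c.kn = R_pow(p[1], p[2]);
  c.n = p[2];
  c.sq = (p[2] == 2.0);
  return c;
}

static inline double xpow(double x, const Curve &c) {
  return c.sq ? x * x : R_pow(x, c.n);
}

static inline double up_curve(double x, const Curve &c) {
  double xn = xpow(x, c);
  return c.vmax * xn / (c.kn + xn);
}

static inline double down_curve(double x, const Curve &c) {
  double xn = xpow(x, c);
  return c.vmax * c.kn / (c.kn + xn);
}

struct Inputs { double wnt, dkk, b, dsl; };

// All nine regulatory curves of a parameter set, precomputed once per run.
struct Curves {
  Curve sw, id, ak, ge, ae, ap, dn, ah, ad;
};

static inline Curves make_curves(const double *par) {
  Curves c;
  c.sw = make_curve(par + P_SW_V);
  c.id = make_curve(par + P_ID_V);
  c.ak = make_curve(par + P_AK_V);
  c.ge = make_curve(par + P_GE_V);
  c.ae = make_curve(par + P_AE_V);
  c.ap = make_curve(par + P_AP_V);
  c.dn = make_curve(par + P_DN_V);
  c.ah = make_curve(par + P_AH_V);
  c.ad = make_curve(par + P_AD_V);
  return c;
}

// RHS of the 7 intracellular ODEs; expression-for-expression the same as
// vec_derivs() in R/fate.R.
static inline void derivs(const double *y, const Inputs &in, const double *par,
                          const Curves &c, double *dy) {
  double w = up_curve(in.wnt, c.sw) * down_curve(in.dkk, c.id);
  double n_act = std::min(y[S_N], in.dsl);
  dy[S_K] = up_curve(y[S_L], c.ak) - par[P_DKK_DEG] * y[S_K];
  dy[S_L] = w * down_curve(in.b, c.ge) - par[P_LEF_DEG] * y[S_L];
  dy[S_E] = down_curve(y[S_L], c.ae) - par[P_ECAD_DEG] * y[S_E];
  dy[S_P] = up_curve(y[S_L], c.ap) - par[P_PF_DEG] * y[S_P];
  dy[S_N] = par[P_NOTCH_SYNTH] - down_curve(y[S_L], c.dn) * y[S_N];
  dy[S_H] = up_curve(n_act, c.ah) - par[P_HES_DEG] * y[S_H];
  dy[S_D] = down_curve(y[S_H], c.ad) - par[P_DF_DEG] * y[S_D];
}

static inline void rk4_advance(double *y, const Inputs &in, const double *par,
                               const Curves &c, double dt, double ode_dt) {
  int n_sub = (int)std::ceil(dt / ode_dt - 1e-9);
  if (n_sub < 1) n_sub = 1;
  double h = dt / n_sub;
  double k1[7], k2[7], k3[7], k4[7], yt[7];
  for (int s = 0; s < n_sub; ++s) {
    derivs(y, in, par, c, k1);
    for (int j = 0; j < 7; ++j) yt[j] = std::max(y[j] + (0.5 * h) * k1[j], 0.0);
    derivs(yt, in, par, c, k2);
    for (int j = 0; j < 7; ++j) yt[j] = std::max(y[j] + (0.5 * h) * k2[j], 0.0);
    derivs(yt, in, par, c, k3);
    for (int j = 0; j < 7; ++j) yt[j] = std::max(y[j] + h * k3[j], 0.0);
    derivs(yt, in, par, c, k4);
    for (int j = 0; j < 7; ++j) {
      double s4 = k1[j] + 2 * k2[j];
      s4 = s4 + 2 * k3[j];
      s4 = s4 + k4[j];
      y[j] = std::max(y[j] + (h / 6) * s4, 0.0);
    }
  }
}

// [[Rcpp::export]]
List hca_run_cpp(NumericVector par_in, IntegerMatrix nb,
                 IntegerVector status_in, NumericMatrix state_in,
                 NumericVector frozen_in, NumericVector death_in,
                 NumericVector exo_per_step,
                 double t0, double dt, double ode_dt, int rec_stride) {
  if (par_in.size() != P_LEN) stop("parameter vector has wrong length");
  const double *par = REAL(par_in);
  const Curves curves = make_curves(par);
  const int n = status_in.size();
  const int n_steps = exo_per_step.size();

  std::vector<int> status(status_in.begin(), status_in.end());
  NumericMatrix state = clone(state_in);
  std::vector<double> frozen(frozen_in.begin(), frozen_in.end());
  std::vector<double> death(death_in.begin(), death_in.end());

  std::vector<double> rec_time, rec_dkk;
  std::vector<int> rec_stem, rec_diff;
  long n_div = 0, n_diff_ev = 0, n_death = 0;

  auto record = [&](double tm) {
    int ns = 0, nd = 0;
    long double kd = 0.0;  // R's sum() accumulates in long double
    for (int i = 0; i < n; ++i) {
      if (status[i] == 1) { ++ns; kd += state(i, S_K); }
      else if (status[i] == 2) ++nd;
    }
    rec_time.push_back(tm);
    rec_stem.push_back(ns);
    rec_diff.push_back(nd);
    rec_dkk.push_back((double)kd);
  };
  record(t0);

  std::vector<int> stems;
  stems.reserve(n);
  std::vector<Inputs> inputs;
  inputs.reserve(n);
  std::vector<double> keys;
  std::vector<int> ord;

  for (int k = 1; k <= n_steps; ++k) {
    double t = t0 + (double)(k - 1) * dt;
    double now = t + dt;
    double exo = exo_per_step[k - 1];

    stems.clear();
    for (int i = 0; i < n; ++i)
      if (status[i] == 1) stems.push_back(i);

    if (!stems.empty()) {
      // (1) micro-environmental inputs from the synchronous snapshot
      inputs.clear();
      for (size_t si = 0; si < stems.size(); ++si) {
        int i = stems[si];
        double e_self = state(i, S_E);
        double b = 0.0, dsl = 0.0, dkk_nb = 0.0;
        for (int d = 0; d < 6; ++d) {
          int j = nb(i, d) - 1;
          int st = status[j];
          double e_j = (st == 1) ? state(j, S_E) : (st == 2 ? frozen[j] : 0.0);
          b += par[P_KAPPA] * std::min(e_self, e_j);
          if (st > 0) dsl += par[P_DSL];
          if (st == 1) dkk_nb += state(j, S_K);
        }
        Inputs in;
        in.wnt = par[P_WNT_EXT];
        in.dkk = exo + par[P_NG_PER_UNIT] * (state(i, S_K) + dkk_nb);
        in.b = b;
        in.dsl = dsl;
        inputs.push_back(in);
      }
      // (2) advance every stem cell's ODEs with frozen inputs
      for (size_t si = 0; si < stems.size(); ++si) {
        double y[7];
        int i = stems[si];
        for (int j = 0; j < 7; ++j) y[j] = state(i, j);
        rk4_advance(y, inputs[si], par, curves, dt, ode_dt);
        for (int j = 0; j < 7; ++j) state(i, j) = y[j];
      }
      // (3) fate decisions in uniformly random order
      keys.resize(stems.size());
      for (size_t si = 0; si < stems.size(); ++si) keys[si] = R::runif(0.0, 1.0);
      ord.resize(stems.size());
      for (size_t si = 0; si < stems.size(); ++si) ord[si] = (int)si;
      std::stable_sort(ord.begin(), ord.end(),
                       [&](int a, int b2) { return keys[a] < keys[b2]; });
      for (size_t oi = 0; oi < ord.size(); ++oi) {
        int i = stems[ord[oi]];
        if (state(i, S_D) >= par[P_CM]) {
          frozen[i] = state(i, S_E);
          status[i] = 2;
          for (int j = 0; j < 8; ++j) state(i, j) = 0.0;
          death[i] = now + par[P_PHI];
          ++n_diff_ev;
        } else if (state(i, S_P) >= par[P_CP] &&
                   now - state(i, S_TDIV) >= par[P_TAU]) {
          int empties[6], ne = 0;
          for (int d = 0; d < 6; ++d) {
            int j = nb(i, d) - 1;
            if (status[j] == 0) empties[ne++] = j;
          }
          if (ne >= 1) {
            double u = R::runif(0.0, 1.0);
            int jj = (int)std::floor(u * ne);
            if (jj >= ne) jj = ne - 1;
            int daughter = empties[jj];
            state(i, S_P) = 0.0;
            state(i, S_D) = 0.0;  // symmetric division restarts both fate clocks
            state(i, S_TDIV) = now;
            status[daughter] = 1;
            for (int j = 0; j < 8; ++j) state(daughter, j) = state(i, j);
            ++n_div;
          }
        }
      }
    }
    // (4) scheduled deaths
    for (int i = 0; i < n; ++i) {
      if (status[i] == 2 && !ISNA(death[i]) && death[i] <= now) {
        status[i] = 0;
        frozen[i] = 0.0;
        death[i] = NA_REAL;
        ++n_death;
      }
    }
    if (k % rec_stride == 0) record(now);
  }

  return List::create(
    _["status"] = IntegerVector(status.begin(), status.end()),
    _["state"] = state,
    _["frozen_ecad"] = NumericVector(frozen.begin(), frozen.end()),
    _["death_time"] = NumericVector(death.begin(), death.end()),
    _["series"] = DataFrame::create(
      _["time"] = NumericVector(rec_time.begin(), rec_time.end()),
      _["n_stem"] = IntegerVector(rec_stem.begin(), rec_stem.end()),
      _["n_differentiated"] = IntegerVector(rec_diff.begin(), rec_diff.end()),
      _["total_dkk"] = NumericVector(rec_dkk.begin(), rec_dkk.end())),
    _["n_divisions"] = (double)n_div,
    _["n_differentiations"] = (double)n_diff_ev,
    _["n_deaths"] = (double)n_death);
}
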