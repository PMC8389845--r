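// Discrete-time Chapman-Kolmogorov propagation of the decision-variable
// distribution with absorbing-boundary truncation.
//
// Transition kernels are cell-integrated (normal CDF differences over cell
// edges, with the outermost cells open to +/- infinity), so every step
// conserves probability mass exactly up to floating-point rounding.
// Boundary truncation removes, from each cell, the fraction of its mass
// lying at or beyond the bound under a within-cell uniform (1-D) or
// triangular (2-D diagonal) approximation; whole-cell truncation would
// quantize the bound at grid resolution.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double ncdf(double z) {
  return 0.5 * std::erfc(-z * M_SQRT1_2);
}

// P(cell value >= B) for mass uniform on [dv - h/2, dv + h/2]
static inline double frac_uniform(double dv, double B, double h) {
  double z = (dv - B) / h + 0.5;
  if (z <= 0.0) return 0.0;
  if (z >= 1.0) return 1.0;
  return z;
}

// P(cell value >= B) for mass triangular on [dv - h, dv + h]
// (sum of two independent uniforms of width h: 2-D grid diagonal)
static inline double frac_tri(double dv, double B, double h) {
  double z = (dv - B) / h;
  if (z <= -1.0) return 0.0;
  if (z >= 1.0) return 1.0;
  if (z < 0.0) { double u = 1.0 + z; return 0.5 * u * u; }
  double u = 1.0 - z;
  return 1.0 - 0.5 * u * u;
}

// 1-D aDDM/acbDDM propagation.
// sides: 0 = left fixation, 1 = right fixation, one per step.
// drift_left/drift_right: deterministic DV increment per step by side.
// sigma: per-step diffusion sd. bounds: bound value after each step.
// n_grid points span [-width, width].
// [[Rcpp::export]]
List cpp_propagate_addm(IntegerVector sides, double drift_left,
                        double drift_right, double sigma,
                        NumericVector bounds, int n_grid, double width) {
  const int S = sides.size(), n = n_grid;
  if (S < 1) stop("empty schedule");
  if (n < 11) stop("grid too coarse");
  const double h = 2.0 * width / (n - 1);
  if (width < bounds[0]) stop("grid too narrow to hold the initial bounds");

  // cell centers g[i] = -width + i*h; initial point mass at DV = 0
  std::vector<double> m(n, 0.0);
  m[(n - 1) / 2] = 1.0;

  // per-side convolution kernels over offsets, tails lumped at the ends
  auto build_kernel = [&](double drift, std::vector<double>& ker,
                          int& omin) {
    int lo = (int) std::floor((drift - 8.0 * sigma) / h);
    int hi = (int) std::ceil((drift + 8.0 * sigma) / h);
    if (lo > hi) { lo = hi = (int) std::lround(drift / h); }
    // offsets beyond +/- n always land in an edge cell; the end entries
    // carry the full CDF tails, so clamping loses no mass
    lo = std::max(lo, -n); hi = std::min(hi, n);
    if (lo > hi) lo = hi;
    omin = lo;
    ker.assign(hi - lo + 1, 0.0);
    for (int o = lo; o <= hi; ++o) {
      double e_lo = (o - 0.5) * h, e_hi = (o + 0.5) * h;
      double p_hi = (o == hi) ? 1.0 : ncdf((e_hi - drift) / sigma);
      double p_lo = (o == lo) ? 0.0 : ncdf((e_lo - drift) / sigma);
      ker[o - lo] = p_hi - p_lo;
    }
  };
  std::vector<double> kerL, kerR;
  int ominL, ominR;
  build_kernel(drift_left, kerL, ominL);
  build_kernel(drift_right, kerR, ominR);

  NumericVector p_left(S), p_right(S);
  std::vector<double> nm(n);
  for (int t = 0; t < S; ++t) {
    const bool left = (sides[t] == 0);
    const std::vector<double>& ker = left ? kerL : kerR;
    const int omin = left ? ominL : ominR;
    std::fill(nm.begin(), nm.end(), 0.0);
    // nm[j + o] += m[j] * ker[o]; out-of-range targets fold into the
    // open-ended edge cells
    for (size_t q = 0; q < ker.size(); ++q) {
      const int o = omin + (int) q;
      const double w = ker[q];
      if (w == 0.0) continue;
      const int j0 = std::min(std::max(0, -o), n);
      const int j1 = std::max(std::min(n, n - o), 0);
      double lowsum = 0.0, highsum = 0.0;
      for (int j = 0; j < j0; ++j) lowsum += m[j];
      for (int j = j0; j < j1; ++j) nm[j + o] += m[j] * w;
      for (int j = std::max(j0, j1); j < n; ++j) highsum += m[j];
      if (o < 0) nm[0] += lowsum * w; else if (o > 0) nm[n - 1] += highsum * w;
    }
    const double B = bounds[t];
    double aL = 0.0, aR = 0.0;
    for (int i = 0; i < n; ++i) {
      double g = -width + i * h;
      double fl = frac_uniform(g, B, h);
      double fr = frac_uniform(-g, B, h);
      if (fl + fr > 1.0) fr = 1.0 - fl;
      double mi = nm[i];
      aL += mi * fl;
      aR += mi * fr;
      m[i] = mi * (1.0 - fl - fr);
    }
    p_left[t] = aL;
    p_right[t] = aR;
  }
  double surv = 0.0;
  for (int i = 0; i < n; ++i) surv += m[i];
  return List::create(_["p_left"] = p_left, _["p_right"] = p_right,
                      _["p_survive"] = surv);
}

// PUC propagation on the joint (mu_post_left, mu_post_right) grid.
// The scalar decision variable U_L - U_R is not Markov; the pair of
// posterior means is, given the (deterministic) measurement counts.
// Before an item's first measurement its axis is an exact point mass at
// the prior mean (delta axis), so the state machine runs 0-D -> 1-D -> 2-D.
// sides: 0 = left, 1 = right. v_left/v_right: true values (ratings).
// bounds: bound after each step. Grid: n points on [g_lo, g_hi] per axis.
// [[Rcpp::export]]
List cpp_propagate_puc(IntegerVector sides, double v_left, double v_right,
                       double mu_p, double sigma_p, double sigma, double A,
                       NumericVector bounds, int n_grid, double g_lo,
                       double g_hi) {
  const int S = sides.size(), n = n_grid;
  if (S < 1) stop("empty schedule");
  if (n < 11) stop("grid too coarse");
  const double h = (g_hi - g_lo) / (n - 1);
  // DV lives on the grid diagonal, whose span is +/- (g_hi - g_lo)
  if (g_hi - g_lo < bounds[0]) stop("grid too narrow to hold the initial bounds");
  const double inv_sp2 = 1.0 / (sigma_p * sigma_p);
  const double inv_s2 = 1.0 / (sigma * sigma);

  arma::vec grid(n);
  for (int i = 0; i < n; ++i) grid[i] = g_lo + i * h;

  // sigma_post after T measurements
  auto spost = [&](int T) { return 1.0 / std::sqrt(inv_sp2 + T * inv_s2); };

  // cell-integrated transition matrix along one axis for measurement
  // count T -> T+1 of an item with true value v:
  // mu_new | mu_old ~ N(alpha*mu_old + beta*v, (beta*sigma)^2)
  auto build_K = [&](int T, double v) {
    double kapT = inv_sp2 + T * inv_s2, kapT1 = kapT + inv_s2;
    double alpha = kapT / kapT1, beta = inv_s2 / kapT1;
    double s = beta * sigma;
    arma::mat K(n, n);
    for (int j = 0; j < n; ++j) {
      double mu = alpha * grid[j] + beta * v;
      double prev = 0.0;
      for (int i = 0; i < n; ++i) {
        double cur = (i == n - 1) ? 1.0 : ncdf((grid[i] + 0.5 * h - mu) / s);
        K(i, j) = cur - prev;
        prev = cur;
      }
    }
    return K;
  };
  // expansion of a delta axis (point mass at mu_p) after first measurement
  auto build_delta = [&](double v) {
    double kap1 = inv_sp2 + inv_s2;
    double alpha = inv_sp2 / kap1, beta = inv_s2 / kap1;
    double mu = alpha * mu_p + beta * v, s = beta * sigma;
    arma::vec w(n);
    double prev = 0.0;
    for (int i = 0; i < n; ++i) {
      double cur = (i == n - 1) ? 1.0 : ncdf((grid[i] + 0.5 * h - mu) / s);
      w[i] = cur - prev;
      prev = cur;
    }
    return w;
  };

  int phase = 0;          // 0: both delta; 1: one axis; 2: full 2-D
  int axis = -1;          // phase 1: 0 = left axis live, 1 = right
  int TL = 0, TR = 0;
  arma::vec m1;
  arma::mat m2;

  NumericVector p_left(S), p_right(S);
  for (int t = 0; t < S; ++t) {
    const bool left = (sides[t] == 0);
    const int Tcur = left ? TL : TR;
    const double v = left ? v_left : v_right;

    if (phase == 0) {
      m1 = build_delta(v);
      axis = left ? 0 : 1;
      phase = 1;
    } else if (phase == 1 && ((left && axis == 0) || (!left && axis == 1))) {
      m1 = build_K(Tcur, v) * m1;
    } else if (phase == 1) {
      arma::vec w = build_delta(v);
      if (axis == 0) m2 = m1 * w.t();   // rows: mu_L, cols: mu_R
      else           m2 = w * m1.t();
      phase = 2;
    } else {
      arma::mat K = build_K(Tcur, v);
      if (left) m2 = K * m2;
      else      m2 = m2 * K.t();
    }
    if (left) ++TL; else ++TR;

    // absorption: DV = (mu_L - mu_R) - A*(sigma_post_L - sigma_post_R)
    const double off = A * (spost(TL) - spost(TR));
    const double B = bounds[t];
    double aL = 0.0, aR = 0.0;
    if (phase == 1) {
      // the dead axis sits exactly at the prior mean
      for (int i = 0; i < n; ++i) {
        double dv = (axis == 0) ? (grid[i] - mu_p - off)
                                : (mu_p - grid[i] - off);
        double fl = frac_uniform(dv, B, h);
        double fr = frac_uniform(-dv, B, h);
        if (fl + fr > 1.0) fr = 1.0 - fl;
        double mi = m1[i];
        aL += mi * fl;
        aR += mi * fr;
        m1[i] = mi * (1.0 - fl - fr);
      }
    } else {
      // dv depends on the diagonal index i - j only
      std::vector<double> fl(2 * n - 1), fr(2 * n - 1);
      bool any = false;
      for (int dd = -(n - 1); dd <= n - 1; ++dd) {
        double dv = dd * h - off;
        double a = frac_tri(dv, B, h);
        double b = frac_tri(-dv, B, h);
        if (a + b > 1.0) b = 1.0 - a;
        fl[dd + n - 1] = a;
        fr[dd + n - 1] = b;
        if (a > 0.0 || b > 0.0) any = true;
      }
      if (any) {
        for (int j = 0; j < n; ++j) {
          double* col = m2.colptr(j);
          for (int i = 0; i < n; ++i) {
            int idx = i - j + n - 1;
            double a = fl[idx], b = fr[idx];
            if (a == 0.0 && b == 0.0) continue;
            double mi = col[i];
            aL += mi * a;
            aR += mi * b;
            col[i] = mi * (1.0 - a - b);
          }
        }
      }
    }
    p_left[t] = aL;
    p_right[t] = aR;
  }

  double surv = (phase == 1) ? arma::accu(m1) : arma::accu(m2);
  return List::create(_["p_left"] = p_left, _["p_right"] = p_right,
                      _["p_survive"] = surv);
}
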