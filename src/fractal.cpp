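#include <Rcpp.h>
using namespace Rcpp;

// Symmetric (mirror, edge included) reflection of an out-of-range index.
// Valid for |overhang| <= n, which holds because windows never exceed the
// slice side.
static inline int reflect(int i, int n) {
  if (i < 0) return -i - 1;
  if (i >= n) return 2 * n - 1 - i;
  return i;
}

// One blanket dilation step over the Chebyshev (8-connected) neighbourhood,
// clipped at the image border:
//   u'(i,j) = max(u(i,j) + 1, max_{|(m,n)-(i,j)|<=1} u(m,n))
//   b'(i,j) = min(b(i,j) - 1, min_{|(m,n)-(i,j)|<=1} b(m,n))
// [[Rcpp::export]]
List cpp_dilate_blanket(NumericMatrix upper, NumericMatrix lower) {
  int nr = upper.nrow(), nc = upper.ncol();
  NumericMatrix u1(nr, nc), b1(nr, nc);
  for (int j = 0; j < nc; ++j) {
    int j0 = std::max(0, j - 1), j1 = std::min(nc - 1, j + 1);
    for (int i = 0; i < nr; ++i) {
      int i0 = std::max(0, i - 1), i1 = std::min(nr - 1, i + 1);
      double mx = upper(i, j) + 1.0, mn = lower(i, j) - 1.0;
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii) {
          double u = upper(ii, jj), b = lower(ii, jj);
          if (u > mx) mx = u;
          if (b < mn) mn = b;
        }
      u1(i, j) = mx;
      b1(i, j) = mn;
    }
  }
  return List::create(_["upper"] = u1, _["lower"] = b1);
}

// Blanket surface areas A(eps) = (v_eps - v_{eps-1}) / 2 for eps = 1..max_eps,
// with v_0 = 0 (upper = lower = g at eps 0).
// [[Rcpp::export]]
NumericVector cpp_blanket_areas(NumericMatrix g, int max_eps) {
  int nr = g.nrow(), nc = g.ncol();
  std::vector<double> u(g.begin(), g.end()), b(g.begin(), g.end());
  std::vector<double> u1(nr * nc), b1(nr * nc);
  NumericVector areas(max_eps);
  double v_prev = 0.0;
  for (int e = 1; e <= max_eps; ++e) {
    for (int j = 0; j < nc; ++j) {
      int j0 = std::max(0, j - 1), j1 = std::min(nc - 1, j + 1);
      for (int i = 0; i < nr; ++i) {
        int i0 = std::max(0, i - 1), i1 = std::min(nr - 1, i + 1);
        double mx = u[i + nr * j] + 1.0, mn = b[i + nr * j] - 1.0;
        for (int jj = j0; jj <= j1; ++jj)
          for (int ii = i0; ii <= i1; ++ii) {
            double uu = u[ii + nr * jj], bb = b[ii + nr * jj];
            if (uu > mx) mx = uu;
            if (bb < mn) mn = bb;
          }
        u1[i + nr * j] = mx;
        b1[i + nr * j] = mn;
      }
    }
    u.swap(u1);
    b.swap(b1);
    double v = 0.0;
    for (int k = 0; k < nr * nc; ++k) v += u[k] - b[k];
    areas[e - 1] = (v - v_prev) / 2.0;
    v_prev = v;
  }
  return areas;
}

// Differential box count N_delta over a cells x cells grid of an R x R image
// whose gray axis is divided into R/S boxes of height h = G*S/R. Assumes the
// image is square with side divisible by cells (cropping happens in R).
// [[Rcpp::export]]
double cpp_box_total(NumericMatrix g, int cells, int gray_levels) {
  int R = g.nrow(), S = R / cells;
  double h = (double)gray_levels * S / (double)R;
  double total = 0.0;
  for (int cj = 0; cj < cells; ++cj)
    for (int ci = 0; ci < cells; ++ci) {
      double mn = g(ci * S, cj * S), mx = mn;
      for (int j = cj * S; j < (cj + 1) * S; ++j)
        for (int i = ci * S; i < (ci + 1) * S; ++i) {
          double v = g(i, j);
          if (v > mx) mx = v;
          if (v < mn) mn = v;
        }
      int k = (int)std::floor(mn / h) + 1;
      int l = (int)std::floor(mx / h) + 1;
      if (k > cells) k = cells;  // top-edge clamp (gray == G-1 exactly)
      if (l > cells) l = cells;
      total += l - k + 1;
    }
  return total;
}

// One blanket step on a w x w patch held in column-major buffers, using
// separable row/column max-min passes (the 3x3 Chebyshev max is the column
// 3-max of the row 3-max). Center +/- 1 is folded in afterwards: the
// neighbourhood already contains the center, so u' = max(3x3max, u + 1).
static void blanket_step(std::vector<double>& u, std::vector<double>& b,
                         std::vector<double>& tu, std::vector<double>& tb,
                         std::vector<double>& u1, std::vector<double>& b1,
                         int w) {
  for (int j = 0; j < w; ++j) {
    const double* uc = &u[w * j];
    const double* bc = &b[w * j];
    double* tuc = &tu[w * j];
    double* tbc = &tb[w * j];
    for (int i = 0; i < w; ++i) {
      int i0 = i > 0 ? i - 1 : 0, i1 = i < w - 1 ? i + 1 : w - 1;
      double mx = uc[i0], mn = bc[i0];
      for (int ii = i0 + 1; ii <= i1; ++ii) {
        if (uc[ii] > mx) mx = uc[ii];
        if (bc[ii] < mn) mn = bc[ii];
      }
      tuc[i] = mx;
      tbc[i] = mn;
    }
  }
  for (int j = 0; j < w; ++j) {
    int j0 = j > 0 ? j - 1 : 0, j1 = j < w - 1 ? j + 1 : w - 1;
    for (int i = 0; i < w; ++i) {
      double mx = tu[i + w * j0], mn = tb[i + w * j0];
      for (int jj = j0 + 1; jj <= j1; ++jj) {
        double uu = tu[i + w * jj], bb = tb[i + w * jj];
        if (uu > mx) mx = uu;
        if (bb < mn) mn = bb;
      }
      double uc = u[i + w * j] + 1.0, bc = b[i + w * j] - 1.0;
      u1[i + w * j] = mx > uc ? mx : uc;
      b1[i + w * j] = mn < bc ? mn : bc;
    }
  }
}

// Per-pixel blanket dimension over a sliding window with symmetric reflection
// padding: for every pixel, the window x window patch centred there is
// extracted and the blanket estimator (OLS of log A on log eps, eps = 1 at
// x = 0) is run on it. Pixels where `mask` is FALSE are skipped (output 0).
// [[Rcpp::export]]
NumericMatrix cpp_local_blanket_map(NumericMatrix g, int window, int max_eps,
                                    LogicalMatrix mask) {
  int nr = g.nrow(), nc = g.ncol();
  int h = window / 2, w = window;
  NumericMatrix out(nr, nc);

  // OLS x-statistics for log(eps), eps = 1..max_eps, shared by every pixel
  std::vector<double> lx(max_eps);
  double xbar = 0.0;
  for (int e = 1; e <= max_eps; ++e) {
    lx[e - 1] = std::log((double)e);
    xbar += lx[e - 1];
  }
  xbar /= max_eps;
  double sxx = 0.0;
  for (int e = 0; e < max_eps; ++e) sxx += (lx[e] - xbar) * (lx[e] - xbar);

  std::vector<double> u(w * w), b(w * w), tu(w * w), tb(w * w),
      u1(w * w), b1(w * w);
  std::vector<double> la(max_eps);

  for (int pj = 0; pj < nc; ++pj)
    for (int pi = 0; pi < nr; ++pi) {
      if (!mask(pi, pj)) continue;
      for (int j = 0; j < w; ++j) {
        int gj = reflect(pj - h + j, nc);
        for (int i = 0; i < w; ++i) {
          double v = g(reflect(pi - h + i, nr), gj);
          u[i + w * j] = v;
          b[i + w * j] = v;
        }
      }
      double v_prev = 0.0;
      for (int e = 1; e <= max_eps; ++e) {
        blanket_step(u, b, tu, tb, u1, b1, w);
        u.swap(u1);
        b.swap(b1);
        double v = 0.0;
        for (int k = 0; k < w * w; ++k) v += u[k] - b[k];
        la[e - 1] = std::log((v - v_prev) / 2.0);
        v_prev = v;
      }
      double sxy = 0.0, ybar = 0.0;
      for (int e = 0; e < max_eps; ++e) ybar += la[e];
      ybar /= max_eps;
      for (int e = 0; e < max_eps; ++e) sxy += (lx[e] - xbar) * (la[e] - ybar);
      out(pi, pj) = 2.0 - sxy / sxx;  // D = 2 - slope
    }
  return out;
}

// Per-pixel single-scale box dimension over a sliding window (reflection
// padding); the patch side must be divisible by cells.
// [[Rcpp::export]]
NumericMatrix cpp_local_box_map(NumericMatrix g, int window, int cells,
                                int gray_levels, LogicalMatrix mask) {
  int nr = g.nrow(), nc = g.ncol();
  int hw = window / 2, w = window, S = w / cells;
  double h = (double)gray_levels * S / (double)w;
  double logd = std::log((double)cells);
  NumericMatrix out(nr, nc);
  std::vector<double> patch(w * w);

  for (int pj = 0; pj < nc; ++pj)
    for (int pi = 0; pi < nr; ++pi) {
      if (!mask(pi, pj)) continue;
      for (int j = 0; j < w; ++j) {
        int gj = reflect(pj - hw + j, nc);
        for (int i = 0; i < w; ++i)
          patch[i + w * j] = g(reflect(pi - hw + i, nr), gj);
      }
      double total = 0.0;
      for (int cj = 0; cj < cells; ++cj)
        for (int ci = 0; ci < cells; ++ci) {
          double mn = patch[ci * S + w * (cj * S)], mx = mn;
          for (int j = cj * S; j < (cj + 1) * S; ++j)
            for (int i = ci * S; i < (ci + 1) * S; ++i) {
              double v = patch[i + w * j];
              if (v > mx) mx = v;
              if (v < mn) mn = v;
            }
          int k = (int)std::floor(mn / h) + 1;
          int l = (int)std::floor(mx / h) + 1;
          if (k > cells) k = cells;
          if (l > cells) l = cells;
          total += l - k + 1;
        }
      out(pi, pj) = std::log(total) / logd;
    }
  return out;
}
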