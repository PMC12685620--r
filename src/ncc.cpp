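#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Zero-mean normalized cross-correlation of a template against an image at
// one placement. Image is H x W with rows = v, cols = u (R layout); the
// template's top-left sits at (row0, col0). Returns NA for constant patches.
static double ncc_at(const double *img, int H, const double *tc,
                     int th, int tw, double sst, int row0, int col0) {
  const double n = (double)th * tw;
  double sum = 0.0, sumsq = 0.0, cross = 0.0;
  for (int c = 0; c < tw; ++c) {
    const double *ic = img + (size_t)(col0 + c) * H + row0;
    const double *tcc = tc + (size_t)c * th;
    for (int r = 0; r < th; ++r) {
      const double x = ic[r];
      sum += x;
      sumsq += x * x;
      cross += x * tcc[r]; // tc is zero-mean: this is the centred cross term
    }
  }
  const double ssp = sumsq - sum * sum / n;
  if (ssp <= 0.0 || sst <= 0.0) return NA_REAL;
  return cross / std::sqrt(ssp * sst);
}

static void centre_template(const NumericMatrix &tp, NumericMatrix &tc,
                            double &sst) {
  const int th = tp.nrow(), tw = tp.ncol();
  long double mean = 0.0L;
  for (int c = 0; c < tw; ++c)
    for (int r = 0; r < th; ++r) mean += tp(r, c);
  mean /= (double)th * tw;
  long double ss = 0.0L;
  for (int c = 0; c < tw; ++c)
    for (int r = 0; r < th; ++r) {
      tc(r, c) = tp(r, c) - (double)mean;
      ss += tc(r, c) * tc(r, c);
    }
  sst = (double)ss;
}

// Exhaustive NCC scan over apex placements (u0..u1) x (v0..v1), 0-based
// pixel coordinates; (au, av) is the apex offset inside the template.
// Iteration order (v outer ascending, u inner ascending) with a strict
// greater-than comparison implements the smallest-v-then-smallest-u
// tie-break.
// [[Rcpp::export]]
List ncc_scan_cpp(NumericMatrix img, NumericMatrix tmpl,
                  int u0, int u1, int v0, int v1, int au, int av,
                  bool return_gamma = false) {
  NumericMatrix tc(tmpl.nrow(), tmpl.ncol());
  double sst = 0.0;
  centre_template(tmpl, tc, sst);
  const int nu = u1 - u0 + 1, nv = v1 - v0 + 1;
  const double *ip = img.begin();
  const double *tp = tc.begin();
  const int H = img.nrow(), th = tc.nrow(), tw = tc.ncol();
  NumericMatrix gm;
  if (return_gamma) gm = NumericMatrix(nv, nu);
  double best = -2.0;
  int bu = -1, bv = -1;
  for (int v = v0; v <= v1; ++v) {
    for (int u = u0; u <= u1; ++u) {
      const double g = ncc_at(ip, H, tp, th, tw, sst, v - av, u - au);
      if (return_gamma) gm(v - v0, u - u0) = g;
      if (!ISNAN(g) && g > best) { best = g; bu = u; bv = v; }
    }
  }
  List out = List::create(_["u"] = bu, _["v"] = bv,
                          _["gamma"] = (bu < 0 ? NA_REAL : best));
  if (return_gamma) out["gamma_matrix"] = gm;
  return out;
}

// Strided variant used for wide-window seeding.
// [[Rcpp::export]]
List ncc_scan_strided_cpp(NumericMatrix img, NumericMatrix tmpl,
                          int u0, int u1, int v0, int v1, int au, int av,
                          int stride) {
  NumericMatrix tc(tmpl.nrow(), tmpl.ncol());
  double sst = 0.0;
  centre_template(tmpl, tc, sst);
  const double *ip = img.begin();
  const double *tp = tc.begin();
  const int H = img.nrow(), th = tc.nrow(), tw = tc.ncol();
  double best = -2.0;
  int bu = -1, bv = -1;
  for (int v = v0; v <= v1; v += stride) {
    for (int u = u0; u <= u1; u += stride) {
      const double g = ncc_at(ip, H, tp, th, tw, sst, v - av, u - au);
      if (!ISNAN(g) && g > best) { best = g; bu = u; bv = v; }
    }
  }
  return List::create(_["u"] = bu, _["v"] = bv,
                      _["gamma"] = (bu < 0 ? NA_REAL : best));
}
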