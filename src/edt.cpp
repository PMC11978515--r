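#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact Euclidean nearest-site (feature) transform on a label image.
// For every pixel, finds the nearest pixel carrying a nonzero label, using
// the two-pass separable lower-envelope algorithm: a per-column scan
// records the nearest labeled row within each column, then a per-row
// parabola envelope over the squared column distances yields the global
// nearest site. Ties resolve to the site whose parabola wins the envelope
// (deterministic for a given image).
//
// Returns: label of nearest site, squared distance (pixels^2), and the
// nearest site's row/column (1-based). Pixels in images with no labels at
// all get label 0 and infinite distance.
// [[Rcpp::export]]
List nearest_site_transform(IntegerMatrix labels) {
  const int H = labels.nrow(), W = labels.ncol();
  const double INF = std::numeric_limits<double>::infinity();

  // phase 1: per column, distance (in rows) to nearest labeled row
  NumericMatrix dr(H, W);      // row distance
  IntegerMatrix sr(H, W);      // source row (0-based), -1 if none
  for (int j = 0; j < W; ++j) {
    double d = INF; int src = -1;
    for (int i = 0; i < H; ++i) {
      if (labels(i, j) > 0) { d = 0; src = i; }
      else if (d < INF) d += 1;
      dr(i, j) = d; sr(i, j) = src;
    }
    d = INF; src = -1;
    for (int i = H - 1; i >= 0; --i) {
      if (labels(i, j) > 0) { d = 0; src = i; }
      else if (d < INF) d += 1;
      if (d < dr(i, j)) { dr(i, j) = d; sr(i, j) = src; }
    }
  }

  IntegerMatrix out_label(H, W), out_row(H, W), out_col(H, W);
  NumericMatrix out_d2(H, W);
  std::vector<int> v(W);
  std::vector<double> zbuf(W + 1), f(W);

  // phase 2: per row, 1D squared-distance envelope over columns
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      double d = dr(i, j);
      f[j] = (d == INF) ? INF : d * d;
    }
    int k = 0; bool any = false;
    for (int j = 0; j < W; ++j) {
      if (f[j] == INF) continue;
      if (!any) { v[0] = j; zbuf[0] = -INF; zbuf[1] = INF; any = true; k = 0; continue; }
      double s;
      while (true) {
        int q = v[k];
        s = ((f[j] + (double)j * j) - (f[q] + (double)q * q)) / (2.0 * (j - q));
        if (s <= zbuf[k]) { --k; }
        else break;
      }
      ++k; v[k] = j; zbuf[k] = s; zbuf[k + 1] = INF;
    }
    if (!any) {
      for (int j = 0; j < W; ++j) {
        out_label(i, j) = 0; out_d2(i, j) = R_PosInf;
        out_row(i, j) = NA_INTEGER; out_col(i, j) = NA_INTEGER;
      }
      continue;
    }
    int kk = 0;
    for (int j = 0; j < W; ++j) {
      while (zbuf[kk + 1] < j) ++kk;
      int q = v[kk];
      double d2 = (double)(j - q) * (j - q) + f[q];
      int si = sr(i, q);
      out_d2(i, j) = d2;
      out_label(i, j) = labels(si, q);
      out_row(i, j) = si + 1;
      out_col(i, j) = q + 1;
    }
  }
  return List::create(_["label"] = out_label, _["dist2"] = out_d2,
                      _["row"] = out_row, _["col"] = out_col);
}

// Gaussian KDE vector field: exact (untruncated) sum of isotropic Gaussian
// kernels over a pixel grid, one field slice per gene. The kernel is
// separable, so each read contributes an outer product of two 1D Gaussians.
// `trunc_px` < 0 disables truncation; otherwise kernels are cut at that
// pixel radius.
// [[Rcpp::export]]
NumericVector kde_accumulate(NumericVector px, NumericVector py,
                             IntegerVector gene, int n_gene,
                             int H, int W, double sigma_px,
                             double trunc_px) {
  NumericVector out(H * W * n_gene);
  const int N = px.size();
  const double inv2s2 = 1.0 / (2.0 * sigma_px * sigma_px);
  std::vector<double> kx(W), ky(H);
  for (int r = 0; r < N; ++r) {
    int lo_i = 0, hi_i = H - 1, lo_j = 0, hi_j = W - 1;
    if (trunc_px >= 0) {
      lo_i = std::max(0, (int)std::floor(py[r] - trunc_px));
      hi_i = std::min(H - 1, (int)std::ceil(py[r] + trunc_px));
      lo_j = std::max(0, (int)std::floor(px[r] - trunc_px));
      hi_j = std::min(W - 1, (int)std::ceil(px[r] + trunc_px));
      if (lo_i > hi_i || lo_j > hi_j) continue;
    }
    for (int i = lo_i; i <= hi_i; ++i) {
      double d = i - py[r];
      ky[i] = std::exp(-d * d * inv2s2);
    }
    for (int j = lo_j; j <= hi_j; ++j) {
      double d = j - px[r];
      kx[j] = std::exp(-d * d * inv2s2);
    }
    double *slice = &out[0] + (size_t)(gene[r] - 1) * H * W;
    for (int j = lo_j; j <= hi_j; ++j) {
      double c = kx[j];
      double *colp = slice + (size_t)j * H;
      for (int i = lo_i; i <= hi_i; ++i) colp[i] += c * ky[i];
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, n_gene);
  return out;
}
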