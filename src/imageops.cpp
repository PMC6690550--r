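#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <functional>

using namespace Rcpp;

// Bilinear resampling with half-pixel centre alignment (the convention used
// by mainstream image libraries): dst pixel centre (i+0.5, j+0.5) maps to
// src coordinate ((i+0.5)*sy-0.5, (j+0.5)*sx-0.5), clamped at the border.
// Constant images are reproduced exactly.
// [[Rcpp::export(name = ".cpp_resize_bilinear")]]
NumericMatrix cpp_resize_bilinear(const NumericMatrix& src, int new_h, int new_w) {
  const int h = src.nrow(), w = src.ncol();
  NumericMatrix dst(new_h, new_w);
  const double sy = (double)h / new_h, sx = (double)w / new_w;
  for (int j = 0; j < new_w; ++j) {
    double xs = (j + 0.5) * sx - 0.5;
    if (xs < 0) xs = 0;
    if (xs > w - 1) xs = w - 1;
    int x0 = (int)std::floor(xs);
    int x1 = std::min(x0 + 1, w - 1);
    double fx = xs - x0;
    for (int i = 0; i < new_h; ++i) {
      double ys = (i + 0.5) * sy - 0.5;
      if (ys < 0) ys = 0;
      if (ys > h - 1) ys = h - 1;
      int y0 = (int)std::floor(ys);
      int y1 = std::min(y0 + 1, h - 1);
      double fy = ys - y0;
      double v = (1 - fy) * ((1 - fx) * src(y0, x0) + fx * src(y0, x1)) +
                 fy       * ((1 - fx) * src(y1, x0) + fx * src(y1, x1));
      dst(i, j) = v;
    }
  }
  return dst;
}

// Separable Gaussian blur, reflect-101 border, kernel radius 4*sigma.
// [[Rcpp::export(name = ".cpp_gaussian_blur")]]
NumericMatrix cpp_gaussian_blur(const NumericMatrix& src, double sigma) {
  const int h = src.nrow(), w = src.ncol();
  if (sigma <= 0) return clone(src);
  int radius = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * radius + 1);
  double s2 = 2.0 * sigma * sigma, ksum = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-(double)(i * i) / s2);
    ksum += k[i + radius];
  }
  for (double& v : k) v /= ksum;

  auto reflect = [](int p, int n) {
    // BORDER_REFLECT_101: ... 2 1 | 0 1 2 ... n-1 | n-2 n-3 ...
    if (n == 1) return 0;
    while (p < 0 || p >= n) {
      if (p < 0) p = -p;
      if (p >= n) p = 2 * n - 2 - p;
    }
    return p;
  };

  NumericMatrix tmp(h, w), dst(h, w);
  for (int j = 0; j < w; ++j)       // vertical pass
    for (int i = 0; i < h; ++i) {
      double acc = 0;
      for (int t = -radius; t <= radius; ++t)
        acc += k[t + radius] * src(reflect(i + t, h), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < w; ++j)       // horizontal pass
    for (int i = 0; i < h; ++i) {
      double acc = 0;
      for (int t = -radius; t <= radius; ++t)
        acc += k[t + radius] * tmp(i, reflect(j + t, w));
      dst(i, j) = acc;
    }
  return dst;
}

// Connected-component labelling of a binary mask with 4- or 8-connectivity.
// Two-pass union-find; labels renumbered 1..n in column-major scan order of
// the first pixel of each component (matching R's matrix order).
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> parent(1, 0); // parent[0] unused
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  // first pass, column-major so provisional labels follow R scan order
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j)) continue;
      int up   = (i > 0 && mask(i - 1, j)) ? lab(i - 1, j) : 0;
      int left = (j > 0 && mask(i, j - 1)) ? lab(i, j - 1) : 0;
      int ul = 0, dl = 0;
      if (connectivity == 8) {
        ul = (i > 0 && j > 0 && mask(i - 1, j - 1)) ? lab(i - 1, j - 1) : 0;
        dl = (i < h - 1 && j > 0 && mask(i + 1, j - 1)) ? lab(i + 1, j - 1) : 0;
      }
      int cand[4] = { up, left, ul, dl };
      int lmin = 0;
      for (int c : cand) if (c > 0 && (lmin == 0 || c < lmin)) lmin = c;
      if (lmin == 0) {
        ++next;
        parent.push_back(next);
        lab(i, j) = next;
      } else {
        lab(i, j) = lmin;
        for (int c : cand) if (c > 0) unite(c, lmin);
      }
    }
  // second pass: resolve and renumber in scan order of first occurrence
  std::vector<int> remap(next + 1, 0);
  int nfinal = 0;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      if (!lab(i, j)) continue;
      int r = find(lab(i, j));
      if (!remap[r]) remap[r] = ++nfinal;
      lab(i, j) = remap[r];
    }
  return lab;
}
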