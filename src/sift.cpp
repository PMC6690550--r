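// Scale-invariant feature transform: difference-of-Gaussian keypoint
// detection with sub-pixel refinement, gradient-orientation assignment and
// the 4x4x8 descriptor of Lowe (2004).  Follows the reference formulation
// (trilinear binning, 0.2 clamp, renormalisation); descriptors are kept as
// unit-norm floats.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Img {
  int h = 0, w = 0;
  std::vector<float> d;
  Img() {}
  Img(int h_, int w_) : h(h_), w(w_), d((size_t)h_ * w_, 0.f) {}
  inline float& at(int r, int c) { return d[(size_t)r * w + c]; }
  inline float at(int r, int c) const { return d[(size_t)r * w + c]; }
};

inline int reflect101(int p, int n) {
  if (n == 1) return 0;
  while (p < 0 || p >= n) {
    if (p < 0) p = -p;
    if (p >= n) p = 2 * n - 2 - p;
  }
  return p;
}

Img blur(const Img& src, double sigma) {
  if (sigma <= 1e-8) return src;
  int radius = (int)std::ceil(4.0 * sigma);
  std::vector<float> k(2 * radius + 1);
  double s2 = 2.0 * sigma * sigma, ksum = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = (float)std::exp(-(double)(i * i) / s2);
    ksum += k[i + radius];
  }
  for (float& v : k) v = (float)(v / ksum);
  const int h = src.h, w = src.w;
  Img tmp(h, w), dst(h, w);
  for (int r = 0; r < h; ++r)
    for (int c = 0; c < w; ++c) {
      float acc = 0;
      if (r >= radius && r + radius < h) {
        const float* p = &src.d[(size_t)(r - radius) * w + c];
        for (int t = 0; t <= 2 * radius; ++t, p += w) acc += k[t] * *p;
      } else {
        for (int t = -radius; t <= radius; ++t)
          acc += k[t + radius] * src.at(reflect101(r + t, h), c);
      }
      tmp.at(r, c) = acc;
    }
  for (int r = 0; r < h; ++r) {
    const float* row = &tmp.d[(size_t)r * w];
    for (int c = 0; c < w; ++c) {
      float acc = 0;
      if (c >= radius && c + radius < w) {
        const float* p = row + c - radius;
        for (int t = 0; t <= 2 * radius; ++t) acc += k[t] * p[t];
      } else {
        for (int t = -radius; t <= radius; ++t)
          acc += k[t + radius] * tmp.at(r, reflect101(c + t, w));
      }
      dst.at(r, c) = acc;
    }
  }
  return dst;
}

Img resize_bilinear(const Img& src, int nh, int nw) {
  Img dst(nh, nw);
  double sy = (double)src.h / nh, sx = (double)src.w / nw;
  for (int i = 0; i < nh; ++i) {
    double ys = (i + 0.5) * sy - 0.5;
    ys = std::min(std::max(ys, 0.0), (double)src.h - 1);
    int y0 = (int)ys, y1 = std::min(y0 + 1, src.h - 1);
    double fy = ys - y0;
    for (int j = 0; j < nw; ++j) {
      double xs = (j + 0.5) * sx - 0.5;
      xs = std::min(std::max(xs, 0.0), (double)src.w - 1);
      int x0 = (int)xs, x1 = std::min(x0 + 1, src.w - 1);
      double fx = xs - x0;
      dst.at(i, j) = (float)((1 - fy) * ((1 - fx) * src.at(y0, x0) + fx * src.at(y0, x1)) +
                             fy * ((1 - fx) * src.at(y1, x0) + fx * src.at(y1, x1)));
    }
  }
  return dst;
}

Img halve(const Img& src) {
  Img dst(std::max(1, src.h / 2), std::max(1, src.w / 2));
  for (int i = 0; i < dst.h; ++i)
    for (int j = 0; j < dst.w; ++j)
      dst.at(i, j) = src.at(2 * i, 2 * j);
  return dst;
}

struct Kp {
  double x, y;        // coordinates in the input image frame
  double sigma;       // detection scale in input-image pixels
  double angle;       // radians in [0, 2*pi)
  double response;    // |DoG| at the refined extremum
  int octave, layer;
  double xi;          // sub-scale offset
  double r_oct, c_oct; // refined position within the octave frame
};

const int DESC_D = 4, DESC_N = 8, DESC_LEN = 128;
const double ORI_SIG_FCTR = 1.5, ORI_RADIUS = 3.0 * ORI_SIG_FCTR;
const double DESC_SCL_FCTR = 3.0, DESC_MAG_THR = 0.2;
const int ORI_BINS = 36;

// Gradient-orientation histogram around (r, c); returns max value.
double calc_orientation_hist(const Img& img, int r, int c, int radius,
                             double sigma, double* hist) {
  double expf_scale = -1.0 / (2.0 * sigma * sigma);
  std::vector<double> raw(ORI_BINS, 0.0);
  for (int i = -radius; i <= radius; ++i) {
    int y = r + i;
    if (y <= 0 || y >= img.h - 1) continue;
    for (int j = -radius; j <= radius; ++j) {
      int x = c + j;
      if (x <= 0 || x >= img.w - 1) continue;
      double dx = img.at(y, x + 1) - img.at(y, x - 1);
      double dy = img.at(y - 1, x) - img.at(y + 1, x);
      double mag = std::sqrt(dx * dx + dy * dy);
      double wgt = std::exp((i * i + j * j) * expf_scale);
      double ang = std::atan2(dy, dx);                 // (-pi, pi]
      int bin = (int)std::floor(ORI_BINS * (ang + M_PI) / (2 * M_PI));
      if (bin >= ORI_BINS) bin = ORI_BINS - 1;
      if (bin < 0) bin = 0;
      raw[bin] += wgt * mag;
    }
  }
  // two circular [1 2 1]/4 smoothing passes
  for (int pass = 0; pass < 2; ++pass) {
    std::vector<double> sm(ORI_BINS);
    for (int i = 0; i < ORI_BINS; ++i)
      sm[i] = 0.25 * raw[(i + ORI_BINS - 1) % ORI_BINS] + 0.5 * raw[i] +
              0.25 * raw[(i + 1) % ORI_BINS];
    raw = sm;
  }
  double mx = 0;
  for (int i = 0; i < ORI_BINS; ++i) { hist[i] = raw[i]; mx = std::max(mx, raw[i]); }
  return mx;
}

void calc_descriptor(const Img& img, double rf, double cf, double angle,
                     double scl_oct, float* dst) {
  const int d = DESC_D, n = DESC_N;
  double cos_t = std::cos(angle), sin_t = std::sin(angle);
  double bins_per_rad = n / (2 * M_PI);
  double exp_scale = -1.0 / (d * d * 0.5);
  double hist_width = DESC_SCL_FCTR * scl_oct;
  int radius = (int)std::round(hist_width * std::sqrt(2.0) * (d + 1) * 0.5);
  radius = std::min(radius, (int)std::sqrt((double)img.h * img.h + (double)img.w * img.w));
  cos_t /= hist_width; sin_t /= hist_width;

  std::vector<double> hist((d + 2) * (d + 2) * (n + 2), 0.0);
  int r0 = (int)std::round(rf), c0 = (int)std::round(cf);

  for (int i = -radius; i <= radius; ++i)
    for (int j = -radius; j <= radius; ++j) {
      double c_rot = j * cos_t - i * sin_t;
      double r_rot = j * sin_t + i * cos_t;
      double rbin = r_rot + d / 2 - 0.5;
      double cbin = c_rot + d / 2 - 0.5;
      int r = r0 + i, c = c0 + j;
      if (rbin > -1 && rbin < d && cbin > -1 && cbin < d &&
          r > 0 && r < img.h - 1 && c > 0 && c < img.w - 1) {
        double dx = img.at(r, c + 1) - img.at(r, c - 1);
        double dy = img.at(r - 1, c) - img.at(r + 1, c);
        double grad_mag = std::sqrt(dx * dx + dy * dy);
        double grad_ang = std::atan2(dy, dx);
        double obin = (grad_ang - angle) * bins_per_rad;
        double wgt = std::exp((c_rot * c_rot + r_rot * r_rot) * exp_scale);
        double mag = grad_mag * wgt;

        int ri = (int)std::floor(rbin), ci = (int)std::floor(cbin),
            oi = (int)std::floor(obin);
        double rfrac = rbin - ri, cfrac = cbin - ci, ofrac = obin - oi;
        while (oi < 0) oi += n;
        while (oi >= n) oi -= n;
        // trilinear distribution into the (d+2)x(d+2)x(n+2) accumulator
        double v_r1 = mag * rfrac, v_r0 = mag - v_r1;
        double v_rc11 = v_r1 * cfrac, v_rc10 = v_r1 - v_rc11;
        double v_rc01 = v_r0 * cfrac, v_rc00 = v_r0 - v_rc01;
        double v[8] = { v_rc00 * (1 - ofrac), v_rc00 * ofrac,
                        v_rc01 * (1 - ofrac), v_rc01 * ofrac,
                        v_rc10 * (1 - ofrac), v_rc10 * ofrac,
                        v_rc11 * (1 - ofrac), v_rc11 * ofrac };
        size_t idx = ((size_t)(ri + 1) * (d + 2) + (ci + 1)) * (n + 2) + oi;
        hist[idx] += v[0];
        hist[idx + 1] += v[1];
        hist[idx + (n + 2)] += v[2];
        hist[idx + (n + 3)] += v[3];
        hist[idx + (d + 2) * (n + 2)] += v[4];
        hist[idx + (d + 2) * (n + 2) + 1] += v[5];
        hist[idx + (d + 3) * (n + 2)] += v[6];
        hist[idx + (d + 3) * (n + 2) + 1] += v[7];
      }
    }

  // fold the circular orientation wrap and strip the border cells
  for (int i = 0; i < d; ++i)
    for (int j = 0; j < d; ++j) {
      size_t idx = ((size_t)(i + 1) * (d + 2) + (j + 1)) * (n + 2);
      hist[idx] += hist[idx + n];
      hist[idx + 1] += hist[idx + n + 1];
      for (int k = 0; k < n; ++k)
        dst[(i * d + j) * n + k] = (float)hist[idx + k];
    }

  double nrm2 = 0;
  for (int k = 0; k < DESC_LEN; ++k) nrm2 += (double)dst[k] * dst[k];
  double thr = std::sqrt(nrm2) * DESC_MAG_THR;
  nrm2 = 0;
  for (int k = 0; k < DESC_LEN; ++k) {
    float v = std::min(dst[k], (float)thr);
    dst[k] = v;
    nrm2 += (double)v * v;
  }
  double scale = 1.0 / std::max(std::sqrt(nrm2), 1e-12);
  for (int k = 0; k < DESC_LEN; ++k) dst[k] = (float)(dst[k] * scale);
}

} // namespace

// [[Rcpp::export(name = ".cpp_sift")]]
List cpp_sift(const NumericMatrix& image, int n_octave_layers, double sigma,
              double contrast_threshold, double edge_threshold,
              bool double_size) {
  const int H = image.nrow(), W = image.ncol();
  if (H < 8 || W < 8) {
    return List::create(_["keypoints"] = NumericMatrix(0, 6),
                        _["descriptors"] = NumericMatrix(0, DESC_LEN));
  }
  // image expected in [0, 255]; work in [0, 1]
  Img base0(H, W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      base0.at(r, c) = (float)(image(r, c) / 255.0);

  const double init_blur = 0.5;  // assumed blur of the input
  Img base;
  if (double_size) {
    base = resize_bilinear(base0, 2 * H, 2 * W);
    double sd = std::sqrt(std::max(sigma * sigma - 4.0 * init_blur * init_blur, 0.01));
    base = blur(base, sd);
  } else {
    double sd = std::sqrt(std::max(sigma * sigma - init_blur * init_blur, 0.01));
    base = blur(base0, sd);
  }

  int n_octaves = (int)std::floor(std::log2((double)std::min(base.h, base.w))) - 2;
  if (n_octaves < 1) n_octaves = 1;
  const int s = n_octave_layers;
  const double k = std::pow(2.0, 1.0 / s);

  // per-octave Gaussian (s+3) and DoG (s+2) stacks
  std::vector<double> sig(s + 3);
  sig[0] = sigma;
  for (int i = 1; i < s + 3; ++i) {
    double prev = sigma * std::pow(k, i - 1);
    double total = prev * k;
    sig[i] = std::sqrt(total * total - prev * prev);
  }

  std::vector<Kp> kps;
  std::vector<float> desc_all;   // 128 floats per keypoint, appended per octave
  size_t desc_done = 0;          // keypoints whose descriptor is computed
  const double prelim_thr = 0.5 * contrast_threshold / s;

  Img oct_base = base;
  for (int o = 0; o < n_octaves; ++o) {
    std::vector<Img> gauss(s + 3), dog(s + 2);
    gauss[0] = oct_base;
    for (int i = 1; i < s + 3; ++i) gauss[i] = blur(gauss[i - 1], sig[i]);
    for (int i = 0; i < s + 2; ++i) {
      dog[i] = Img(oct_base.h, oct_base.w);
      for (size_t t = 0; t < dog[i].d.size(); ++t)
        dog[i].d[t] = gauss[i + 1].d[t] - gauss[i].d[t];
    }
    const int h = oct_base.h, w = oct_base.w, border = 5;

    for (int li = 1; li <= s; ++li) {
      const Img &D0 = dog[li - 1], &D1 = dog[li], &D2 = dog[li + 1];
      for (int r = border; r < h - border; ++r)
        for (int c = border; c < w - border; ++c) {
          float v = D1.at(r, c);
          if (std::fabs(v) <= prelim_thr) continue;
          bool mx = true, mn = true;
          for (int dr = -1; dr <= 1 && (mx || mn); ++dr)
            for (int dc = -1; dc <= 1; ++dc) {
              float a = D0.at(r + dr, c + dc), b = D1.at(r + dr, c + dc),
                    cc = D2.at(r + dr, c + dc);
              if (v < a || v < b || v < cc) mx = false;
              if (v > a || v > b || v > cc) mn = false;
              if (!mx && !mn) break;
            }
          if (!mx && !mn) continue;

          // sub-pixel / sub-scale refinement by 3D quadratic fit
          int rr = r, cc = c, ll = li;
          double xr = 0, xc = 0, xi = 0, contr = 0;
          bool ok = false;
          for (int iter = 0; iter < 5; ++iter) {
            const Img &P = dog[ll - 1], &C = dog[ll], &N = dog[ll + 1];
            double dx = 0.5 * (C.at(rr, cc + 1) - C.at(rr, cc - 1));
            double dy = 0.5 * (C.at(rr + 1, cc) - C.at(rr - 1, cc));
            double ds = 0.5 * (N.at(rr, cc) - P.at(rr, cc));
            double vc = C.at(rr, cc);
            double dxx = C.at(rr, cc + 1) + C.at(rr, cc - 1) - 2 * vc;
            double dyy = C.at(rr + 1, cc) + C.at(rr - 1, cc) - 2 * vc;
            double dss = N.at(rr, cc) + P.at(rr, cc) - 2 * vc;
            double dxy = 0.25 * (C.at(rr + 1, cc + 1) - C.at(rr + 1, cc - 1) -
                                 C.at(rr - 1, cc + 1) + C.at(rr - 1, cc - 1));
            double dxs = 0.25 * (N.at(rr, cc + 1) - N.at(rr, cc - 1) -
                                 P.at(rr, cc + 1) + P.at(rr, cc - 1));
            double dys = 0.25 * (N.at(rr + 1, cc) - N.at(rr - 1, cc) -
                                 P.at(rr + 1, cc) + P.at(rr - 1, cc));
            // solve H * x = -g for the 3x3 Hessian
            double A[9] = { dxx, dxy, dxs, dxy, dyy, dys, dxs, dys, dss };
            double g[3] = { dx, dy, ds };
            double det = A[0] * (A[4] * A[8] - A[5] * A[7]) -
                         A[1] * (A[3] * A[8] - A[5] * A[6]) +
                         A[2] * (A[3] * A[7] - A[4] * A[6]);
            if (std::fabs(det) < 1e-20) break;
            double inv[9] = {
              (A[4] * A[8] - A[5] * A[7]), -(A[1] * A[8] - A[2] * A[7]),
              (A[1] * A[5] - A[2] * A[4]), -(A[3] * A[8] - A[5] * A[6]),
              (A[0] * A[8] - A[2] * A[6]), -(A[0] * A[5] - A[2] * A[3]),
              (A[3] * A[7] - A[4] * A[6]), -(A[0] * A[7] - A[1] * A[6]),
              (A[0] * A[4] - A[1] * A[3]) };
            xc = -(inv[0] * g[0] + inv[1] * g[1] + inv[2] * g[2]) / det;
            xr = -(inv[3] * g[0] + inv[4] * g[1] + inv[5] * g[2]) / det;
            xi = -(inv[6] * g[0] + inv[7] * g[1] + inv[8] * g[2]) / det;
            if (std::fabs(xr) < 0.5 && std::fabs(xc) < 0.5 && std::fabs(xi) < 0.5) {
              contr = vc + 0.5 * (dx * xc + dy * xr + ds * xi);
              ok = true;
              break;
            }
            rr += (int)std::round(xr);
            cc += (int)std::round(xc);
            ll += (int)std::round(xi);
            if (ll < 1 || ll > s || rr < border || rr >= h - border ||
                cc < border || cc >= w - border)
              break;
          }
          if (!ok) continue;
          if (std::fabs(contr) * s < contrast_threshold) continue;

          { // principal-curvature (edge) test on the refined layer
            const Img& C = dog[ll];
            double vc = C.at(rr, cc);
            double dxx = C.at(rr, cc + 1) + C.at(rr, cc - 1) - 2 * vc;
            double dyy = C.at(rr + 1, cc) + C.at(rr - 1, cc) - 2 * vc;
            double dxy = 0.25 * (C.at(rr + 1, cc + 1) - C.at(rr + 1, cc - 1) -
                                 C.at(rr - 1, cc + 1) + C.at(rr - 1, cc - 1));
            double tr = dxx + dyy, det2 = dxx * dyy - dxy * dxy;
            double e = edge_threshold;
            if (det2 <= 0 || tr * tr * e >= (e + 1) * (e + 1) * det2) continue;
          }

          Kp kp;
          kp.octave = o; kp.layer = ll; kp.xi = xi;
          kp.r_oct = rr + xr; kp.c_oct = cc + xc;
          double oct_scale = std::pow(2.0, o);
          kp.x = (cc + xc) * oct_scale;
          kp.y = (rr + xr) * oct_scale;
          kp.sigma = sigma * std::pow(2.0, (ll + xi) / s) * oct_scale;
          kp.response = std::fabs(contr);

          // orientation assignment on the matching Gaussian layer
          double scl_oct = sigma * std::pow(2.0, (ll + xi) / s);
          const Img& G = gauss[ll];
          double hist[ORI_BINS];
          int radius = (int)std::round(ORI_RADIUS * scl_oct);
          double omax = calc_orientation_hist(G, rr, cc, radius,
                                              ORI_SIG_FCTR * scl_oct, hist);
          double mag_thr = omax * 0.8;
          for (int b = 0; b < ORI_BINS; ++b) {
            int l = (b + ORI_BINS - 1) % ORI_BINS, rbin = (b + 1) % ORI_BINS;
            if (hist[b] > hist[l] && hist[b] > hist[rbin] && hist[b] >= mag_thr) {
              double db = b + 0.5 * (hist[l] - hist[rbin]) /
                          (hist[l] - 2 * hist[b] + hist[rbin]);
              if (db < 0) db += ORI_BINS;
              if (db >= ORI_BINS) db -= ORI_BINS;
              Kp kq = kp;
              kq.angle = db * 2 * M_PI / ORI_BINS - M_PI;
              if (kq.angle < 0) kq.angle += 2 * M_PI;
              kps.push_back(kq);
            }
          }
        }
    }

    // prepare next octave before gauss goes out of scope
    if (o + 1 < n_octaves) oct_base = halve(gauss[s]);

    // descriptors for this octave's keypoints while the stack is in scope;
    // new keypoints are appended in order, so [desc_done, size) is octave o
    for (size_t i = desc_done; i < kps.size(); ++i) {
      Kp& kp = kps[i];
      double scl_oct = sigma * std::pow(2.0, (kp.layer + kp.xi) / s);
      const Img& G = gauss[kp.layer];
      desc_all.resize(desc_all.size() + DESC_LEN);
      calc_descriptor(G, kp.r_oct, kp.c_oct, kp.angle, scl_oct,
                      &desc_all[desc_all.size() - DESC_LEN]);
    }
    desc_done = kps.size();
  }

  const double coord_scale = double_size ? 0.5 : 1.0;
  int n = (int)kps.size();
  NumericMatrix K(n, 6);
  NumericMatrix D(n, DESC_LEN);
  for (int i = 0; i < n; ++i) {
    K(i, 0) = kps[i].x * coord_scale;
    K(i, 1) = kps[i].y * coord_scale;
    K(i, 2) = kps[i].sigma * coord_scale;
    K(i, 3) = kps[i].angle;
    K(i, 4) = kps[i].response;
    K(i, 5) = kps[i].octave + (double_size ? -1 : 0);
    for (int j = 0; j < DESC_LEN; ++j) D(i, j) = desc_all[(size_t)i * DESC_LEN + j];
  }
  colnames(K) = CharacterVector::create("x", "y", "scale", "orientation",
                                        "response", "octave");
  return List::create(_["keypoints"] = K, _["descriptors"] = D);
}
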