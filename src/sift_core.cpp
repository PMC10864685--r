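// Low-level kernels for scale-space construction, keypoint description,
// descriptor matching and synthetic pattern rasterisation. Images are
// numeric matrices with rows = y (downward) and cols = x.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cmath>

using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // symmetric reflection including the edge pixel: -1 -> 0, n -> n-1
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian blur, kernel truncated at 4 sigma, reflected borders.
// [[Rcpp::export(name = ".gauss_blur_cpp")]]
arma::mat gauss_blur_cpp(const arma::mat& img, double sigma) {
  if (sigma <= 0) return img;
  int radius = std::max(1, (int)std::ceil(4.0 * sigma));
  arma::vec k(2 * radius + 1);
  for (int i = -radius; i <= radius; ++i)
    k(i + radius) = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
  k /= arma::accu(k);

  int nr = img.n_rows, nc = img.n_cols;
  arma::mat tmp(nr, nc), out(nr, nc);
  // along rows (vertical)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int i = -radius; i <= radius; ++i)
        s += k(i + radius) * img(reflect_idx(r + i, nr), c);
      tmp(r, c) = s;
    }
  // along cols (horizontal)
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double s = 0.0;
      for (int i = -radius; i <= radius; ++i)
        s += k(i + radius) * tmp(r, reflect_idx(c + i, nc));
      out(r, c) = s;
    }
  return out;
}

// Corner-aligned bilinear resize.
// [[Rcpp::export(name = ".resize_bilinear_cpp")]]
arma::mat resize_bilinear_cpp(const arma::mat& img, int out_h, int out_w) {
  int nr = img.n_rows, nc = img.n_cols;
  arma::mat out(out_h, out_w);
  double sy = (out_h > 1) ? (double)(nr - 1) / (out_h - 1) : 0.0;
  double sx = (out_w > 1) ? (double)(nc - 1) / (out_w - 1) : 0.0;
  for (int r = 0; r < out_h; ++r) {
    double fy = r * sy;
    int y0 = (int)std::floor(fy); if (y0 > nr - 2) y0 = nr - 2; if (y0 < 0) y0 = 0;
    double wy = fy - y0;
    for (int c = 0; c < out_w; ++c) {
      double fx = c * sx;
      int x0 = (int)std::floor(fx); if (x0 > nc - 2) x0 = nc - 2; if (x0 < 0) x0 = 0;
      double wx = fx - x0;
      out(r, c) = (1 - wy) * ((1 - wx) * img(y0, x0) + wx * img(y0, x0 + 1)) +
                  wy * ((1 - wx) * img(y0 + 1, x0) + wx * img(y0 + 1, x0 + 1));
    }
  }
  return out;
}

// Rotate (degrees, about image centre) and scale, bilinear, zeros outside.
// [[Rcpp::export(name = ".affine_view_cpp")]]
arma::mat affine_view_cpp(const arma::mat& img, double angle_deg, double scale) {
  int nr = img.n_rows, nc = img.n_cols;
  double th = angle_deg * M_PI / 180.0;
  double ca = std::cos(th), sa = std::sin(th);
  double cy = (nr - 1) / 2.0, cx = (nc - 1) / 2.0;
  arma::mat out(nr, nc, arma::fill::zeros);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      // inverse map: rotate by -angle, scale by 1/scale
      double dx = (c - cx), dy = (r - cy);
      double sxp = (ca * dx + sa * dy) / scale + cx;
      double syp = (-sa * dx + ca * dy) / scale + cy;
      int x0 = (int)std::floor(sxp), y0 = (int)std::floor(syp);
      if (x0 < 0 || y0 < 0 || x0 > nc - 2 || y0 > nr - 2) continue;
      double wx = sxp - x0, wy = syp - y0;
      out(r, c) = (1 - wy) * ((1 - wx) * img(y0, x0) + wx * img(y0, x0 + 1)) +
                  wy * ((1 - wx) * img(y0 + 1, x0) + wx * img(y0 + 1, x0 + 1));
    }
  }
  return out;
}

// Strict 26-neighbour extrema over one octave of DoG images.
// Returns (level, row, col), all 1-based, interior levels/pixels only.
// [[Rcpp::export(name = ".detect_extrema_cpp")]]
IntegerMatrix detect_extrema_cpp(List dog) {
  int nlev = dog.size();
  std::vector<arma::mat> D(nlev);
  for (int i = 0; i < nlev; ++i) D[i] = as<arma::mat>(dog[i]);
  int nr = D[0].n_rows, nc = D[0].n_cols;
  std::vector<int> lv, rv, cv;
  for (int l = 1; l < nlev - 1; ++l) {
    const arma::mat& lo = D[l - 1];
    const arma::mat& mi = D[l];
    const arma::mat& hi = D[l + 1];
    for (int r = 1; r < nr - 1; ++r) {
      for (int c = 1; c < nc - 1; ++c) {
        double v = mi(r, c);
        bool mx = true, mn = true;
        for (int dr = -1; dr <= 1 && (mx || mn); ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            double a = lo(r + dr, c + dc), b = mi(r + dr, c + dc), d = hi(r + dr, c + dc);
            if (!(dr == 0 && dc == 0)) {
              if (b >= v) mx = false;
              if (b <= v) mn = false;
            }
            if (a >= v || d >= v) mx = false;
            if (a <= v || d <= v) mn = false;
            if (!mx && !mn) break;
          }
        }
        if (mx || mn) { lv.push_back(l + 1); rv.push_back(r + 1); cv.push_back(c + 1); }
      }
    }
  }
  IntegerMatrix out(lv.size(), 3);
  for (size_t i = 0; i < lv.size(); ++i) {
    out(i, 0) = lv[i]; out(i, 1) = rv[i]; out(i, 2) = cv[i];
  }
  colnames(out) = CharacterVector::create("level", "row", "col");
  return out;
}

// Gradient-orientation histogram around (row, col) [1-based] of a blurred
// level. Circular Gaussian window, sigma_w = sigma_factor * sigma_rel,
// radius 3*sigma_w. Returns nbins counts (bin 0 covers [0, 360/nbins) deg).
// [[Rcpp::export(name = ".orientation_hist_cpp")]]
NumericVector orientation_hist_cpp(const arma::mat& L, int row, int col,
                                   double sigma_rel, int nbins,
                                   double sigma_factor) {
  int nr = L.n_rows, nc = L.n_cols;
  int r0 = row - 1, c0 = col - 1;
  double sw = sigma_factor * sigma_rel;
  int radius = std::max(1, (int)std::round(3.0 * sw));
  NumericVector hist(nbins);
  double binw = 360.0 / nbins;
  for (int dr = -radius; dr <= radius; ++dr) {
    for (int dc = -radius; dc <= radius; ++dc) {
      if (dr * dr + dc * dc > radius * radius) continue;
      int r = r0 + dr, c = c0 + dc;
      if (r < 1 || c < 1 || r > nr - 2 || c > nc - 2) continue;
      double dx = L(r, c + 1) - L(r, c - 1);
      double dy = L(r + 1, c) - L(r - 1, c);
      double m = std::sqrt(dx * dx + dy * dy);
      if (m == 0) continue;
      double th = std::atan2(dy, dx) * 180.0 / M_PI;
      if (th < 0) th += 360.0;
      double w = std::exp(-0.5 * (dr * dr + dc * dc) / (sw * sw));
      int b = (int)std::floor(th / binw);
      if (b >= nbins) b = nbins - 1;
      hist[b] += m * w;
    }
  }
  return hist;
}

// 128-d descriptor: window x window pixel neighbourhood rotated into the
// keypoint frame, subblocks x subblocks cells of nbins orientation bins,
// trilinear sharing, Gaussian weight sigma = window/2, normalize -> clamp
// -> renormalize. Flat patch returns all zeros.
// [[Rcpp::export(name = ".descriptor_cpp")]]
NumericVector descriptor_cpp(const arma::mat& L, double row, double col,
                             double ori_deg, int window, int subblocks,
                             int nbins, double clampv) {
  int nr = L.n_rows, nc = L.n_cols;
  int d = subblocks;
  double half = window / 2.0;
  double th = ori_deg * M_PI / 180.0;
  double ca = std::cos(th), sa = std::sin(th);
  double sigw = half;              // Gaussian over the whole window
  double cell = (double)window / d;
  int R = (int)std::ceil(half * std::sqrt(2.0)) + 1;
  int r0 = (int)std::round(row), c0 = (int)std::round(col);

  std::vector<double> acc(d * d * nbins, 0.0);
  double obinw = 360.0 / nbins;

  for (int dr = -R; dr <= R; ++dr) {
    for (int dc = -R; dc <= R; ++dc) {
      int r = r0 + dr, c = c0 + dc;
      if (r < 1 || c < 1 || r > nr - 2 || c > nc - 2) continue;
      // rotate pixel offset into keypoint frame (by -orientation)
      double u = ca * dc + sa * dr;
      double v = -sa * dc + ca * dr;
      double rbin = v / cell + d / 2.0 - 0.5;
      double cbin = u / cell + d / 2.0 - 0.5;
      if (rbin <= -1.0 || rbin >= (double)d || cbin <= -1.0 || cbin >= (double)d)
        continue;
      double gx = L(r, c + 1) - L(r, c - 1);
      double gy = L(r + 1, c) - L(r - 1, c);
      double m = std::sqrt(gx * gx + gy * gy);
      if (m == 0) continue;
      double ang = std::atan2(gy, gx) * 180.0 / M_PI - ori_deg;
      while (ang < 0) ang += 360.0;
      while (ang >= 360.0) ang -= 360.0;
      double obin = ang / obinw;
      double w = m * std::exp(-0.5 * (u * u + v * v) / (sigw * sigw));

      int rb = (int)std::floor(rbin), cb = (int)std::floor(cbin),
          ob = (int)std::floor(obin);
      double fr = rbin - rb, fc = cbin - cb, fo = obin - ob;
      for (int ir = 0; ir <= 1; ++ir) {
        int rr = rb + ir;
        if (rr < 0 || rr >= d) continue;
        double wr = w * (ir ? fr : 1 - fr);
        for (int ic = 0; ic <= 1; ++ic) {
          int cc = cb + ic;
          if (cc < 0 || cc >= d) continue;
          double wc = wr * (ic ? fc : 1 - fc);
          for (int io = 0; io <= 1; ++io) {
            int oo = (ob + io) % nbins;
            acc[(rr * d + cc) * nbins + oo] += wc * (io ? fo : 1 - fo);
          }
        }
      }
    }
  }

  int n = d * d * nbins;
  NumericVector out(n);
  double nrm = 0.0;
  for (int i = 0; i < n; ++i) nrm += acc[i] * acc[i];
  nrm = std::sqrt(nrm);
  if (nrm == 0) return out;
  for (int i = 0; i < n; ++i) out[i] = acc[i] / nrm;
  // clamp-and-renormalize fixed point: the k largest components saturate
  // at the clamp, the rest rescale so the norm stays 1. Found by direct
  // water-filling over the sorted components; if no feasible saturation
  // set exists (fewer than 1/clamp^2 populated bins), fall back to a
  // single clamp + renormalization.
  std::vector<double> srt(out.begin(), out.end());
  std::sort(srt.begin(), srt.end(), std::greater<double>());
  double rem = 0.0;
  for (int i = 0; i < n; ++i) rem += srt[i] * srt[i];
  bool solved = false;
  for (int k = 0; k <= n; ++k) {
    if (k > 0) rem -= srt[k - 1] * srt[k - 1];
    double target = 1.0 - k * clampv * clampv;
    double next_v = (k < n) ? srt[k] : 0.0;
    if (target <= 1e-12) {
      // the k saturated components alone carry the whole norm
      double thr = srt[k - 1];
      for (int i = 0; i < n; ++i) out[i] = (out[i] >= thr) ? clampv : 0.0;
      solved = true;
      break;
    }
    if (rem <= 1e-12) break;  // infeasible: not enough unsaturated mass
    double beta = std::sqrt(target / rem);
    if (beta * next_v <= clampv + 1e-12) {
      for (int i = 0; i < n; ++i) {
        double x = beta * out[i];
        out[i] = (x > clampv) ? clampv : x;
      }
      solved = true;
      break;
    }
  }
  if (!solved) {
    for (int i = 0; i < n; ++i) if (out[i] > clampv) out[i] = clampv;
    double nrm2 = 0.0;
    for (int i = 0; i < n; ++i) nrm2 += out[i] * out[i];
    nrm2 = std::sqrt(nrm2);
    if (nrm2 > 0) for (int i = 0; i < n; ++i) out[i] /= nrm2;
  }
  return out;
}

// Exact k nearest neighbours (Euclidean) of each query row among target
// rows. Returns list(index = n x k 1-based, distance = n x k).
// [[Rcpp::export(name = ".knn_cpp")]]
List knn_cpp(const arma::mat& query, const arma::mat& target, int k) {
  int nq = query.n_rows, nt = target.n_rows;
  arma::vec qn = arma::sum(arma::square(query), 1);
  arma::vec tn = arma::sum(arma::square(target), 1);
  IntegerMatrix idx(nq, k);
  NumericMatrix dist(nq, k);
  // process queries in blocks to bound memory
  int block = 256;
  for (int s = 0; s < nq; s += block) {
    int e = std::min(nq, s + block);
    arma::mat G = query.rows(s, e - 1) * target.t();   // (e-s) x nt
    for (int i = s; i < e; ++i) {
      arma::rowvec d2 = qn(i) + tn.t() - 2.0 * G.row(i - s);
      arma::uvec ord = arma::sort_index(d2);
      for (int j = 0; j < k && j < nt; ++j) {
        double v = d2(ord(j));
        dist(i, j) = std::sqrt(v > 0 ? v : 0);
        idx(i, j) = ord(j) + 1;
      }
    }
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Jittered-grid Voronoi tessellation raster. Seeds live on a gx x gy grid
// (column-major over grid cells: cell (i,j) -> index j*gx+i). For each
// pixel, nearest and second-nearest seed in the 5x5 surrounding grid
// neighbourhood; intensity = shade(nearest), darkened near cell borders.
// [[Rcpp::export(name = ".voronoi_pattern_cpp")]]
arma::mat voronoi_pattern_cpp(int height, int width,
                              const arma::vec& seed_x, const arma::vec& seed_y,
                              const arma::vec& shade,
                              int gx, int gy, double spacing,
                              double boundary_width, double boundary_darkness) {
  arma::mat out(height, width);
  for (int r = 0; r < height; ++r) {
    for (int c = 0; c < width; ++c) {
      int gi = (int)std::floor(c / spacing);
      int gj = (int)std::floor(r / spacing);
      double d1 = 1e30, d2 = 1e30;
      int best = -1;
      for (int j = gj - 2; j <= gj + 2; ++j) {
        if (j < 0 || j >= gy) continue;
        for (int i = gi - 2; i <= gi + 2; ++i) {
          if (i < 0 || i >= gx) continue;
          int s = j * gx + i;
          double dx = c - seed_x(s), dy = r - seed_y(s);
          double dd = std::sqrt(dx * dx + dy * dy);
          if (dd < d1) { d2 = d1; d1 = dd; best = s; }
          else if (dd < d2) { d2 = dd; }
        }
      }
      double val = shade(best);
      double gap = d2 - d1;      // 0 on the cell border
      if (gap < boundary_width) {
        val -= boundary_darkness * (1.0 - gap / boundary_width);
      }
      out(r, c) = std::min(1.0, std::max(0.0, val));
    }
  }
  return out;
}

// Mean gradient magnitude (central differences, interior pixels).
// [[Rcpp::export(name = ".mean_gradient_cpp")]]
double mean_gradient_cpp(const arma::mat& img) {
  int nr = img.n_rows, nc = img.n_cols;
  double s = 0.0; long n = 0;
  for (int r = 1; r < nr - 1; ++r)
    for (int c = 1; c < nc - 1; ++c) {
      double dx = img(r, c + 1) - img(r, c - 1);
      double dy = img(r + 1, c) - img(r - 1, c);
      s += std::sqrt(dx * dx + dy * dy);
      ++n;
    }
  return n ? s / n : 0.0;
}

// Batched identification scoring: for each query descriptor and each
// database entry (a contiguous row block of `target`), the two nearest
// distances; the ratio test (d1 < ratio*d2 strictly, d2 > 0) accumulates
// per-entry match counts and matched-distance sums. Semantics identical
// to per-entry knn_search + ratio_filter.
// [[Rcpp::export(name = ".match_counts_cpp")]]
List match_counts_cpp(const arma::mat& query, const arma::mat& target,
                      const IntegerVector& entry_start,
                      const IntegerVector& entry_len, double ratio) {
  int nq = query.n_rows, ne = entry_start.size();
  arma::vec qn = arma::sum(arma::square(query), 1);
  arma::vec tn = arma::sum(arma::square(target), 1);
  IntegerVector counts(ne);
  NumericVector sums(ne);
  int block = 128;
  for (int s = 0; s < nq; s += block) {
    int e = std::min(nq, s + block);
    arma::mat G = query.rows(s, e - 1) * target.t();
    for (int i = s; i < e; ++i) {
      for (int en = 0; en < ne; ++en) {
        int st = entry_start[en], len = entry_len[en];
        if (len < 2) continue;
        double d1 = 1e300, d2 = 1e300;
        for (int j = 0; j < len; ++j) {
          double v = qn(i) + tn(st + j) - 2.0 * G(i - s, st + j);
          if (v < d1) { d2 = d1; d1 = v; }
          else if (v < d2) { d2 = v; }
        }
        d1 = std::sqrt(d1 > 0 ? d1 : 0);
        d2 = std::sqrt(d2 > 0 ? d2 : 0);
        if (d2 > 0 && d1 < ratio * d2) {
          counts[en] += 1;
          sums[en] += d1;
        }
      }
    }
  }
  return List::create(_["n_matches"] = counts, _["sum_distance"] = sums);
}
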