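// Low-level image kernels shared by the workflow stages. All matrices are
// column-major base-R matrices; pixel (row, col) is 1-based on the R side.
#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Connected-component labelling on a logical mask, 8-connectivity.
// Returns an integer matrix of labels (0 = background), labelled in
// raster-scan discovery order so results are independent of any RNG.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back(c * nr + r);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (!dr && !dc) continue;
            int rr = cr + dr, c2 = cc + dc;
            if (rr < 0 || rr >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(rr, c2) && !lab(rr, c2)) {
              lab(rr, c2) = next;
              stack.push_back(c2 * nr + rr);
            }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Per-pixel Shannon entropy (base 2) of the intensity histogram over a disc
// neighbourhood of the given radius, window clipped at the frame border.
// `q` holds integer bin indices in [0, nbins).
// [[Rcpp::export]]
NumericMatrix cpp_local_entropy(const IntegerMatrix& q, int radius, int nbins) {
  const int nr = q.nrow(), nc = q.ncol();
  if (radius < 1) stop("radius must be >= 1");
  std::vector<std::pair<int,int> > disc;
  for (int dc = -radius; dc <= radius; ++dc)
    for (int dr = -radius; dr <= radius; ++dr)
      if (dr * dr + dc * dc <= radius * radius) disc.push_back(std::make_pair(dr, dc));
  NumericMatrix out(nr, nc);
  std::vector<int> hist(nbins, 0);
  std::vector<int> touched;
  touched.reserve(disc.size());
  const double log2inv = 1.0 / std::log(2.0);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int n = 0;
      for (size_t i = 0; i < disc.size(); ++i) {
        int rr = r + disc[i].first, cc = c + disc[i].second;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int b = q(rr, cc);
        if (hist[b]++ == 0) touched.push_back(b);
        ++n;
      }
      double h = 0.0;
      for (size_t i = 0; i < touched.size(); ++i) {
        double p = (double)hist[touched[i]] / n;
        h -= p * std::log(p) * log2inv;
        hist[touched[i]] = 0;
      }
      touched.clear();
      out(r, c) = h;
    }
  }
  return out;
}

// Box-filter local mean with window half-width `radius`, border windows
// clipped and renormalised (integral-image implementation).
// [[Rcpp::export]]
NumericMatrix cpp_box_mean(const NumericMatrix& x, int radius) {
  const int nr = x.nrow(), nc = x.ncol();
  // summed-area table with a zero guard row/col
  std::vector<double> sat((nr + 1) * (size_t)(nc + 1), 0.0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      sat[(size_t)(c + 1) * (nr + 1) + (r + 1)] =
        x(r, c) + sat[(size_t)c * (nr + 1) + (r + 1)] +
        sat[(size_t)(c + 1) * (nr + 1) + r] - sat[(size_t)c * (nr + 1) + r];
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    int c0 = std::max(0, c - radius), c1 = std::min(nc - 1, c + radius);
    for (int r = 0; r < nr; ++r) {
      int r0 = std::max(0, r - radius), r1 = std::min(nr - 1, r + radius);
      double s = sat[(size_t)(c1 + 1) * (nr + 1) + (r1 + 1)] -
                 sat[(size_t)c0 * (nr + 1) + (r1 + 1)] -
                 sat[(size_t)(c1 + 1) * (nr + 1) + r0] +
                 sat[(size_t)c0 * (nr + 1) + r0];
      out(r, c) = s / ((double)(r1 - r0 + 1) * (c1 - c0 + 1));
    }
  }
  return out;
}

static inline double catmull_rom(double p0, double p1, double p2, double p3, double t) {
  return p1 + 0.5 * t * (p2 - p0 + t * (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3 +
                 t * (3.0 * (p1 - p2) + p3 - p0)));
}

// Cubic (Catmull-Rom) resampling of a single channel to out_nr x out_nc,
// pixel-centre alignment, border replication.
// [[Rcpp::export]]
NumericMatrix cpp_resize_cubic(const NumericMatrix& x, int out_nr, int out_nc) {
  const int nr = x.nrow(), nc = x.ncol();
  if (out_nr < 1 || out_nc < 1) stop("invalid output size");
  NumericMatrix tmp(out_nr, nc), out(out_nr, out_nc);
  const double sr = (double)nr / out_nr, sc = (double)nc / out_nc;
  // rows
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < out_nr; ++r) {
      double src = (r + 0.5) * sr - 0.5;
      int i1 = (int)std::floor(src);
      double t = src - i1;
      int i0 = std::max(0, std::min(nr - 1, i1 - 1));
      int a1 = std::max(0, std::min(nr - 1, i1));
      int i2 = std::max(0, std::min(nr - 1, i1 + 1));
      int i3 = std::max(0, std::min(nr - 1, i1 + 2));
      tmp(r, c) = catmull_rom(x(i0, c), x(a1, c), x(i2, c), x(i3, c), t);
    }
  }
  // columns
  for (int c = 0; c < out_nc; ++c) {
    double src = (c + 0.5) * sc - 0.5;
    int j1 = (int)std::floor(src);
    double t = src - j1;
    int j0 = std::max(0, std::min(nc - 1, j1 - 1));
    int b1 = std::max(0, std::min(nc - 1, j1));
    int j2 = std::max(0, std::min(nc - 1, j1 + 1));
    int j3 = std::max(0, std::min(nc - 1, j1 + 2));
    for (int r = 0; r < out_nr; ++r)
      out(r, c) = catmull_rom(tmp(r, j0), tmp(r, b1), tmp(r, j2), tmp(r, j3), t);
  }
  return out;
}

// Contrast-limited adaptive histogram equalisation on an 8-bit channel.
// Tile mappings are clipped at clip_fraction of the tile mass (excess
// redistributed uniformly) and blended bilinearly between tile centres.
// [[Rcpp::export]]
NumericMatrix cpp_clahe(const NumericMatrix& x, int tiles_r, int tiles_c,
                        double clip_fraction) {
  const int nr = x.nrow(), nc = x.ncol(), nbins = 256;
  if (tiles_r < 1 || tiles_c < 1) stop("invalid tile grid");
  if (tiles_r > nr) tiles_r = nr;
  if (tiles_c > nc) tiles_c = nc;
  // tile boundaries (equal split)
  std::vector<int> rb(tiles_r + 1), cb(tiles_c + 1);
  for (int i = 0; i <= tiles_r; ++i) rb[i] = (int)std::round((double)i * nr / tiles_r);
  for (int j = 0; j <= tiles_c; ++j) cb[j] = (int)std::round((double)j * nc / tiles_c);
  // per-tile clipped-CDF mapping to [0,255]
  std::vector<double> map((size_t)tiles_r * tiles_c * nbins, 0.0);
  std::vector<double> ctr_r(tiles_r), ctr_c(tiles_c);
  std::vector<double> hist(nbins);
  for (int ti = 0; ti < tiles_r; ++ti) {
    for (int tj = 0; tj < tiles_c; ++tj) {
      std::fill(hist.begin(), hist.end(), 0.0);
      double npix = 0;
      for (int c = cb[tj]; c < cb[tj + 1]; ++c)
        for (int r = rb[ti]; r < rb[ti + 1]; ++r) {
          int b = (int)std::lround(x(r, c));
          if (b < 0) b = 0; if (b > 255) b = 255;
          hist[b] += 1.0; npix += 1.0;
        }
      double clip = std::max(1.0, clip_fraction * npix);
      double excess = 0.0;
      for (int b = 0; b < nbins; ++b)
        if (hist[b] > clip) { excess += hist[b] - clip; hist[b] = clip; }
      double add = excess / nbins;
      double cum = 0.0;
      double* m = &map[((size_t)ti * tiles_c + tj) * nbins];
      for (int b = 0; b < nbins; ++b) {
        cum += hist[b] + add;
        m[b] = 255.0 * cum / npix;
      }
      ctr_r[ti] = 0.5 * (rb[ti] + rb[ti + 1] - 1);
      ctr_c[tj] = 0.5 * (cb[tj] + cb[tj + 1] - 1);
    }
  }
  // bracketing tile centres and blend weight for a coordinate
  auto bracket = [](const std::vector<double>& ctr, double v,
                    int& i0, int& i1, double& w) {
    int n = (int)ctr.size();
    if (n == 1 || v <= ctr[0]) { i0 = i1 = 0; w = 0.0; return; }
    if (v >= ctr[n - 1]) { i0 = i1 = n - 1; w = 0.0; return; }
    int j = 0;
    while (j < n - 2 && ctr[j + 1] <= v) ++j;
    i0 = j; i1 = j + 1;
    w = (v - ctr[j]) / (ctr[j + 1] - ctr[j]);
  };
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    int tj0, tj1; double wc;
    bracket(ctr_c, (double)c, tj0, tj1, wc);
    for (int r = 0; r < nr; ++r) {
      int ti0, ti1; double wr;
      bracket(ctr_r, (double)r, ti0, ti1, wr);
      int b = (int)std::lround(x(r, c));
      if (b < 0) b = 0; if (b > 255) b = 255;
      double v00 = map[((size_t)ti0 * tiles_c + tj0) * nbins + b];
      double v01 = map[((size_t)ti0 * tiles_c + tj1) * nbins + b];
      double v10 = map[((size_t)ti1 * tiles_c + tj0) * nbins + b];
      double v11 = map[((size_t)ti1 * tiles_c + tj1) * nbins + b];
      out(r, c) = (1 - wr) * ((1 - wc) * v00 + wc * v01) +
                  wr * ((1 - wc) * v10 + wc * v11);
    }
  }
  return out;
}

// Local maxima of `x` above `floor_value`, greedily thinned so surviving
// peaks are mutually >= min_dist apart; returned sorted by decreasing value
// as a matrix with columns (row, col, value), 1-based indices.
// [[Rcpp::export]]
NumericMatrix cpp_peak_local_max(const NumericMatrix& x, double min_dist,
                                 double floor_value) {
  const int nr = x.nrow(), nc = x.ncol();
  std::vector<int> rows, cols;
  std::vector<double> vals;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = x(r, c);
      if (v <= floor_value) continue;
      bool ismax = true;
      for (int dc = -1; dc <= 1 && ismax; ++dc)
        for (int dr = -1; dr <= 1; ++dr) {
          if (!dr && !dc) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          double u = x(rr, cc);
          // strict on earlier raster neighbours breaks plateau ties
          if (u > v || (u == v && (cc * nr + rr) < (c * nr + r))) { ismax = false; break; }
        }
      if (ismax) { rows.push_back(r); cols.push_back(c); vals.push_back(v); }
    }
  }
  std::vector<size_t> ord(vals.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](size_t a, size_t b) { return vals[a] > vals[b]; });
  std::vector<size_t> keep;
  const double d2 = min_dist * min_dist;
  for (size_t i = 0; i < ord.size(); ++i) {
    size_t k = ord[i];
    bool ok = true;
    for (size_t j = 0; j < keep.size(); ++j) {
      double dr = rows[k] - rows[keep[j]], dc = cols[k] - cols[keep[j]];
      if (dr * dr + dc * dc < d2) { ok = false; break; }
    }
    if (ok) keep.push_back(k);
  }
  NumericMatrix out(keep.size(), 3);
  for (size_t i = 0; i < keep.size(); ++i) {
    out(i, 0) = rows[keep[i]] + 1;
    out(i, 1) = cols[keep[i]] + 1;
    out(i, 2) = vals[keep[i]];
  }
  colnames(out) = CharacterVector::create("row", "col", "value");
  return out;
}
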