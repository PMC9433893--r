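// Beamforming and filtering kernels.
//
// Conventions: rf is [axial sample x element]; image grids are
// [axial row x lateral column]; pixel (i, j) sits at depth i * dz (mm,
// 0-based) and lateral position lat_x[j] (mm). Delays are one-way
// (receive-only), appropriate for photoacoustic acquisition where the
// acoustic wave travels from the absorber to the array once.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double interp_sample(const double* col, int n, double tau) {
  // Catmull-Rom cubic interpolation at fractional sample index tau
  // (0-based); linear at the array ends; out-of-range samples contribute
  // nothing. Cubic interpolation keeps delayed channels coherent even when
  // the pulse is sampled at only a few samples per cycle.
  if (tau < 0.0) return 0.0;
  int i0 = static_cast<int>(std::floor(tau));
  if (i0 >= n - 1) return 0.0;
  double w = tau - i0;
  if (i0 < 1 || i0 >= n - 2)
    return col[i0] * (1.0 - w) + col[i0 + 1] * w;
  double p0 = col[i0 - 1], p1 = col[i0], p2 = col[i0 + 1], p3 = col[i0 + 2];
  return p1 + 0.5 * w * (p2 - p0 +
         w * (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3 +
         w * (3.0 * (p1 - p2) + p3 - p0)));
}

// Delayed channel data for one lateral image line: D[i + e * n_rows] is the
// rf of element e evaluated at the one-way travel time from pixel row i.
static void delay_line(const NumericMatrix& rf, const NumericVector& elem_x,
                       double fs, double c_mm_us, double dz, double lx,
                       int n_rows, std::vector<double>& D) {
  const int n_el = rf.ncol(), n_s = rf.nrow();
  for (int e = 0; e < n_el; ++e) {
    const double* col = &rf(0, e);
    const double dx = lx - elem_x[e];
    double* out = &D[static_cast<size_t>(e) * n_rows];
    for (int i = 0; i < n_rows; ++i) {
      double z = i * dz;
      double tau = std::sqrt(z * z + dx * dx) / c_mm_us * fs;
      out[i] = interp_sample(col, n_s, tau);
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_das_rf(NumericMatrix rf, NumericVector elem_x,
                         NumericVector lat_x, double fs, double c_mm_us,
                         double dz, int n_rows) {
  const int n_el = rf.ncol(), n_lat = lat_x.size();
  NumericMatrix img(n_rows, n_lat);
  std::vector<double> D(static_cast<size_t>(n_rows) * n_el);
  for (int j = 0; j < n_lat; ++j) {
    delay_line(rf, elem_x, fs, c_mm_us, dz, lat_x[j], n_rows, D);
    for (int e = 0; e < n_el; ++e) {
      const double* col = &D[static_cast<size_t>(e) * n_rows];
      for (int i = 0; i < n_rows; ++i) img(i, j) += col[i];
    }
  }
  return img;
}

// Short-lag spatial coherence image. For each pixel, the normalized
// cross-correlation of delayed channel pairs at lag m (averaged over the
// available pairs, correlation window of 2 * half_kernel + 1 axial rows,
// clipped at the borders) is combined across lags with the supplied weights.
// With unit weights and normalize = FALSE this is the plain SLSC sum over
// lags 1..M; with normalize = TRUE the output is divided by sum(weights) so
// a perfectly coherent target maps to 1.
// [[Rcpp::export]]
NumericMatrix cpp_slsc(NumericMatrix rf, NumericVector elem_x,
                       NumericVector lat_x, double fs, double c_mm_us,
                       double dz, int n_rows, NumericVector weights,
                       int half_kernel, bool normalize, bool clip_negative) {
  const int n_el = rf.ncol(), n_lat = lat_x.size();
  const int M = weights.size();
  const double eps = 1e-300;
  double wsum = 0.0;
  for (int m = 0; m < M; ++m) wsum += weights[m];

  NumericMatrix img(n_rows, n_lat);
  std::vector<double> D(static_cast<size_t>(n_rows) * n_el);
  // prefix sums over rows: P2 for squares per element, Pm per pair
  std::vector<double> P2(static_cast<size_t>(n_rows + 1) * n_el);
  std::vector<double> Pm(n_rows + 1);
  std::vector<double> acc(n_rows), cnt(n_rows);

  for (int j = 0; j < n_lat; ++j) {
    delay_line(rf, elem_x, fs, c_mm_us, dz, lat_x[j], n_rows, D);
    for (int e = 0; e < n_el; ++e) {
      const double* col = &D[static_cast<size_t>(e) * n_rows];
      double* p = &P2[static_cast<size_t>(e) * (n_rows + 1)];
      p[0] = 0.0;
      for (int i = 0; i < n_rows; ++i) p[i + 1] = p[i] + col[i] * col[i];
    }
    for (int m = 1; m <= M; ++m) {
      std::fill(acc.begin(), acc.end(), 0.0);
      std::fill(cnt.begin(), cnt.end(), 0.0);
      for (int e = 0; e + m < n_el; ++e) {
        const double* a = &D[static_cast<size_t>(e) * n_rows];
        const double* b = &D[static_cast<size_t>(e + m) * n_rows];
        const double* pa = &P2[static_cast<size_t>(e) * (n_rows + 1)];
        const double* pb = &P2[static_cast<size_t>(e + m) * (n_rows + 1)];
        Pm[0] = 0.0;
        for (int i = 0; i < n_rows; ++i) Pm[i + 1] = Pm[i] + a[i] * b[i];
        for (int i = 0; i < n_rows; ++i) {
          int lo = i - half_kernel;
          if (lo < 0) lo = 0;
          int hi = i + half_kernel;
          if (hi > n_rows - 1) hi = n_rows - 1;
          double d1 = pa[hi + 1] - pa[lo];
          double d2 = pb[hi + 1] - pb[lo];
          if (d1 > eps && d2 > eps) {
            // sqrt separately: the product of two representable energies
            // can underflow for near-silent windows
            double c = (Pm[hi + 1] - Pm[lo]) / (std::sqrt(d1) * std::sqrt(d2));
            if (clip_negative && c < 0.0) c = 0.0;
            acc[i] += c;
            cnt[i] += 1.0;
          }
        }
      }
      const double w = weights[m - 1];
      for (int i = 0; i < n_rows; ++i)
        if (cnt[i] > 0.0) img(i, j) += w * acc[i] / cnt[i];
    }
    if (normalize && wsum > 0.0)
      for (int i = 0; i < n_rows; ++i) img(i, j) /= wsum;
  }
  return img;
}

// Median filter over a 3-D tensor [ni x nj x nf] with an odd-sized
// (ka x kl x kf) kernel, clipped (shrinking) windows at the borders, and
// NA-skipping: NA voxels are excluded from the window; a window with no
// finite values yields NA.
// [[Rcpp::export]]
NumericVector cpp_median3(NumericVector a, int ni, int nj, int nf,
                          int ka, int kl, int kf) {
  const int ha = ka / 2, hl = kl / 2, hf = kf / 2;
  NumericVector out(a.size());
  std::vector<double> buf;
  buf.reserve(static_cast<size_t>(ka) * kl * kf);
  for (int f = 0; f < nf; ++f) {
    int f0 = std::max(0, f - hf), f1 = std::min(nf - 1, f + hf);
    for (int j = 0; j < nj; ++j) {
      int j0 = std::max(0, j - hl), j1 = std::min(nj - 1, j + hl);
      for (int i = 0; i < ni; ++i) {
        int i0 = std::max(0, i - ha), i1 = std::min(ni - 1, i + ha);
        buf.clear();
        for (int ff = f0; ff <= f1; ++ff)
          for (int jj = j0; jj <= j1; ++jj) {
            const double* col =
                &a[0] + static_cast<size_t>(ff) * ni * nj +
                static_cast<size_t>(jj) * ni;
            for (int ii = i0; ii <= i1; ++ii)
              if (!ISNAN(col[ii])) buf.push_back(col[ii]);
          }
        double med;
        if (buf.empty()) {
          med = NA_REAL;
        } else {
          size_t n = buf.size(), mid = n / 2;
          std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
          med = buf[mid];
          if (n % 2 == 0) {
            double lo = *std::max_element(buf.begin(), buf.begin() + mid);
            med = 0.5 * (med + lo);
          }
        }
        out[static_cast<size_t>(f) * ni * nj + static_cast<size_t>(j) * ni +
            i] = med;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ni, nj, nf);
  return out;
}
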