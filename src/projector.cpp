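#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Parallel-beam geometry, pixel pitch = detector bin pitch = 1.
// Image is an N x N matrix indexed (row t1, col t2), 0-based; physical
// coordinates x = col - c, y = row - c with c = (N-1)/2, so the grid occupies
// [-N/2, N/2]^2. A ray at angle theta (radians, CCW from +x) and detector
// coordinate s runs along v = (-sin, cos) through the point s * (cos, sin):
// the detector axis is u = (cos, sin) and y_r integrates the image along v
// with exact pixel intersection lengths (Siddon traversal).

struct RaySeg {
  int idx;      // column-major linear pixel index (row + N*col)
  double len;   // intersection length
};

// Siddon traversal of one ray; appends (pixel, length) pairs to out.
static void ray_weights(double theta, double s, int N,
                        std::vector<RaySeg> &out) {
  const double half = N / 2.0;
  const double ux = std::cos(theta), uy = std::sin(theta);
  const double vx = -uy, vy = ux;
  const double px = s * ux, py = s * uy;
  const double eps = 1e-12;

  // clip the infinite line to the grid bounding box
  double t0 = -1e30, t1 = 1e30;
  if (std::fabs(vx) < eps) {
    if (px <= -half || px >= half) return;
  } else {
    double ta = (-half - px) / vx, tb = (half - px) / vx;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta); t1 = std::min(t1, tb);
  }
  if (std::fabs(vy) < eps) {
    if (py <= -half || py >= half) return;
  } else {
    double ta = (-half - py) / vy, tb = (half - py) / vy;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta); t1 = std::min(t1, tb);
  }
  if (t1 <= t0 + eps) return;

  double t = t0;
  // parameter of the next x- and y-plane crossing after t0
  double tx = 1e30, ty = 1e30, dtx = 0.0, dty = 0.0;
  if (std::fabs(vx) >= eps) {
    dtx = 1.0 / std::fabs(vx);
    double xi = px + t * vx + half;              // in [0, N]
    double m = (vx > 0) ? std::floor(xi + 1e-9) + 1.0
                        : std::ceil(xi - 1e-9) - 1.0;
    tx = (m - half - px) / vx;
  }
  if (std::fabs(vy) >= eps) {
    dty = 1.0 / std::fabs(vy);
    double yi = py + t * vy + half;
    double m = (vy > 0) ? std::floor(yi + 1e-9) + 1.0
                        : std::ceil(yi - 1e-9) - 1.0;
    ty = (m - half - py) / vy;
  }

  while (t < t1 - eps) {
    double tn = std::min(std::min(tx, ty), t1);
    double tm = 0.5 * (t + tn);
    int col = (int)std::floor(px + tm * vx + half);
    int row = (int)std::floor(py + tm * vy + half);
    double len = tn - t;
    if (len > eps && col >= 0 && col < N && row >= 0 && row < N) {
      RaySeg seg; seg.idx = row + N * col; seg.len = len;
      out.push_back(seg);
    }
    if (tn >= t1 - eps) break;
    if (tx <= tn + eps) tx += dtx;
    if (ty <= tn + eps) ty += dty;
    t = tn;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_radon(NumericMatrix img, NumericVector thetas, int n_bins) {
  int N = img.nrow();
  int n_ang = thetas.size();
  NumericMatrix sino(n_ang, n_bins);
  std::vector<RaySeg> segs;
  double c_det = (n_bins - 1) / 2.0;
  for (int a = 0; a < n_ang; ++a) {
    for (int b = 0; b < n_bins; ++b) {
      segs.clear();
      ray_weights(thetas[a], b - c_det, N, segs);
      double acc = 0.0;
      for (size_t k = 0; k < segs.size(); ++k)
        acc += segs[k].len * img[segs[k].idx];
      sino(a, b) = acc;
    }
  }
  return sino;
}

// exact adjoint of cpp_radon (same weights, transposed)
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix sino, NumericVector thetas, int N) {
  int n_ang = sino.nrow(), n_bins = sino.ncol();
  NumericMatrix img(N, N);
  std::vector<RaySeg> segs;
  double c_det = (n_bins - 1) / 2.0;
  for (int a = 0; a < n_ang; ++a) {
    for (int b = 0; b < n_bins; ++b) {
      double y = sino(a, b);
      if (y == 0.0) continue;
      segs.clear();
      ray_weights(thetas[a], b - c_det, N, segs);
      for (size_t k = 0; k < segs.size(); ++k)
        img[segs[k].idx] += segs[k].len * y;
    }
  }
  return img;
}

// pixel-driven backprojection with linear interpolation along the detector,
// used by FBP (smoother than the unmatched Siddon adjoint)
// [[Rcpp::export]]
NumericMatrix cpp_backproject_interp(NumericMatrix sino, NumericVector thetas,
                                     int N) {
  int n_ang = sino.nrow(), n_bins = sino.ncol();
  NumericMatrix img(N, N);
  double c = (N - 1) / 2.0, c_det = (n_bins - 1) / 2.0;
  for (int a = 0; a < n_ang; ++a) {
    double ct = std::cos(thetas[a]), st = std::sin(thetas[a]);
    for (int col = 0; col < N; ++col) {
      double x = col - c;
      for (int row = 0; row < N; ++row) {
        double y = row - c;
        double s = x * ct + y * st + c_det;
        int b0 = (int)std::floor(s);
        double w = s - b0;
        double val = 0.0;
        if (b0 >= 0 && b0 < n_bins) val += (1.0 - w) * sino(a, b0);
        if (b0 + 1 >= 0 && b0 + 1 < n_bins) val += w * sino(a, b0 + 1);
        img(row, col) += val;
      }
    }
  }
  return img;
}

// One full ART (Kaczmarz) sweep over the rays listed in `order` (0-based
// linear ray index r = angle * n_bins + bin). Zero-norm rows are skipped.
// [[Rcpp::export]]
NumericMatrix cpp_art_sweep(NumericMatrix x, NumericMatrix sino,
                            NumericVector thetas, IntegerVector order,
                            double lambda) {
  int N = x.nrow();
  int n_bins = sino.ncol();
  NumericMatrix out = clone(x);
  std::vector<RaySeg> segs;
  double c_det = (n_bins - 1) / 2.0;
  for (int q = 0; q < order.size(); ++q) {
    int r = order[q];
    int a = r / n_bins, b = r % n_bins;
    segs.clear();
    ray_weights(thetas[a], b - c_det, N, segs);
    double dot = 0.0, nrm2 = 0.0;
    for (size_t k = 0; k < segs.size(); ++k) {
      dot += segs[k].len * out[segs[k].idx];
      nrm2 += segs[k].len * segs[k].len;
    }
    if (nrm2 <= 0.0) continue;
    double corr = lambda * (sino(a, b) - dot) / nrm2;
    for (size_t k = 0; k < segs.size(); ++k)
      out[segs[k].idx] += corr * segs[k].len;
  }
  return out;
}

// separable Gaussian blur with reflected boundary (scale-space building block)
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int r = (int)std::ceil(3.5 * sigma);
  std::vector<double> w(2 * r + 1);
  double s2 = 2.0 * sigma * sigma, tot = 0.0;
  for (int k = -r; k <= r; ++k) { w[k + r] = std::exp(-k * k / s2); tot += w[k + r]; }
  for (int k = 0; k <= 2 * r; ++k) w[k] /= tot;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = -r; k <= r; ++k) {
        int ii = i + k;
        if (ii < 0) ii = -ii - 1;
        if (ii >= nr) ii = 2 * nr - ii - 1;
        if (ii < 0) ii = 0; if (ii >= nr) ii = nr - 1;
        acc += w[k + r] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  // along columns (horizontal)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = -r; k <= r; ++k) {
        int jj = j + k;
        if (jj < 0) jj = -jj - 1;
        if (jj >= nc) jj = 2 * nc - jj - 1;
        if (jj < 0) jj = 0; if (jj >= nc) jj = nc - 1;
        acc += w[k + r] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  return out;
}

// bilinear resampling: out(row,col) = img at (xs, ys) (0-based coords),
// zero outside the field of view
// [[Rcpp::export]]
NumericMatrix cpp_bilinear_sample(NumericMatrix img, NumericMatrix xs,
                                  NumericMatrix ys) {
  int nr = xs.nrow(), nc = xs.ncol();
  int mr = img.nrow(), mc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double x = xs(i, j), y = ys(i, j);
      int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
      double fx = x - x0, fy = y - y0;
      double acc = 0.0;
      for (int dy = 0; dy <= 1; ++dy)
        for (int dx = 0; dx <= 1; ++dx) {
          int xx = x0 + dx, yy = y0 + dy;
          if (xx < 0 || xx >= mc || yy < 0 || yy >= mr) continue;
          double wgt = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy);
          acc += wgt * img(yy, xx);
        }
      out(i, j) = acc;
    }
  return out;
}
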