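// Compiled kernels for the localization pipeline.
//
// Pixel convention (used package-wide): pixel i (0-based) spans [i, i+1) in
// continuous pixel coordinates, so its center sits at i + 0.5.  The PSF is a
// pixel-integrated 2D Gaussian: the expected photon count in pixel (i, j) of
// a ROI is  mu = I * dEx(i) * dEy(j) + bg  with dE the difference of Gaussian
// CDFs across the pixel edges.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double INV_SQRT2 = 0.7071067811865475244;
static const double INV_SQRT2PI = 0.3989422804014326779;

// integral of a unit 1D Gaussian centered at x (sd sigma) over [i, i+1)
static inline double dE(int i, double x, double sigma) {
  double a = (i - x) * INV_SQRT2 / sigma;
  double b = (i + 1 - x) * INV_SQRT2 / sigma;
  return 0.5 * (std::erf(b) - std::erf(a));
}

// d(dE)/dx and d2(dE)/dx2
static inline double dE_dx(int i, double x, double sigma) {
  double u0 = (i - x) / sigma, u1 = (i + 1 - x) / sigma;
  return INV_SQRT2PI / sigma *
         (std::exp(-0.5 * u0 * u0) - std::exp(-0.5 * u1 * u1));
}
static inline double dE_dx2(int i, double x, double sigma) {
  double u0 = (i - x) / sigma, u1 = (i + 1 - x) / sigma;
  return INV_SQRT2PI / (sigma * sigma) *
         (u0 * std::exp(-0.5 * u0 * u0) - u1 * std::exp(-0.5 * u1 * u1));
}

// Expected ROI model for parameter matrix theta (N x 4: x, y, I, bg).
// Returns (n*n) x N matrix, pixel (i, j) at row i + n*j (x fastest).
// [[Rcpp::export]]
NumericMatrix cpp_roi_mu(NumericMatrix theta, double sigma, int n) {
  int N = theta.nrow();
  NumericMatrix mu(n * n, N);
  for (int k = 0; k < N; ++k) {
    double x = theta(k, 0), y = theta(k, 1), I = theta(k, 2), bg = theta(k, 3);
    std::vector<double> Ex(n), Ey(n);
    for (int i = 0; i < n; ++i) { Ex[i] = dE(i, x, sigma); Ey[i] = dE(i, y, sigma); }
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        mu(i + n * j, k) = I * Ex[i] * Ey[j] + bg;
  }
  return mu;
}

// Per-parameter Newton-Raphson MLE for the 4-parameter model on one ROI.
// rois: (n*n) x N photon counts.  Returns N x 7:
// x, y, I, bg, logL, iterations, converged.
// [[Rcpp::export]]
NumericMatrix cpp_fit_rois(NumericMatrix rois, double sigma, int n,
                           int max_iter, double tol_xy, double tol_photon) {
  int N = rois.ncol();
  if (rois.nrow() != n * n) stop("ROI rows must equal n*n");
  NumericMatrix out(N, 7);
  std::vector<double> Ex(n), Ey(n), dExv(n), dEyv(n), d2Ex(n), d2Ey(n);

  for (int k = 0; k < N; ++k) {
    // initialization: photon-weighted centroid; bg from min; I from excess
    double tot = 0.0, mn = R_PosInf, cx = 0.0, cy = 0.0;
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        double d = rois(i + n * j, k);
        tot += d;
        if (d < mn) mn = d;
        cx += d * (i + 0.5);
        cy += d * (j + 0.5);
      }
    double x, y, I, bg;
    bg = std::max(mn, 1e-6);
    I = std::max(tot - n * n * bg, 1.0);
    if (tot > 0) { cx /= tot; cy /= tot; } else { cx = n / 2.0; cy = n / 2.0; }
    x = cx; y = cy;
    if (tot <= 0.0) {  // all-zero ROI: degenerate fit
      out(k, 0) = n / 2.0; out(k, 1) = n / 2.0; out(k, 2) = 0.0; out(k, 3) = 0.0;
      out(k, 4) = 0.0; out(k, 5) = 0; out(k, 6) = 1;
      continue;
    }

    int it = 0;
    bool conv = false;
    for (it = 1; it <= max_iter; ++it) {
      double dx_step = 0, dy_step = 0, dI_step = 0, dbg_step = 0;
      for (int p = 0; p < 4; ++p) {
        for (int i = 0; i < n; ++i) {
          Ex[i] = dE(i, x, sigma);   Ey[i] = dE(i, y, sigma);
          dExv[i] = dE_dx(i, x, sigma); dEyv[i] = dE_dx(i, y, sigma);
          d2Ex[i] = dE_dx2(i, x, sigma); d2Ey[i] = dE_dx2(i, y, sigma);
        }
        double g = 0.0, h = 0.0;  // dL/dtheta, d2L/dtheta2
        for (int j = 0; j < n; ++j)
          for (int i = 0; i < n; ++i) {
            double d = rois(i + n * j, k);
            double mu = I * Ex[i] * Ey[j] + bg;
            if (mu < 1e-12) mu = 1e-12;
            double dmu, d2mu;
            switch (p) {
              case 0: dmu = I * dExv[i] * Ey[j]; d2mu = I * d2Ex[i] * Ey[j]; break;
              case 1: dmu = I * Ex[i] * dEyv[j]; d2mu = I * Ex[i] * d2Ey[j]; break;
              case 2: dmu = Ex[i] * Ey[j];       d2mu = 0.0; break;
              default: dmu = 1.0;                d2mu = 0.0; break;
            }
            double r = d / mu - 1.0;
            g += r * dmu;
            h += r * d2mu - d * dmu * dmu / (mu * mu);
          }
        double step = (h < -1e-12) ? (g / h) : 0.0;  // Newton toward maximum
        switch (p) {
          case 0:
            if (step > 1.0) step = 1.0; else if (step < -1.0) step = -1.0;
            x -= step; if (x < 0) x = 0; if (x > n) x = n;
            dx_step = std::fabs(step); break;
          case 1:
            if (step > 1.0) step = 1.0; else if (step < -1.0) step = -1.0;
            y -= step; if (y < 0) y = 0; if (y > n) y = n;
            dy_step = std::fabs(step); break;
          case 2:
            I -= step; if (I < 1e-6) I = 1e-6;
            dI_step = std::fabs(step); break;
          default:
            bg -= step; if (bg < 1e-8) bg = 1e-8;
            dbg_step = std::fabs(step); break;
        }
      }
      if (dx_step < tol_xy && dy_step < tol_xy &&
          dI_step < tol_photon && dbg_step < tol_photon) { conv = true; break; }
    }

    // log-likelihood at optimum (up to the data-only lgamma constant)
    double ll = 0.0;
    for (int i = 0; i < n; ++i) { Ex[i] = dE(i, x, sigma); Ey[i] = dE(i, y, sigma); }
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        double d = rois(i + n * j, k);
        double mu = I * Ex[i] * Ey[j] + bg;
        if (mu < 1e-12) mu = 1e-12;
        ll += d * std::log(mu) - mu;
      }
    out(k, 0) = x; out(k, 1) = y; out(k, 2) = I; out(k, 3) = bg;
    out(k, 4) = ll; out(k, 5) = it > max_iter ? max_iter : it;
    out(k, 6) = conv ? 1 : 0;
  }
  colnames(out) = CharacterVector::create("x", "y", "I", "bg", "logL",
                                          "iterations", "converged");
  return out;
}

// CRLB standard deviations from the Fisher information of the Poisson model.
// theta: N x 4 (x, y, I, bg).  Returns N x 5: sd_x, sd_y, sd_I, sd_bg (pixel /
// photon units) and a singularity flag.
// [[Rcpp::export]]
NumericMatrix cpp_crlb(NumericMatrix theta, double sigma, int n) {
  int N = theta.nrow();
  NumericMatrix out(N, 5);
  for (int k = 0; k < N; ++k) {
    double x = theta(k, 0), y = theta(k, 1), I = theta(k, 2), bg = theta(k, 3);
    arma::mat F(4, 4, arma::fill::zeros);
    std::vector<double> Ex(n), Ey(n), dExv(n), dEyv(n);
    for (int i = 0; i < n; ++i) {
      Ex[i] = dE(i, x, sigma);   Ey[i] = dE(i, y, sigma);
      dExv[i] = dE_dx(i, x, sigma); dEyv[i] = dE_dx(i, y, sigma);
    }
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        double mu = I * Ex[i] * Ey[j] + bg;
        if (mu < 1e-12) mu = 1e-12;
        arma::vec d(4);
        d(0) = I * dExv[i] * Ey[j];
        d(1) = I * Ex[i] * dEyv[j];
        d(2) = Ex[i] * Ey[j];
        d(3) = 1.0;
        F += d * d.t() / mu;
      }
    arma::mat C;
    bool ok = arma::inv_sympd(C, F);
    if (!ok) ok = arma::inv(C, F);
    if (ok && C(0, 0) > 0 && C(1, 1) > 0 && C(2, 2) > 0 && C(3, 3) > 0) {
      out(k, 0) = std::sqrt(C(0, 0));
      out(k, 1) = std::sqrt(C(1, 1));
      out(k, 2) = std::sqrt(C(2, 2));
      out(k, 3) = std::sqrt(C(3, 3));
      out(k, 4) = 0;
    } else {
      out(k, 0) = NA_REAL; out(k, 1) = NA_REAL;
      out(k, 2) = NA_REAL; out(k, 3) = NA_REAL;
      out(k, 4) = 1;
    }
  }
  colnames(out) = CharacterVector::create("sd_x", "sd_y", "sd_I", "sd_bg",
                                          "singular");
  return out;
}

// Candidate detection: difference of two separable boxcar smoothings
// (radii r1 < r2), strict local maxima in a (2*rmax+1)^2 neighborhood above
// `threshold`, merged within `min_sep` pixels (brighter wins), and at least
// `margin` pixels from every border.  img: nx x ny matrix (x = row, 0-based
// coordinates returned).  Returns k x 3: ix, iy, value.
// [[Rcpp::export]]
NumericMatrix cpp_find_candidates(NumericMatrix img, double threshold,
                                  int r1, int r2, int rmax, int min_sep,
                                  int margin) {
  int nx = img.nrow(), ny = img.ncol();
  auto boxsmooth = [&](const NumericMatrix& src, int r) {
    NumericMatrix tmp(nx, ny), dst(nx, ny);
    double w = 2 * r + 1;
    for (int j = 0; j < ny; ++j) {  // along x with edge clamping
      for (int i = 0; i < nx; ++i) {
        double s = 0.0;
        for (int u = i - r; u <= i + r; ++u) {
          int uu = u < 0 ? 0 : (u >= nx ? nx - 1 : u);
          s += src(uu, j);
        }
        tmp(i, j) = s / w;
      }
    }
    for (int i = 0; i < nx; ++i) {  // along y
      for (int j = 0; j < ny; ++j) {
        double s = 0.0;
        for (int u = j - r; u <= j + r; ++u) {
          int uu = u < 0 ? 0 : (u >= ny ? ny - 1 : u);
          s += tmp(i, uu);
        }
        dst(i, j) = s / w;
      }
    }
    return dst;
  };
  NumericMatrix f1 = boxsmooth(img, r1);
  NumericMatrix f2 = boxsmooth(img, r2);

  std::vector<int> xs, ys;
  std::vector<double> vs;
  for (int j = margin; j < ny - margin; ++j)
    for (int i = margin; i < nx - margin; ++i) {
      double v = f1(i, j) - f2(i, j);
      if (v < threshold) continue;
      bool ismax = true;
      for (int dj = -rmax; dj <= rmax && ismax; ++dj)
        for (int di = -rmax; di <= rmax; ++di) {
          if (di == 0 && dj == 0) continue;
          int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
          double w = f1(ii, jj) - f2(ii, jj);
          if (w > v || (w == v && (dj < 0 || (dj == 0 && di < 0)))) {
            ismax = false; break;
          }
        }
      if (ismax) { xs.push_back(i); ys.push_back(j); vs.push_back(v); }
    }

  // merge near-duplicates, keep the brighter
  int m = xs.size();
  std::vector<bool> keep(m, true);
  for (int a = 0; a < m; ++a)
    for (int b = a + 1; b < m; ++b) {
      if (!keep[a] || !keep[b]) continue;
      if (std::abs(xs[a] - xs[b]) <= min_sep &&
          std::abs(ys[a] - ys[b]) <= min_sep) {
        if (vs[a] >= vs[b]) keep[b] = false; else keep[a] = false;
      }
    }
  int cnt = 0;
  for (int a = 0; a < m; ++a) if (keep[a]) ++cnt;
  NumericMatrix out(cnt, 3);
  int r = 0;
  for (int a = 0; a < m; ++a)
    if (keep[a]) { out(r, 0) = xs[a]; out(r, 1) = ys[a]; out(r, 2) = vs[a]; ++r; }
  colnames(out) = CharacterVector::create("ix", "iy", "value");
  return out;
}

// Expected (noise-free) photon image for one frame: sum of pixel-integrated
// Gaussians plus uniform background.  Positions in continuous pixel units.
// [[Rcpp::export]]
NumericMatrix cpp_expected_frame(int nx, int ny, NumericVector x,
                                 NumericVector y, NumericVector photons,
                                 double bg, double sigma) {
  NumericMatrix img(nx, ny);
  std::fill(img.begin(), img.end(), bg);
  int win = (int)std::ceil(5.0 * sigma) + 1;
  for (int k = 0; k < x.size(); ++k) {
    int cx = (int)std::floor(x[k]), cy = (int)std::floor(y[k]);
    int i0 = std::max(0, cx - win), i1 = std::min(nx - 1, cx + win);
    int j0 = std::max(0, cy - win), j1 = std::min(ny - 1, cy + win);
    if (i0 > i1 || j0 > j1) continue;  // far outside: ignore
    for (int i = i0; i <= i1; ++i) {
      double ex = dE(i, x[k], sigma) * photons[k];
      if (ex == 0.0) continue;
      for (int j = j0; j <= j1; ++j) img(i, j) += ex * dE(j, y[k], sigma);
    }
  }
  return img;
}

// Sum of unit-integral 2D Gaussians on the SR grid, truncated at 4 sigma.
// Positions and sigmas in SR pixel units.
// [[Rcpp::export]]
NumericMatrix cpp_render_sr(int nx, int ny, NumericVector x, NumericVector y,
                            NumericVector sx, NumericVector sy) {
  NumericMatrix img(nx, ny);
  for (int k = 0; k < x.size(); ++k) {
    int wx = (int)std::ceil(4.0 * sx[k]) + 1;
    int wy = (int)std::ceil(4.0 * sy[k]) + 1;
    int cx = (int)std::floor(x[k]), cy = (int)std::floor(y[k]);
    int i0 = std::max(0, cx - wx), i1 = std::min(nx - 1, cx + wx);
    int j0 = std::max(0, cy - wy), j1 = std::min(ny - 1, cy + wy);
    for (int i = i0; i <= i1; ++i) {
      double ex = dE(i, x[k], sx[k]);
      if (ex == 0.0) continue;
      for (int j = j0; j <= j1; ++j) img(i, j) += ex * dE(j, y[k], sy[k]);
    }
  }
  return img;
}
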