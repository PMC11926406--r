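#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate Gaussian ministack densities onto a (nz, ny, nx) grid stored
// column-major in (z, y, x) order (index = z + nz*y + nz*ny*x).
//
// Each ministack k contributes, at physical point p,
//   exp(-perp^2 / (2 sr^2)) * exp(-(t - mu)^2 / (2 sa^2))
// where t is the coordinate of p - center_k along the stack's local
// (cis->trans) axis and perp the distance from that axis.  Evaluation is
// restricted to a conservative bounding box around each stack's density
// mass (4 sigma), which keeps the cost proportional to occupied volume.
// [[Rcpp::export]]
NumericVector cpp_splat_density(IntegerVector dims, NumericVector spacing,
                                NumericMatrix centers, NumericMatrix axes,
                                double axial_mu, double axial_sigma,
                                double stack_radius) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  NumericVector out(static_cast<R_xlen_t>(nz) * ny * nx);
  const double inv2sa = 1.0 / (2.0 * axial_sigma * axial_sigma);
  const double inv2sr = 1.0 / (2.0 * stack_radius * stack_radius);
  const double half = 4.0 * std::max(axial_sigma, stack_radius);

  for (int k = 0; k < centers.nrow(); ++k) {
    const double az = axes(k, 0), ay = axes(k, 1), ax = axes(k, 2);
    // center of the enzyme's density along the local axis
    const double cz = centers(k, 0) + axial_mu * az;
    const double cy = centers(k, 1) + axial_mu * ay;
    const double cx = centers(k, 2) + axial_mu * ax;
    const int z0 = std::max(0, (int)std::floor((cz - half) / dz));
    const int z1 = std::min(nz - 1, (int)std::ceil((cz + half) / dz));
    const int y0 = std::max(0, (int)std::floor((cy - half) / dy));
    const int y1 = std::min(ny - 1, (int)std::ceil((cy + half) / dy));
    const int x0 = std::max(0, (int)std::floor((cx - half) / dx));
    const int x1 = std::min(nx - 1, (int)std::ceil((cx + half) / dx));
    const double oz = centers(k, 0), oy = centers(k, 1), ox = centers(k, 2);
    for (int x = x0; x <= x1; ++x) {
      const double rx = x * dx - ox;
      for (int y = y0; y <= y1; ++y) {
        const double ry = y * dy - oy;
        const R_xlen_t base = static_cast<R_xlen_t>(nz) * (y + static_cast<R_xlen_t>(ny) * x);
        for (int z = z0; z <= z1; ++z) {
          const double rz = z * dz - oz;
          const double t = rz * az + ry * ay + rx * ax;
          const double perp2 = rz * rz + ry * ry + rx * rx - t * t;
          const double dt = t - axial_mu;
          out[base + z] += std::exp(-(perp2 * inv2sr) - dt * dt * inv2sa);
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

static void blur_axis(std::vector<double>& buf, std::vector<double>& tmp,
                      int n_along, R_xlen_t stride, R_xlen_t n_lines,
                      R_xlen_t line_stride_outer, int outer_per_line,
                      const std::vector<double>& kern) {
  // generic 1D convolution along one axis; zero padding at borders
  const int kh = (int)(kern.size() - 1) / 2;
  for (R_xlen_t line = 0; line < n_lines; ++line) {
    // compute the base offset of this line: lines are enumerated over the
    // two remaining axes via outer_per_line (inner count) decomposition
    R_xlen_t inner = line % outer_per_line;
    R_xlen_t outer = line / outer_per_line;
    R_xlen_t base = inner * ((stride == 1) ? (R_xlen_t)n_along : 1) + outer * line_stride_outer;
    for (int i = 0; i < n_along; ++i) tmp[i] = buf[base + (R_xlen_t)i * stride];
    for (int i = 0; i < n_along; ++i) {
      double acc = 0.0;
      const int j0 = std::max(0, i - kh), j1 = std::min(n_along - 1, i + kh);
      for (int j = j0; j <= j1; ++j) acc += tmp[j] * kern[kh + (i - j)];
      buf[base + (R_xlen_t)i * stride] = acc;
    }
  }
}

// Separable Gaussian blur of a (nz, ny, nx) array; sigmas in voxel units.
// Kernel truncated at 4 sigma and normalized to unit sum, so total image
// mass is preserved away from borders (zero padding outside).
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector img, IntegerVector dims,
                                NumericVector sigma_vox) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<double> buf(img.begin(), img.end());
  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> tmp(nmax);

  for (int axis = 0; axis < 3; ++axis) {
    const double s = sigma_vox[axis];
    if (s <= 0) continue;
    const int kh = std::max(1, (int)std::ceil(4.0 * s));
    std::vector<double> kern(2 * kh + 1);
    double ksum = 0.0;
    for (int i = -kh; i <= kh; ++i) {
      kern[kh + i] = std::exp(-0.5 * (double)i * i / (s * s));
      ksum += kern[kh + i];
    }
    for (double& k : kern) k /= ksum;

    if (axis == 0) {            // along z: stride 1, lines over (y, x)
      blur_axis(buf, tmp, nz, 1, (R_xlen_t)ny * nx, (R_xlen_t)nz * ny, ny, kern);
    } else if (axis == 1) {     // along y: stride nz, lines over (z, x)
      const int khn = kh; (void)khn;
      for (R_xlen_t x = 0; x < nx; ++x) {
        for (R_xlen_t z = 0; z < nz; ++z) {
          R_xlen_t base = z + (R_xlen_t)nz * ny * x;
          for (int i = 0; i < ny; ++i) tmp[i] = buf[base + (R_xlen_t)i * nz];
          for (int i = 0; i < ny; ++i) {
            double acc = 0.0;
            const int j0 = std::max(0, i - kh), j1 = std::min(ny - 1, i + kh);
            for (int j = j0; j <= j1; ++j) acc += tmp[j] * kern[kh + (i - j)];
            buf[base + (R_xlen_t)i * nz] = acc;
          }
        }
      }
    } else {                    // along x: stride nz*ny, lines over (z, y)
      const R_xlen_t st = (R_xlen_t)nz * ny;
      for (R_xlen_t y = 0; y < ny; ++y) {
        for (R_xlen_t z = 0; z < nz; ++z) {
          R_xlen_t base = z + (R_xlen_t)nz * y;
          for (int i = 0; i < nx; ++i) tmp[i] = buf[base + (R_xlen_t)i * st];
          for (int i = 0; i < nx; ++i) {
            double acc = 0.0;
            const int j0 = std::max(0, i - kh), j1 = std::min(nx - 1, i + kh);
            for (int j = j0; j <= j1; ++j) acc += tmp[j] * kern[kh + (i - j)];
            buf[base + (R_xlen_t)i * st] = acc;
          }
        }
      }
    }
  }
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = dims;
  return out;
}

// Poisson shot noise + Gaussian read noise + clamp + digitize, using R's RNG
// (so draws are governed by set.seed on the R side).
// [[Rcpp::export]]
NumericVector cpp_apply_noise(NumericVector lambda, double read_sd, bool shot) {
  const R_xlen_t n = lambda.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = shot ? R::rpois(lambda[i]) : lambda[i];
    if (read_sd > 0) v += R::norm_rand() * read_sd;
    out[i] = std::round(std::max(v, 0.0));
  }
  out.attr("dim") = lambda.attr("dim");
  return out;
}

// Costes threshold scan.  For every occupied intensity level t of channel A
// (descending), with t_b = slope * t + intercept, computes the Pearson
// correlation of the below-threshold voxel set {A <= t AND B <= t_b}
// ("and" mode; "or" uses the union).  A voxel enters the below set once
// t >= e_i where e_i = max(A_i, (B_i - intercept)/slope) (min for "or"),
// so sorting by e gives every candidate's statistics in one sweep.
// Returns candidates (descending), below-set sizes and correlations
// (NaN where undefined: fewer than 2 voxels or no spread in a channel).
// [[Rcpp::export]]
List cpp_costes_scan(NumericVector va, NumericVector vb, double slope,
                     double intercept, bool and_mode) {
  const R_xlen_t n = va.size();
  std::vector<double> e(n), a(n), b(n);
  std::vector<R_xlen_t> ord(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double eb = (vb[i] - intercept) / slope;
    e[i] = and_mode ? std::max(va[i], eb) : std::min(va[i], eb);
    ord[i] = i;
  }
  std::sort(ord.begin(), ord.end(),
            [&](R_xlen_t i, R_xlen_t j) { return e[i] < e[j]; });
  std::vector<double> es(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    es[i] = e[ord[i]];
    a[i] = va[ord[i]];
    b[i] = vb[ord[i]];
  }
  std::vector<double> cand(va.begin(), va.end());
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

  const R_xlen_t k = (R_xlen_t)cand.size();
  NumericVector r_below(k), n_below(k);
  double Sa = 0, Sb = 0, Saa = 0, Sbb = 0, Sab = 0;
  double amin = R_PosInf, amax = R_NegInf, bmin = R_PosInf, bmax = R_NegInf;
  R_xlen_t p = 0;
  for (R_xlen_t c = 0; c < k; ++c) {          // ascending candidates
    const double t = cand[c];
    while (p < n && es[p] <= t) {
      Sa += a[p]; Sb += b[p];
      Saa += a[p] * a[p]; Sbb += b[p] * b[p]; Sab += a[p] * b[p];
      amin = std::min(amin, a[p]); amax = std::max(amax, a[p]);
      bmin = std::min(bmin, b[p]); bmax = std::max(bmax, b[p]);
      ++p;
    }
    n_below[c] = (double)p;
    if (p >= 2 && amax > amin && bmax > bmin) {
      const double var_a = Saa - Sa * Sa / p;
      const double var_b = Sbb - Sb * Sb / p;
      const double cov_ab = Sab - Sa * Sb / p;
      r_below[c] = (var_a > 0 && var_b > 0)
        ? cov_ab / std::sqrt(var_a * var_b) : NA_REAL;
    } else {
      r_below[c] = NA_REAL;
    }
  }
  // emit in descending-candidate order to match the documented scan
  NumericVector cand_out(k), n_out(k), r_out(k);
  for (R_xlen_t c = 0; c < k; ++c) {
    cand_out[c] = cand[k - 1 - c];
    n_out[c] = n_below[k - 1 - c];
    r_out[c] = r_below[k - 1 - c];
  }
  return List::create(_["t_a"] = cand_out, _["n_below"] = n_out,
                      _["r_below"] = r_out);
}
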