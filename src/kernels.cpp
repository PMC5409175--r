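#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Column-major voxel index helpers (0-based i,j,k)
static inline R_xlen_t vidx(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Trilinear sample at continuous 0-based voxel coordinate; fill outside.
static double sample_linear(const double *a, int nx, int ny, int nz,
                            double x, double y, double z, double fill) {
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) return fill;
  // clamp to valid interpolation domain (edge replication within half voxel)
  x = clampd(x, 0.0, nx - 1.0);
  y = clampd(y, 0.0, ny - 1.0);
  z = clampd(z, 0.0, nz - 1.0);
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  if (k0 == nz - 1) k0--;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  if (k0 < 0) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double v000 = a[vidx(i0, j0, k0, nx, ny)];
  double v100 = a[vidx(i0 + 1, j0, k0, nx, ny)];
  double v010 = a[vidx(i0, j0 + 1, k0, nx, ny)];
  double v110 = a[vidx(i0 + 1, j0 + 1, k0, nx, ny)];
  double v001 = a[vidx(i0, j0, k0 + 1, nx, ny)];
  double v101 = a[vidx(i0 + 1, j0, k0 + 1, nx, ny)];
  double v011 = a[vidx(i0, j0 + 1, k0 + 1, nx, ny)];
  double v111 = a[vidx(i0 + 1, j0 + 1, k0 + 1, nx, ny)];
  double c00 = v000 * (1 - fx) + v100 * fx;
  double c10 = v010 * (1 - fx) + v110 * fx;
  double c01 = v001 * (1 - fx) + v101 * fx;
  double c11 = v011 * (1 - fx) + v111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static double sample_nearest(const double *a, int nx, int ny, int nz,
                             double x, double y, double z, double fill) {
  int i = (int)std::floor(x + 0.5), j = (int)std::floor(y + 0.5),
      k = (int)std::floor(z + 0.5);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return fill;
  return a[vidx(i, j, k, nx, ny)];
}

// Resample: output voxel (0-based) -> moving voxel coordinate via 4x4 matrix C.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector mov, IntegerVector mdim,
                                  IntegerVector odim, NumericMatrix C,
                                  int interp, double fill) {
  int mnx = mdim[0], mny = mdim[1], mnz = mdim[2];
  int nx = odim[0], ny = odim[1], nz = odim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double *a = mov.begin();
  double c00 = C(0, 0), c01 = C(0, 1), c02 = C(0, 2), c03 = C(0, 3);
  double c10 = C(1, 0), c11 = C(1, 1), c12 = C(1, 2), c13 = C(1, 3);
  double c20 = C(2, 0), c21 = C(2, 1), c22 = C(2, 2), c23 = C(2, 3);
  R_xlen_t p = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, p++) {
        double x = c00 * i + c01 * j + c02 * k + c03;
        double y = c10 * i + c11 * j + c12 * k + c13;
        double z = c20 * i + c21 * j + c22 * k + c23;
        out[p] = interp == 0 ? sample_linear(a, mnx, mny, mnz, x, y, z, fill)
                             : sample_nearest(a, mnx, mny, mnz, x, y, z, fill);
      }
  return out;
}

// Resample through a dense displacement field on the output grid.
// Output voxel v: world x = Atgt v; sample moving at voxel coord
// Binv (x + u(v)) where u is the displacement (mm, world frame).
// [[Rcpp::export]]
NumericVector resample_field_cpp(NumericVector mov, IntegerVector mdim,
                                 IntegerVector odim, NumericMatrix Atgt,
                                 NumericMatrix Binv, NumericVector ux,
                                 NumericVector uy, NumericVector uz,
                                 int interp, double fill) {
  int mnx = mdim[0], mny = mdim[1], mnz = mdim[2];
  int nx = odim[0], ny = odim[1], nz = odim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double *a = mov.begin();
  R_xlen_t p = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, p++) {
        double wx = Atgt(0, 0) * i + Atgt(0, 1) * j + Atgt(0, 2) * k + Atgt(0, 3) + ux[p];
        double wy = Atgt(1, 0) * i + Atgt(1, 1) * j + Atgt(1, 2) * k + Atgt(1, 3) + uy[p];
        double wz = Atgt(2, 0) * i + Atgt(2, 1) * j + Atgt(2, 2) * k + Atgt(2, 3) + uz[p];
        double x = Binv(0, 0) * wx + Binv(0, 1) * wy + Binv(0, 2) * wz + Binv(0, 3);
        double y = Binv(1, 0) * wx + Binv(1, 1) * wy + Binv(1, 2) * wz + Binv(1, 3);
        double z = Binv(2, 0) * wx + Binv(2, 1) * wy + Binv(2, 2) * wz + Binv(2, 3);
        out[p] = interp == 0 ? sample_linear(a, mnx, mny, mnz, x, y, z, fill)
                             : sample_nearest(a, mnx, mny, mnz, x, y, z, fill);
      }
  return out;
}

// Separable Gaussian smoothing, reflective boundaries; sigma in voxels per axis.
static void smooth_axis(std::vector<double> &a, int nx, int ny, int nz,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * radius + 1);
  double s = 0;
  for (int t = -radius; t <= radius; t++) {
    kern[t + radius] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += kern[t + radius];
  }
  for (auto &v : kern) v /= s;
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  std::vector<double> line(len);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? (R_xlen_t)nx : (R_xlen_t)nx * ny);
  int nOuter1 = axis == 0 ? ny : nx;
  int nOuter2 = axis == 2 ? ny : nz;
  for (int o2 = 0; o2 < nOuter2; o2++)
    for (int o1 = 0; o1 < nOuter1; o1++) {
      R_xlen_t base;
      if (axis == 0) base = vidx(0, o1, o2, nx, ny);
      else if (axis == 1) base = vidx(o1, 0, o2, nx, ny);
      else base = vidx(o1, o2, 0, nx, ny);
      for (int t = 0; t < len; t++) line[t] = a[base + stride * t];
      for (int t = 0; t < len; t++) {
        double acc = 0;
        for (int u = -radius; u <= radius; u++) {
          int idx = t + u;
          if (idx < 0) idx = -idx - 1;
          if (idx >= len) idx = 2 * len - idx - 1;
          if (idx < 0) idx = 0;
          if (idx >= len) idx = len - 1;
          acc += kern[u + radius] * line[idx];
        }
        a[base + stride * t] = acc;
      }
    }
}

// [[Rcpp::export]]
NumericVector gauss_smooth3_cpp(NumericVector arr, IntegerVector dim,
                                NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(arr.begin(), arr.end());
  smooth_axis(a, nx, ny, nz, 0, sigma[0]);
  smooth_axis(a, nx, ny, nz, 1, sigma[1]);
  smooth_axis(a, nx, ny, nz, 2, sigma[2]);
  return NumericVector(a.begin(), a.end());
}

// MIND descriptor: six-neighbourhood patch self-similarity.
// Returns nvox x 6 matrix; components in (0,1], max component 1 per voxel.
// [[Rcpp::export]]
NumericMatrix mind_cpp(NumericVector arr, IntegerVector dim, double sigma,
                       double floorEps) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  int offs[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                    {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
  NumericMatrix D(nvox, 6);
  std::vector<double> diff2(nvox);
  for (int c = 0; c < 6; c++) {
    int oi = offs[c][0], oj = offs[c][1], ok = offs[c][2];
    R_xlen_t p = 0;
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++, p++) {
          int ii = i + oi, jj = j + oj, kk = k + ok;
          // clamp (edge replication)
          if (ii < 0) ii = 0; if (ii >= nx) ii = nx - 1;
          if (jj < 0) jj = 0; if (jj >= ny) jj = ny - 1;
          if (kk < 0) kk = 0; if (kk >= nz) kk = nz - 1;
          double d = arr[p] - arr[vidx(ii, jj, kk, nx, ny)];
          diff2[p] = d * d;
        }
    smooth_axis(diff2, nx, ny, nz, 0, sigma);
    smooth_axis(diff2, nx, ny, nz, 1, sigma);
    smooth_axis(diff2, nx, ny, nz, 2, sigma);
    for (R_xlen_t q = 0; q < nvox; q++) D(q, c) = diff2[q];
  }
  for (R_xlen_t q = 0; q < nvox; q++) {
    double V = 0;
    for (int c = 0; c < 6; c++) V += D(q, c);
    V /= 6.0;
    if (V < floorEps) V = floorEps;
    double mx = 0;
    double e[6];
    for (int c = 0; c < 6; c++) {
      e[c] = std::exp(-D(q, c) / V);
      if (e[c] > mx) mx = e[c];
    }
    for (int c = 0; c < 6; c++) D(q, c) = e[c] / mx;
  }
  return D;
}

// 26-connected region growing within [lo, hi] from seed (0-based ijk).
// [[Rcpp::export]]
LogicalVector region_grow_cpp(NumericVector arr, IntegerVector dim,
                              IntegerVector seed, double lo, double hi) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  LogicalVector out(nvox);
  std::vector<char> visited(nvox, 0);
  R_xlen_t s = vidx(seed[0], seed[1], seed[2], nx, ny);
  if (arr[s] < lo || arr[s] > hi)
    stop("seed intensity %f outside window [%f, %f]", (double)arr[s], lo, hi);
  std::vector<R_xlen_t> stack;
  stack.push_back(s);
  visited[s] = 1;
  while (!stack.empty()) {
    R_xlen_t p = stack.back();
    stack.pop_back();
    out[p] = true;
    int k = (int)(p / ((R_xlen_t)nx * ny));
    int rem = (int)(p % ((R_xlen_t)nx * ny));
    int j = rem / nx, i = rem % nx;
    for (int dk = -1; dk <= 1; dk++)
      for (int dj = -1; dj <= 1; dj++)
        for (int di = -1; di <= 1; di++) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          R_xlen_t q = vidx(ii, jj, kk, nx, ny);
          if (visited[q]) continue;
          visited[q] = 1;
          if (arr[q] >= lo && arr[q] <= hi) stack.push_back(q);
        }
  }
  return out;
}

// Boundary voxels of a mask (6-connectivity; array edge counts as boundary).
// [[Rcpp::export]]
LogicalVector boundary_mask_cpp(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t p = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, p++) {
        if (!mask[p]) continue;
        bool b = (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 ||
                  k == nz - 1);
        if (!b) {
          b = !mask[p - 1] || !mask[p + 1] || !mask[p - nx] || !mask[p + nx] ||
              !mask[p - (R_xlen_t)nx * ny] || !mask[p + (R_xlen_t)nx * ny];
        }
        out[p] = b;
      }
  return out;
}

// Brute-force nearest neighbours: for each query row, closest ref row.
// [[Rcpp::export]]
List nn_match_cpp(NumericMatrix query, NumericMatrix ref) {
  int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int q = 0; q < nq; q++) {
    double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    double best = R_PosInf;
    int bi = 0;
    for (int r = 0; r < nr; r++) {
      double dx = qx - ref(r, 0), dy = qy - ref(r, 1), dz = qz - ref(r, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bi = r; }
    }
    idx[q] = bi + 1;
    dist[q] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Primary-beam dose kernel.
// mu: attenuation (mm^-1) on grid with voxel->world affine A (world->voxel Ainv).
// src: source position (mm); iso: isocentre (mm); SAD = |iso - src|.
// collR: field radius at isocentre plane (mm); sigma: penumbra sigma (mm).
// Dose(v) = w(r_iso) * exp(-line integral of mu from entry to v) * (SAD/s)^2
// where s is the source-axis distance of v's projection.
// [[Rcpp::export]]
NumericVector dose_kernel_cpp(NumericVector mu, IntegerVector dim,
                              NumericMatrix A, NumericMatrix Ainv,
                              NumericVector src, NumericVector iso,
                              double collR, double sigma, double stepMm,
                              double wmin) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double *m = mu.begin();
  double dx = iso[0] - src[0], dy = iso[1] - src[1], dz = iso[2] - src[2];
  double SAD = std::sqrt(dx * dx + dy * dy + dz * dz);
  dx /= SAD; dy /= SAD; dz /= SAD;
  double sq2 = std::sqrt(2.0);
  R_xlen_t p = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, p++) {
        double wx = A(0, 0) * i + A(0, 1) * j + A(0, 2) * k + A(0, 3);
        double wy = A(1, 0) * i + A(1, 1) * j + A(1, 2) * k + A(1, 3);
        double wz = A(2, 0) * i + A(2, 1) * j + A(2, 2) * k + A(2, 3);
        double vx = wx - src[0], vy = wy - src[1], vz = wz - src[2];
        double s = vx * dx + vy * dy + vz * dz;
        if (s < 1e-6) continue;
        double px = vx - s * dx, py = vy - s * dy, pz = vz - s * dz;
        double r = std::sqrt(px * px + py * py + pz * pz) * SAD / s;
        double w = 0.5 * erfc((r - collR) / (sigma * sq2));
        if (w < wmin) continue;
        // ray march from voxel back toward source (midpoint rule)
        double rayn = std::sqrt(vx * vx + vy * vy + vz * vz);
        double ex = vx / rayn, ey = vy / rayn, ez = vz / rayn;
        double integ = 0;
        int maxSteps = (int)(rayn / stepMm) + 2;
        for (int t = 0; t < maxSteps; t++) {
          double qx = wx - (t + 0.5) * stepMm * ex;
          double qy = wy - (t + 0.5) * stepMm * ey;
          double qz = wz - (t + 0.5) * stepMm * ez;
          double gx = Ainv(0, 0) * qx + Ainv(0, 1) * qy + Ainv(0, 2) * qz + Ainv(0, 3);
          double gy = Ainv(1, 0) * qx + Ainv(1, 1) * qy + Ainv(1, 2) * qz + Ainv(1, 3);
          double gz = Ainv(2, 0) * qx + Ainv(2, 1) * qy + Ainv(2, 2) * qz + Ainv(2, 3);
          if (gx < -1 || gy < -1 || gz < -1 || gx > nx || gy > ny || gz > nz)
            break;
          integ += sample_linear(m, nx, ny, nz, gx, gy, gz, 0.0);
        }
        integ *= stepMm;
        double invsq = (SAD / s) * (SAD / s);
        out[p] = w * std::exp(-integ) * invsq;
      }
  return out;
}

// Mutual information between fixed image and moving image resampled through
// C (fixed voxel -> moving voxel). Linear binning (partial volume in both
// dimensions) for a smooth metric surface. Returns MI in nats.
// [[Rcpp::export]]
double mi_metric_cpp(NumericVector fix, IntegerVector fdim, NumericVector mov,
                     IntegerVector mdim, NumericMatrix C, int nbins,
                     NumericVector fixRange, NumericVector movRange,
                     int stride) {
  int fnx = fdim[0], fny = fdim[1], fnz = fdim[2];
  int mnx = mdim[0], mny = mdim[1], mnz = mdim[2];
  std::vector<double> joint((size_t)nbins * nbins, 0.0);
  double flo = fixRange[0], fsc = (nbins - 1) / (fixRange[1] - fixRange[0]);
  double mlo = movRange[0], msc = (nbins - 1) / (movRange[1] - movRange[0]);
  const double *a = mov.begin();
  double total = 0;
  for (int k = 0; k < fnz; k += stride)
    for (int j = 0; j < fny; j += stride)
      for (int i = 0; i < fnx; i += stride) {
        double x = C(0, 0) * i + C(0, 1) * j + C(0, 2) * k + C(0, 3);
        double y = C(1, 0) * i + C(1, 1) * j + C(1, 2) * k + C(1, 3);
        double z = C(2, 0) * i + C(2, 1) * j + C(2, 2) * k + C(2, 3);
        if (x < 0 || y < 0 || z < 0 || x > mnx - 1 || y > mny - 1 ||
            z > mnz - 1)
          continue;
        double mval = sample_linear(a, mnx, mny, mnz, x, y, z, 0.0);
        double fval = fix[vidx(i, j, k, fnx, fny)];
        double fb = clampd((fval - flo) * fsc, 0.0, nbins - 1.0);
        double mb = clampd((mval - mlo) * msc, 0.0, nbins - 1.0);
        int f0 = (int)std::floor(fb); if (f0 == nbins - 1) f0--;
        int m0 = (int)std::floor(mb); if (m0 == nbins - 1) m0--;
        double ff = fb - f0, mf = mb - m0;
        joint[f0 * nbins + m0] += (1 - ff) * (1 - mf);
        joint[(f0 + 1) * nbins + m0] += ff * (1 - mf);
        joint[f0 * nbins + m0 + 1] += (1 - ff) * mf;
        joint[(f0 + 1) * nbins + m0 + 1] += ff * mf;
        total += 1;
      }
  if (total < 100) return NA_REAL;
  std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
  for (int f = 0; f < nbins; f++)
    for (int g = 0; g < nbins; g++) {
      joint[f * nbins + g] /= total;
      pf[f] += joint[f * nbins + g];
      pm[g] += joint[f * nbins + g];
    }
  double mi = 0;
  for (int f = 0; f < nbins; f++)
    for (int g = 0; g < nbins; g++) {
      double pj = joint[f * nbins + g];
      if (pj > 1e-12) mi += pj * std::log(pj / (pf[f] * pm[g]));
    }
  return mi;
}

// Central-difference gradient along each axis; spacing in mm per axis.
// [[Rcpp::export]]
List gradient3_cpp(NumericVector arr, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector gx(nvox), gy(nvox), gz(nvox);
  R_xlen_t p = 0;
  R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, p++) {
        int im = i > 0 ? i - 1 : 0, ip = i < nx - 1 ? i + 1 : nx - 1;
        int jm = j > 0 ? j - 1 : 0, jp = j < ny - 1 ? j + 1 : ny - 1;
        int km = k > 0 ? k - 1 : 0, kp = k < nz - 1 ? k + 1 : nz - 1;
        gx[p] = (arr[p + (ip - i)] - arr[p - (i - im)]) / ((ip - im) * spacing[0]);
        gy[p] = (arr[p + (R_xlen_t)(jp - j) * nx] - arr[p - (R_xlen_t)(j - jm) * nx]) /
                ((jp - jm) * spacing[1]);
        gz[p] = (arr[p + (R_xlen_t)(kp - k) * sz] - arr[p - (R_xlen_t)(k - km) * sz]) /
                ((kp - km) * spacing[2]);
      }
  return List::create(_["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
}
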