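#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Mirror (symmetric, half-sample) boundary index.
static inline int reflectIndex(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// Correlate a 3D array (dims d1,d2,d3 column-major) with a centered 1D
// kernel along one axis (1-based), mirror boundary:
//   out[i] = sum_t k[t] * in[i + t - c],  c = (K-1)/2.
// [[Rcpp::export(name = ".convAxis")]]
NumericVector convAxis(NumericVector arr, NumericVector kernel, int axis) {
  IntegerVector dim = arr.attr("dim");
  if (dim.size() != 3) stop("expected a 3D array");
  if (axis < 1 || axis > 3) stop("axis must be 1, 2 or 3");
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int K = kernel.size();
  if (K % 2 == 0) stop("kernel length must be odd");
  const int c = (K - 1) / 2;

  NumericVector out(arr.size());
  out.attr("dim") = dim;

  const double *in = arr.begin();
  const double *k = kernel.begin();
  double *o = out.begin();

  int n, strideAxis;
  if (axis == 1)      { n = d1; strideAxis = 1; }
  else if (axis == 2) { n = d2; strideAxis = d1; }
  else                { n = d3; strideAxis = d1 * d2; }

  std::vector<double> line(n);
  // Iterate over all lines along `axis`.
  const int nOuter = (int)(arr.size() / n);
  for (int line_i = 0; line_i < nOuter; ++line_i) {
    // Base offset of this line.
    long base;
    if (axis == 1) {
      base = (long)line_i * d1;
    } else if (axis == 2) {
      const int i1 = line_i % d1, i3 = line_i / d1;
      base = (long)i1 + (long)i3 * d1 * d2;
    } else {
      base = line_i; // i1 + i2*d1
    }
    for (int i = 0; i < n; ++i) line[i] = in[base + (long)i * strideAxis];
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int t = 0; t < K; ++t)
        s += k[t] * line[reflectIndex(i + t - c, n)];
      o[base + (long)i * strideAxis] = s;
    }
  }
  return out;
}

// Render straight tube segments with a radial Gaussian profile (peak 1,
// scale = radius), combined by maximum. Coordinates are continuous voxel
// indices (0-based) in (x, y, z) order; the canvas is a (z, y, x) array.
// Returns intensity, the 1-based id of the winning segment per voxel
// (0 = none within support) and the distance to that segment.
// [[Rcpp::export(name = ".renderTubes")]]
List renderTubes(IntegerVector dimZyx, NumericMatrix p0, NumericMatrix p1,
                 double radius, double support) {
  const int nz = dimZyx[0], ny = dimZyx[1], nx = dimZyx[2];
  const long nvox = (long)nz * ny * nx;
  NumericVector inten(nvox);
  IntegerVector fid(nvox);
  NumericVector dist(nvox);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  inten.attr("dim") = dimZyx;
  fid.attr("dim") = dimZyx;
  dist.attr("dim") = dimZyx;

  const int nSeg = p0.nrow();
  const double twoR2 = 2.0 * radius * radius;
  const int rloc = (int)std::ceil(support) + 1;

  for (int s = 0; s < nSeg; ++s) {
    const double ax = p0(s, 0), ay = p0(s, 1), az = p0(s, 2);
    const double bx = p1(s, 0), by = p1(s, 1), bz = p1(s, 2);
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    const double L = std::sqrt(ux * ux + uy * uy + uz * uz);
    const int nStep = std::max(1, (int)std::ceil(L / 0.5));
    for (int st = 0; st <= nStep; ++st) {
      const double t = (double)st / nStep;
      const double qx = ax + t * ux, qy = ay + t * uy, qz = az + t * uz;
      const int x0 = std::max(0, (int)std::floor(qx) - rloc);
      const int x1 = std::min(nx - 1, (int)std::ceil(qx) + rloc);
      const int y0 = std::max(0, (int)std::floor(qy) - rloc);
      const int y1 = std::min(ny - 1, (int)std::ceil(qy) + rloc);
      const int z0 = std::max(0, (int)std::floor(qz) - rloc);
      const int z1 = std::min(nz - 1, (int)std::ceil(qz) + rloc);
      for (int x = x0; x <= x1; ++x) {
        for (int y = y0; y <= y1; ++y) {
          for (int z = z0; z <= z1; ++z) {
            // distance voxel -> full segment
            const double wx = x - ax, wy = y - ay, wz = z - az;
            double tt = 0.0;
            if (L > 0) {
              tt = (wx * ux + wy * uy + wz * uz) / (L * L);
              if (tt < 0) tt = 0;
              if (tt > 1) tt = 1;
            }
            const double dx = wx - tt * ux, dy = wy - tt * uy,
                         dz = wz - tt * uz;
            const double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 > support * support) continue;
            const double v = std::exp(-d2 / twoR2);
            const long idx = (long)z + (long)nz * (y + (long)ny * x);
            if (v > inten[idx]) {
              inten[idx] = v;
              fid[idx] = s + 1;
              dist[idx] = std::sqrt(d2);
            }
          }
        }
      }
    }
  }
  return List::create(_["intensity"] = inten, _["fiberId"] = fid,
                      _["dist"] = dist);
}

// Per-voxel eigendecomposition of symmetric 3x3 tensors given as an n x 6
// matrix with columns (xx, yy, zz, xy, xz, yz). Returns eigenvalues in
// ascending order and the eigenvector of the smallest eigenvalue.
// [[Rcpp::export(name = ".eigSymField")]]
List eigSymField(NumericMatrix T6) {
  const int n = T6.nrow();
  NumericMatrix axis(n, 3), eig(n, 3);
  arma::mat33 M;
  arma::vec3 ev;
  arma::mat33 V;
  for (int i = 0; i < n; ++i) {
    const double xx = T6(i, 0), yy = T6(i, 1), zz = T6(i, 2);
    const double xy = T6(i, 3), xz = T6(i, 4), yz = T6(i, 5);
    if (!std::isfinite(xx + yy + zz + xy + xz + yz)) {
      axis(i, 0) = 0; axis(i, 1) = 0; axis(i, 2) = 1;
      eig(i, 0) = NA_REAL; eig(i, 1) = NA_REAL; eig(i, 2) = NA_REAL;
      continue;
    }
    M(0, 0) = xx; M(1, 1) = yy; M(2, 2) = zz;
    M(0, 1) = M(1, 0) = xy;
    M(0, 2) = M(2, 0) = xz;
    M(1, 2) = M(2, 1) = yz;
    arma::eig_sym(ev, V, M);
    eig(i, 0) = ev(0); eig(i, 1) = ev(1); eig(i, 2) = ev(2);
    axis(i, 0) = V(0, 0); axis(i, 1) = V(1, 0); axis(i, 2) = V(2, 0);
  }
  return List::create(_["axis"] = axis, _["eigenvalues"] = eig);
}

// For each row (unit axial vector) of V, the index (1-based) of the row of
// H maximizing |v . h|. H holds hemisphere representatives whose z
// components are sorted ascending (the Fibonacci layout), which lets the
// search restrict itself to a z-band of `band` rows around the query's
// canonical z; `band >= nrow(H)` degrades to an exact full scan.
// [[Rcpp::export(name = ".nearestAxisBin")]]
IntegerVector nearestAxisBin(const NumericMatrix &V, const NumericMatrix &H,
                             const int band) {
  const int n = V.nrow(), m = H.nrow();
  IntegerVector out(n);
  std::vector<double> hx(m), hy(m), hz(m);
  for (int j = 0; j < m; ++j) {
    hx[j] = H(j, 0); hy[j] = H(j, 1); hz[j] = H(j, 2);
  }
  const bool full = band >= m;
  for (int i = 0; i < n; ++i) {
    double vx = V(i, 0), vy = V(i, 1), vz = V(i, 2);
    if (vz < 0) { vx = -vx; vy = -vy; vz = -vz; } // canonical hemisphere
    int lo = 0, hi = m - 1;
    if (!full) {
      const int c = (int)(vz * m);
      lo = std::max(0, c - band);
      hi = std::min(m - 1, c + band);
    }
    double best = -1.0;
    int bestJ = 0;
    for (int j = lo; j <= hi; ++j) {
      const double d = std::fabs(vx * hx[j] + vy * hy[j] + vz * hz[j]);
      if (d > best) { best = d; bestJ = j; }
    }
    out[i] = bestJ + 1;
  }
  return out;
}
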