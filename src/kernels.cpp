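#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline R_xlen_t lin3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Resample a 3D volume onto a new grid.  A (3x3) and b (3) map 0-based output
// voxel indices to continuous 0-based input indices.  method: 0 = nearest,
// 1 = trilinear.  Samples falling outside the source grid receive `pad`.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector src, IntegerVector sdim,
                                  IntegerVector odim, NumericMatrix A,
                                  NumericVector b, int method, double pad) {
  const int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  const int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double a00 = A(0,0), a01 = A(0,1), a02 = A(0,2);
  const double a10 = A(1,0), a11 = A(1,1), a12 = A(1,2);
  const double a20 = A(2,0), a21 = A(2,1), a22 = A(2,2);
  const double b0 = b[0], b1 = b[1], b2 = b[2];
  R_xlen_t q = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      const double pjx = a01 * j + a02 * k + b0;
      const double pjy = a11 * j + a12 * k + b1;
      const double pjz = a21 * j + a22 * k + b2;
      for (int i = 0; i < ox; ++i, ++q) {
        const double px = a00 * i + pjx;
        const double py = a10 * i + pjy;
        const double pz = a20 * i + pjz;
        if (method == 0) {
          const int ri = (int)std::lround(px);
          const int rj = (int)std::lround(py);
          const int rk = (int)std::lround(pz);
          if (ri >= 0 && ri < nx && rj >= 0 && rj < ny && rk >= 0 && rk < nz)
            out[q] = src[lin3(ri, rj, rk, nx, ny)];
          else
            out[q] = pad;
        } else {
          const double fx = std::floor(px), fy = std::floor(py), fz = std::floor(pz);
          const int i0 = (int)fx, j0 = (int)fy, k0 = (int)fz;
          const double tx = px - fx, ty = py - fy, tz = pz - fz;
          double acc = 0.0;
          for (int dk = 0; dk < 2; ++dk) {
            const double wz = dk ? tz : 1.0 - tz;
            if (wz == 0.0) continue;
            for (int dj = 0; dj < 2; ++dj) {
              const double wy = dj ? ty : 1.0 - ty;
              if (wy == 0.0) continue;
              for (int di = 0; di < 2; ++di) {
                const double wx = di ? tx : 1.0 - tx;
                if (wx == 0.0) continue;
                const int ii = i0 + di, jj = j0 + dj, kk = k0 + dk;
                double v;
                if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
                  v = src[lin3(ii, jj, kk, nx, ny)];
                else
                  v = pad;
                acc += wx * wy * wz * v;
              }
            }
          }
          out[q] = acc;
        }
      }
    }
  }
  return out;
}

// Largest 26-connected component of a logical mask (column-major 3D).
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> comp(n, 0);
  int ncomp = 0, best = 0;
  R_xlen_t best_size = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || comp[s]) continue;
    ++ncomp;
    R_xlen_t size = 0;
    stack.clear();
    stack.push_back(s);
    comp[s] = ncomp;
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      ++size;
      const int k = (int)(v / ((R_xlen_t)nx * ny));
      const int r = (int)(v % ((R_xlen_t)nx * ny));
      const int j = r / nx, i = r % nx;
      for (int dk = -1; dk <= 1; ++dk) {
        const int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            const int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            const R_xlen_t w = lin3(ii, jj, kk, nx, ny);
            if (mask[w] && !comp[w]) {
              comp[w] = ncomp;
              stack.push_back(w);
            }
          }
        }
      }
    }
    if (size > best_size) { best_size = size; best = ncomp; }
  }
  LogicalVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = comp[s] == best;
  return out;
}

// For each 0-based linear index in `vac`, return the value of the nearest
// (Euclidean, mm-scaled) voxel flagged in `donor`.  Expanding Chebyshev-shell
// search; exact because the search continues until the shell lower bound
// exceeds the best distance found.  NA if no donor exists anywhere.
// [[Rcpp::export]]
NumericVector cpp_nearest_donor(NumericVector vals, LogicalVector donor,
                                IntegerVector dim, NumericVector spacing,
                                IntegerVector vac) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double smin = std::min(sx, std::min(sy, sz));
  const int rmax = std::max(nx, std::max(ny, nz));
  const R_xlen_t nv = vac.size();
  NumericVector out(nv);
  for (R_xlen_t q = 0; q < nv; ++q) {
    const R_xlen_t v = (R_xlen_t)vac[q];
    const int k = (int)(v / ((R_xlen_t)nx * ny));
    const int r0 = (int)(v % ((R_xlen_t)nx * ny));
    const int j = r0 / nx, i = r0 % nx;
    double best_d2 = R_PosInf;
    double best_val = NA_REAL;
    for (int r = 0; r <= rmax; ++r) {
      if (best_d2 < R_PosInf) {
        const double lb = (double)r * smin;
        if (lb * lb > best_d2) break;
      }
      const int klo = std::max(0, k - r), khi = std::min(nz - 1, k + r);
      const int jlo = std::max(0, j - r), jhi = std::min(ny - 1, j + r);
      const int ilo = std::max(0, i - r), ihi = std::min(nx - 1, i + r);
      for (int kk = klo; kk <= khi; ++kk) {
        const bool kface = (kk == k - r || kk == k + r);
        const double dz = (kk - k) * sz;
        for (int jj = jlo; jj <= jhi; ++jj) {
          const bool jface = (jj == j - r || jj == j + r);
          const double dy = (jj - j) * sy;
          for (int ii = ilo; ii <= ihi; ++ii) {
            // only shell voxels (skip the interior already visited)
            if (!kface && !jface && !(ii == i - r || ii == i + r)) continue;
            const R_xlen_t w = lin3(ii, jj, kk, nx, ny);
            if (!donor[w]) continue;
            const double dx = (ii - i) * sx;
            const double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < best_d2) { best_d2 = d2; best_val = vals[w]; }
          }
        }
      }
    }
    out[q] = best_val;
  }
  return out;
}

// Mean of `vals` over a cube window of half-width `radius` around each voxel
// in `at` (0-based linear), restricted to voxels flagged in `include`.
// Falls back to the center value when the window holds no included voxel.
// [[Rcpp::export]]
NumericVector cpp_box_mean(NumericVector vals, LogicalVector include,
                           IntegerVector dim, IntegerVector at, int radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nv = at.size();
  NumericVector out(nv);
  for (R_xlen_t q = 0; q < nv; ++q) {
    const R_xlen_t v = (R_xlen_t)at[q];
    const int k = (int)(v / ((R_xlen_t)nx * ny));
    const int r0 = (int)(v % ((R_xlen_t)nx * ny));
    const int j = r0 / nx, i = r0 % nx;
    double acc = 0.0;
    R_xlen_t cnt = 0;
    for (int kk = std::max(0, k - radius); kk <= std::min(nz - 1, k + radius); ++kk)
      for (int jj = std::max(0, j - radius); jj <= std::min(ny - 1, j + radius); ++jj)
        for (int ii = std::max(0, i - radius); ii <= std::min(nx - 1, i + radius); ++ii) {
          const R_xlen_t w = lin3(ii, jj, kk, nx, ny);
          if (include[w]) { acc += vals[w]; ++cnt; }
        }
    out[q] = cnt ? acc / cnt : vals[v];
  }
  return out;
}

// Normalised cross-correlation between baseline and follow-up restricted to
// `mask` (0-based linear indices into the baseline), over all integer voxel
// offsets center +/- halfw per axis.  Returns the score array with
// dimensions (2*halfw+1) in offset order (dx fastest).  Offsets for which
// fewer than 10 mask voxels land inside the follow-up get NA.
// [[Rcpp::export]]
NumericVector cpp_ncc_search(NumericVector base, NumericVector foll,
                             IntegerVector dim, IntegerVector mask,
                             IntegerVector halfw, IntegerVector center) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int hx = halfw[0], hy = halfw[1], hz = halfw[2];
  const R_xlen_t nm = mask.size();
  std::vector<int> mi(nm), mj(nm), mk(nm);
  std::vector<double> bv(nm);
  for (R_xlen_t q = 0; q < nm; ++q) {
    const R_xlen_t v = (R_xlen_t)mask[q];
    mk[q] = (int)(v / ((R_xlen_t)nx * ny));
    const int r0 = (int)(v % ((R_xlen_t)nx * ny));
    mj[q] = r0 / nx;
    mi[q] = r0 % nx;
    bv[q] = base[v];
  }
  const int cx = center[0], cy = center[1], cz = center[2];
  const int ox = 2 * hx + 1, oy = 2 * hy + 1, oz = 2 * hz + 1;
  NumericVector out((R_xlen_t)ox * oy * oz);
  R_xlen_t p = 0;
  for (int dz = cz - hz; dz <= cz + hz; ++dz)
    for (int dy = cy - hy; dy <= cy + hy; ++dy)
      for (int dx = cx - hx; dx <= cx + hx; ++dx, ++p) {
        double sb = 0, sf = 0, sbb = 0, sff = 0, sbf = 0;
        R_xlen_t n = 0;
        for (R_xlen_t q = 0; q < nm; ++q) {
          const int ii = mi[q] + dx, jj = mj[q] + dy, kk = mk[q] + dz;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          const double f = foll[lin3(ii, jj, kk, nx, ny)];
          const double bq = bv[q];
          sb += bq; sf += f; sbb += bq * bq; sff += f * f; sbf += bq * f;
          ++n;
        }
        if (n < 10) { out[p] = NA_REAL; continue; }
        const double cov = sbf - sb * sf / n;
        const double vb = sbb - sb * sb / n;
        const double vf = sff - sf * sf / n;
        out[p] = (vb <= 0 || vf <= 0) ? NA_REAL : cov / std::sqrt(vb * vf);
      }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}
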