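// Voxel-level kernels: phantom rasterisation, separable Gaussian smoothing,
// marching-tetrahedra isosurfacing, chord/mask crossing counts, rigid
// nearest-neighbour resampling, trilinear overlap scoring and connected
// component labelling.  All physical coordinates are in mm; voxel (i,j,k)
// is 0-based with centre at origin + (i,j,k) * spacing.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline double vx(const NumericVector& origin, const NumericVector& sp,
                        int i, int axis) {
  return origin[axis] + i * sp[axis];
}

// ---------------------------------------------------------------------------
// Phantom rasterisation: classify voxels of a spherical shell and an angular
// patch window in a single pass.  Returns 0 = background, 1 = shell outside
// the patch window, 2 = shell inside the patch window.
// [[Rcpp::export]]
IntegerVector cpp_shell_patch(IntegerVector dim, NumericVector spacing,
                              NumericVector origin, NumericVector center,
                              double r_inner, double r_outer,
                              bool with_patch, double az_center,
                              double az_halfwidth, double polar_lo,
                              double polar_hi) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out((R_xlen_t)nx * ny * nz);
  const double r_in2 = r_inner * r_inner, r_out2 = r_outer * r_outer;
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    const double dz = vx(origin, spacing, k, 2) - center[2];
    for (int j = 0; j < ny; ++j) {
      const double dy = vx(origin, spacing, j, 1) - center[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        const double dx = vx(origin, spacing, i, 0) - center[0];
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < r_in2 || d2 > r_out2) continue;
        int v = 1;
        if (with_patch) {
          const double r = std::sqrt(d2);
          const double polar = (r > 0) ? std::acos(dz / r) : 0.0;
          if (polar >= polar_lo && polar <= polar_hi) {
            double daz = std::atan2(dy, dx) - az_center;
            while (daz > M_PI) daz -= 2.0 * M_PI;
            while (daz < -M_PI) daz += 2.0 * M_PI;
            if (std::fabs(daz) <= az_halfwidth) v = 2;
          }
        }
        out[idx] = v;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing (reflected borders), sigma per axis in voxels.
static void smooth_axis(std::vector<double>& a, int nx, int ny, int nz,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  const int radius = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> w(2 * radius + 1);
  double s = 0;
  for (int t = -radius; t <= radius; ++t) {
    w[t + radius] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += w[t + radius];
  }
  for (double& x : w) x /= s;
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int len = n[axis];
  const R_xlen_t st = stride[axis];
  std::vector<double> line(len);
  // iterate over all lines along `axis`
  const int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  for (int u = 0; u < n[a1]; ++u) {
    for (int v = 0; v < n[a2]; ++v) {
      const R_xlen_t base = (R_xlen_t)u * stride[a1] + (R_xlen_t)v * stride[a2];
      for (int t = 0; t < len; ++t) line[t] = a[base + t * st];
      for (int t = 0; t < len; ++t) {
        double acc = 0;
        for (int d = -radius; d <= radius; ++d) {
          int p = t + d;
          if (p < 0) p = -p - 1;          // reflect
          if (p >= len) p = 2 * len - p - 1;
          acc += w[d + radius] * line[p];
        }
        a[base + t * st] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector field, IntegerVector dim,
                                  NumericVector sigma_vox) {
  std::vector<double> a(field.begin(), field.end());
  smooth_axis(a, dim[0], dim[1], dim[2], 0, sigma_vox[0]);
  smooth_axis(a, dim[0], dim[1], dim[2], 1, sigma_vox[1]);
  smooth_axis(a, dim[0], dim[1], dim[2], 2, sigma_vox[2]);
  NumericVector out(a.begin(), a.end());
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra.  Each grid cell is split into six tetrahedra sharing
// the main diagonal; the decomposition uses the same face diagonals in every
// cell, so shared faces match and the surface of an interior component is
// watertight.  Vertices are linearly interpolated to the crossing level and
// deduplicated by their (global) edge endpoints.  Triangles are oriented so
// the normal points from the high-value (interior) side to the low side.

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx_, vy_, vz_;
  std::vector<int> f0, f1, f2;
};

static int mt_vertex(MTState& st, uint64_t ga, uint64_t gb, double fa, double fb,
                     const double pa[3], const double pb[3], double level) {
  if (ga > gb) return mt_vertex(st, gb, ga, fb, fa, pb, pa, level);
  const uint64_t key = ga * 2000000011ULL + gb;
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  const double t = (level - fa) / (fb - fa);
  st.vx_.push_back(pa[0] + t * (pb[0] - pa[0]));
  st.vy_.push_back(pa[1] + t * (pb[1] - pa[1]));
  st.vz_.push_back(pa[2] + t * (pb[2] - pa[2]));
  const int id = (int)st.vx_.size() - 1;
  st.edge_vertex.emplace(key, id);
  return id;
}

static void mt_emit(MTState& st, int a, int b, int c,
                    const double in_pt[3], bool toward_inside) {
  // orient so normal points AWAY from in_pt when toward_inside is false,
  // TOWARD in_pt when true (used for the single-outside-vertex case).
  const double ux = st.vx_[b] - st.vx_[a], uy = st.vy_[b] - st.vy_[a],
               uz = st.vz_[b] - st.vz_[a];
  const double wx = st.vx_[c] - st.vx_[a], wy = st.vy_[c] - st.vy_[a],
               wz = st.vz_[c] - st.vz_[a];
  const double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz,
               nz = ux * wy - uy * wx;
  const double cx = (st.vx_[a] + st.vx_[b] + st.vx_[c]) / 3.0 - in_pt[0];
  const double cy = (st.vy_[a] + st.vy_[b] + st.vy_[c]) / 3.0 - in_pt[1];
  const double cz = (st.vz_[a] + st.vz_[b] + st.vz_[c]) / 3.0 - in_pt[2];
  double d = nx * cx + ny * cy + nz * cz;
  if (toward_inside) d = -d;
  if (d < 0) std::swap(b, c);
  st.f0.push_back(a); st.f1.push_back(b); st.f2.push_back(c);
}

static void mt_tet(MTState& st, const uint64_t g[4], const double f[4],
                   const double p[4][3], double level) {
  bool in[4];
  int nin = 0;
  for (int t = 0; t < 4; ++t) { in[t] = f[t] > level; nin += in[t]; }
  if (nin == 0 || nin == 4) return;
  int ins[4], outs[4];
  int ni = 0, no = 0;
  for (int t = 0; t < 4; ++t) (in[t] ? ins[ni++] : outs[no++]) = t;
  if (nin == 1) {
    const int A = ins[0];
    const int v0 = mt_vertex(st, g[A], g[outs[0]], f[A], f[outs[0]], p[A], p[outs[0]], level);
    const int v1 = mt_vertex(st, g[A], g[outs[1]], f[A], f[outs[1]], p[A], p[outs[1]], level);
    const int v2 = mt_vertex(st, g[A], g[outs[2]], f[A], f[outs[2]], p[A], p[outs[2]], level);
    mt_emit(st, v0, v1, v2, p[A], false);
  } else if (nin == 3) {
    const int D = outs[0];
    const int v0 = mt_vertex(st, g[D], g[ins[0]], f[D], f[ins[0]], p[D], p[ins[0]], level);
    const int v1 = mt_vertex(st, g[D], g[ins[1]], f[D], f[ins[1]], p[D], p[ins[1]], level);
    const int v2 = mt_vertex(st, g[D], g[ins[2]], f[D], f[ins[2]], p[D], p[ins[2]], level);
    mt_emit(st, v0, v1, v2, p[D], true);
  } else {
    const int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
    const int vac = mt_vertex(st, g[A], g[C], f[A], f[C], p[A], p[C], level);
    const int vad = mt_vertex(st, g[A], g[D], f[A], f[D], p[A], p[D], level);
    const int vbd = mt_vertex(st, g[B], g[D], f[B], f[D], p[B], p[D], level);
    const int vbc = mt_vertex(st, g[B], g[C], f[B], f[C], p[B], p[C], level);
    double mid_in[3];
    for (int t = 0; t < 3; ++t) mid_in[t] = 0.5 * (p[A][t] + p[B][t]);
    // quad vac-vad-vbd-vbc, fan-triangulated
    mt_emit(st, vac, vad, vbd, mid_in, false);
    mt_emit(st, vac, vbd, vbc, mid_in, false);
  }
}

// vertex order within a cell: bit pattern (x, y, z) offsets
static const int CUBE_OFF[8][3] = {
  {0,0,0}, {1,0,0}, {1,1,0}, {0,1,0}, {0,0,1}, {1,0,1}, {1,1,1}, {0,1,1}};
// six tetrahedra around the 0-6 diagonal
static const int TETS[6][4] = {
  {0,1,2,6}, {0,2,3,6}, {0,3,7,6}, {0,7,4,6}, {0,4,5,6}, {0,5,1,6}};

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector field, IntegerVector dim,
                        NumericVector spacing, NumericVector origin,
                        double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  MTState st;
  uint64_t g[4];
  double f[4], p[4][3];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        // gather cube
        double cf[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          const int ii = i + CUBE_OFF[c][0], jj = j + CUBE_OFF[c][1],
                    kk = k + CUBE_OFF[c][2];
          cf[c] = field[(R_xlen_t)ii + (R_xlen_t)jj * nx + (R_xlen_t)kk * nx * ny];
          (cf[c] > level ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          for (int c = 0; c < 4; ++c) {
            const int vtx = TETS[t][c];
            const int ii = i + CUBE_OFF[vtx][0], jj = j + CUBE_OFF[vtx][1],
                      kk = k + CUBE_OFF[vtx][2];
            g[c] = (uint64_t)ii + (uint64_t)jj * nx + (uint64_t)kk * nx * ny;
            f[c] = cf[vtx];
            p[c][0] = vx(origin, spacing, ii, 0);
            p[c][1] = vx(origin, spacing, jj, 1);
            p[c][2] = vx(origin, spacing, kk, 2);
          }
          mt_tet(st, g, f, p, level);
        }
      }
  const int nv = (int)st.vx_.size(), nf = (int)st.f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int t = 0; t < nv; ++t) {
    V(t, 0) = st.vx_[t]; V(t, 1) = st.vy_[t]; V(t, 2) = st.vz_[t];
  }
  for (int t = 0; t < nf; ++t) {
    F(t, 0) = st.f0[t] + 1; F(t, 1) = st.f1[t] + 1; F(t, 2) = st.f2[t] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Chord crossing counts: march each chord at a fixed step, sample the mask by
// nearest voxel, count binary transitions along the chord.
// [[Rcpp::export]]
IntegerVector cpp_count_crossings(LogicalVector mask, IntegerVector dim,
                                  NumericVector spacing, NumericVector origin,
                                  NumericMatrix p0, NumericMatrix p1,
                                  double step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nc = p0.nrow();
  IntegerVector out(nc);
  for (int c = 0; c < nc; ++c) {
    const double ax = p0(c, 0), ay = p0(c, 1), az = p0(c, 2);
    double dx = p1(c, 0) - ax, dy = p1(c, 1) - ay, dz = p1(c, 2) - az;
    const double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    int nstep = (int)std::ceil(len / step);
    if (nstep < 1) nstep = 1;
    int prev = 0, ncross = 0;
    for (int s = 0; s <= nstep; ++s) {
      const double t = (double)s / nstep;
      const int i = (int)std::lround((ax + t * dx - origin[0]) / spacing[0]);
      const int j = (int)std::lround((ay + t * dy - origin[1]) / spacing[1]);
      const int k = (int)std::lround((az + t * dz - origin[2]) / spacing[2]);
      int cur = 0;
      if (i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz)
        cur = mask[(R_xlen_t)i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny] ? 1 : 0;
      if (s > 0 && cur != prev) ++ncross;
      prev = cur;
    }
    out[c] = ncross;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Rigid nearest-neighbour resampling.  The forward map is
//   y = R (x - center) + center + translation
// and each output voxel centre y is filled from the input voxel nearest to
// the preimage x = R^T (y - center - translation) + center.
// [[Rcpp::export]]
LogicalVector cpp_resample_rigid(LogicalVector mask, IntegerVector dim,
                                 NumericVector spacing, NumericVector origin,
                                 NumericMatrix rot, NumericVector trans,
                                 NumericVector center) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  double R[3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) R[a][b] = rot(a, b);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    const double yz = vx(origin, spacing, k, 2) - center[2] - trans[2];
    for (int j = 0; j < ny; ++j) {
      const double yy = vx(origin, spacing, j, 1) - center[1] - trans[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        const double yx = vx(origin, spacing, i, 0) - center[0] - trans[0];
        // x = R^T y' + center
        const double px = R[0][0] * yx + R[1][0] * yy + R[2][0] * yz + center[0];
        const double py = R[0][1] * yx + R[1][1] * yy + R[2][1] * yz + center[1];
        const double pz = R[0][2] * yx + R[1][2] * yy + R[2][2] * yz + center[2];
        const int ii = (int)std::lround((px - origin[0]) / spacing[0]);
        const int jj = (int)std::lround((py - origin[1]) / spacing[1]);
        const int kk = (int)std::lround((pz - origin[2]) / spacing[2]);
        if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
          out[idx] = mask[(R_xlen_t)ii + (R_xlen_t)jj * nx + (R_xlen_t)kk * nx * ny];
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Registration objective: mean trilinearly-interpolated value of `field` at
// the rigidly transformed points (rows of `pts`, mm).
// [[Rcpp::export]]
double cpp_overlap_score(NumericVector field, IntegerVector dim,
                         NumericVector spacing, NumericVector origin,
                         NumericMatrix pts, NumericMatrix rot,
                         NumericVector trans, NumericVector center) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int np = pts.nrow();
  double R[3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) R[a][b] = rot(a, b);
  double acc = 0;
  for (int p = 0; p < np; ++p) {
    const double dx = pts(p, 0) - center[0], dy = pts(p, 1) - center[1],
                 dz = pts(p, 2) - center[2];
    const double X = R[0][0] * dx + R[0][1] * dy + R[0][2] * dz + center[0] + trans[0];
    const double Y = R[1][0] * dx + R[1][1] * dy + R[1][2] * dz + center[1] + trans[1];
    const double Z = R[2][0] * dx + R[2][1] * dy + R[2][2] * dz + center[2] + trans[2];
    const double gx = (X - origin[0]) / spacing[0];
    const double gy = (Y - origin[1]) / spacing[1];
    const double gz = (Z - origin[2]) / spacing[2];
    const int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
              k0 = (int)std::floor(gz);
    if (i0 < 0 || i0 + 1 >= nx || j0 < 0 || j0 + 1 >= ny || k0 < 0 || k0 + 1 >= nz)
      continue;
    const double fx = gx - i0, fy = gy - j0, fz = gz - k0;
    double v = 0;
    for (int c = 0; c < 8; ++c) {
      const int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
      const double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
      v += w * field[(R_xlen_t)(i0 + di) + (R_xlen_t)(j0 + dj) * nx +
                     (R_xlen_t)(k0 + dk) * nx * ny];
    }
    acc += v;
  }
  return acc / np;
}

// ---------------------------------------------------------------------------
// Connected component labelling (6- or 26-connectivity), flood fill.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  std::vector<int> nb_off;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (!di && !dj && !dk) continue;
        const int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        nb_off.push_back(di);
        nb_off.push_back(dj);
        nb_off.push_back(dk);
      }
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int i = cur % nx, j = (cur / nx) % ny, k = cur / ((R_xlen_t)nx * ny);
      for (size_t q = 0; q < nb_off.size(); q += 3) {
        const int ii = i + nb_off[q], jj = j + nb_off[q + 1], kk = k + nb_off[q + 2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        const R_xlen_t t = (R_xlen_t)ii + (R_xlen_t)jj * nx + (R_xlen_t)kk * nx * ny;
        if (mask[t] && !lab[t]) {
          lab[t] = next;
          stack.push_back(t);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Chord crossing counts against a continuous occupancy field: march each
// chord, sample the field by trilinear interpolation, count crossings of
// `level`.  Samples outside the grid read as 0.
// [[Rcpp::export]]
IntegerVector cpp_count_crossings_field(NumericVector field, IntegerVector dim,
                                        NumericVector spacing,
                                        NumericVector origin,
                                        NumericMatrix p0, NumericMatrix p1,
                                        double step, double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nc = p0.nrow();
  IntegerVector out(nc);
  for (int c = 0; c < nc; ++c) {
    const double ax = p0(c, 0), ay = p0(c, 1), az = p0(c, 2);
    double dx = p1(c, 0) - ax, dy = p1(c, 1) - ay, dz = p1(c, 2) - az;
    const double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    int nstep = (int)std::ceil(len / step);
    if (nstep < 1) nstep = 1;
    int prev = 0, ncross = 0;
    for (int s = 0; s <= nstep; ++s) {
      const double t = (double)s / nstep;
      const double gx = (ax + t * dx - origin[0]) / spacing[0];
      const double gy = (ay + t * dy - origin[1]) / spacing[1];
      const double gz = (az + t * dz - origin[2]) / spacing[2];
      const int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
                k0 = (int)std::floor(gz);
      double v = 0;
      if (i0 >= 0 && i0 + 1 < nx && j0 >= 0 && j0 + 1 < ny && k0 >= 0 &&
          k0 + 1 < nz) {
        const double fx = gx - i0, fy = gy - j0, fz = gz - k0;
        for (int q = 0; q < 8; ++q) {
          const int di = q & 1, dj = (q >> 1) & 1, dk = (q >> 2) & 1;
          const double w =
              (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          v += w * field[(R_xlen_t)(i0 + di) + (R_xlen_t)(j0 + dj) * nx +
                         (R_xlen_t)(k0 + dk) * nx * ny];
        }
      }
      const int cur = v > level ? 1 : 0;
      if (s > 0 && cur != prev) ++ncross;
      prev = cur;
    }
    out[c] = ncross;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Rigid resampling with trilinear interpolation of the binary mask followed
// by thresholding at 0.5; sub-voxel surface placement where nearest-
// neighbour lookup would introduce a full voxel of staircase noise.
// [[Rcpp::export]]
LogicalVector cpp_resample_rigid_linear(LogicalVector mask, IntegerVector dim,
                                        NumericVector spacing,
                                        NumericVector origin,
                                        NumericMatrix rot, NumericVector trans,
                                        NumericVector center) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  double R[3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) R[a][b] = rot(a, b);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    const double yz = vx(origin, spacing, k, 2) - center[2] - trans[2];
    for (int j = 0; j < ny; ++j) {
      const double yy = vx(origin, spacing, j, 1) - center[1] - trans[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        const double yx = vx(origin, spacing, i, 0) - center[0] - trans[0];
        const double px = R[0][0] * yx + R[1][0] * yy + R[2][0] * yz + center[0];
        const double py = R[0][1] * yx + R[1][1] * yy + R[2][1] * yz + center[1];
        const double pz = R[0][2] * yx + R[1][2] * yy + R[2][2] * yz + center[2];
        const double gx = (px - origin[0]) / spacing[0];
        const double gy = (py - origin[1]) / spacing[1];
        const double gz = (pz - origin[2]) / spacing[2];
        const int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
                  k0 = (int)std::floor(gz);
        if (i0 < -1 || i0 + 1 > nx || j0 < -1 || j0 + 1 > ny || k0 < -1 ||
            k0 + 1 > nz)
          continue;
        const double fx = gx - i0, fy = gy - j0, fz = gz - k0;
        double v = 0;
        for (int q = 0; q < 8; ++q) {
          const int di = q & 1, dj = (q >> 1) & 1, dk = (q >> 2) & 1;
          const int ii = i0 + di, jj = j0 + dj, kk = k0 + dk;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          const double w =
              (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          v += w * (mask[(R_xlen_t)ii + (R_xlen_t)jj * nx +
                         (R_xlen_t)kk * nx * ny] ? 1.0 : 0.0);
        }
        out[idx] = v > 0.5;
      }
    }
  }
  return out;
}
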