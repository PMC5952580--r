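#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Shared conventions (see the geometry module docs):
//   - right-handed coordinates, isocenter at the volume center,
//     voxel values sampled at voxel centers;
//   - source at angle theta sits at sid*(cos t, sin t, 0);
//   - flat detector centered on the line through the isocenter opposite the
//     source, at distance sdd from the source; detector u-axis
//     (-sin t, cos t, 0) lies in the rotation plane, v-axis is +z;
//   - volume grid nx*ny*nz with isotropic in-plane voxel_size vs, x extent
//     [-nx*vs/2, nx*vs/2], column-major storage ix + nx*(iy + ny*iz).

struct Ray {
  double sx, sy, sz;   // source
  double dx, dy, dz;   // direction (not normalized), length = |d|
  double len;
};

// Siddon/Amanatides-Woo traversal of one ray through the grid.
// mode 0: accumulate sum(vol[i] * seg_len) into *out (forward projection).
// mode 1: accumulate val * seg_len into vol[i] for i with iz in [z0, z1]
//         (exact transpose of the forward traversal).
static inline void trace_ray(const Ray& r,
                             const double* vol, double* volw,
                             int nx, int ny, int nz, double vs,
                             int mode, double val, double* out,
                             int z0, int z1) {
  const double bx = -0.5 * nx * vs, by = -0.5 * ny * vs, bz = -0.5 * nz * vs;
  const double hx =  0.5 * nx * vs, hy =  0.5 * ny * vs, hz =  0.5 * nz * vs;
  const double eps = 1e-12;

  double tmin = 0.0, tmax = 1.0;
  const double s[3] = {r.sx, r.sy, r.sz};
  const double d[3] = {r.dx, r.dy, r.dz};
  const double lo[3] = {bx, by, bz};
  const double hi[3] = {hx, hy, hz};
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < eps) {
      if (s[a] <= lo[a] || s[a] >= hi[a]) return;  // parallel, outside slab
    } else {
      double t0 = (lo[a] - s[a]) / d[a];
      double t1 = (hi[a] - s[a]) / d[a];
      if (t0 > t1) std::swap(t0, t1);
      if (t0 > tmin) tmin = t0;
      if (t1 < tmax) tmax = t1;
    }
  }
  if (tmin >= tmax) return;

  // entry voxel
  int ix, iy, iz;
  {
    double px = s[0] + tmin * d[0], py = s[1] + tmin * d[1], pz = s[2] + tmin * d[2];
    ix = (int)std::floor((px - bx) / vs); if (ix < 0) ix = 0; if (ix > nx - 1) ix = nx - 1;
    iy = (int)std::floor((py - by) / vs); if (iy < 0) iy = 0; if (iy > ny - 1) iy = ny - 1;
    iz = (int)std::floor((pz - bz) / vs); if (iz < 0) iz = 0; if (iz > nz - 1) iz = nz - 1;
  }
  const int stx = (d[0] > eps) - (d[0] < -eps);
  const int sty = (d[1] > eps) - (d[1] < -eps);
  const int stz = (d[2] > eps) - (d[2] < -eps);
  const double big = 1e30;
  double tnx = big, tny = big, tnz = big;   // t of next boundary crossing
  double dtx = big, dty = big, dtz = big;   // t increment per voxel step
  if (stx != 0) {
    tnx = (bx + (ix + (stx > 0)) * vs - s[0]) / d[0];
    dtx = vs / std::fabs(d[0]);
  }
  if (sty != 0) {
    tny = (by + (iy + (sty > 0)) * vs - s[1]) / d[1];
    dty = vs / std::fabs(d[1]);
  }
  if (stz != 0) {
    tnz = (bz + (iz + (stz > 0)) * vs - s[2]) / d[2];
    dtz = vs / std::fabs(d[2]);
  }

  double t = tmin, acc = 0.0;
  const long sxy = (long)nx * ny;
  while (t < tmax - eps) {
    double tn = std::min(std::min(tnx, tny), std::min(tnz, tmax));
    double seg = (tn - t) * r.len;
    if (seg > 0) {
      long idx = ix + (long)nx * iy + sxy * iz;
      if (mode == 0) acc += vol[idx] * seg;
      else if (iz >= z0 && iz <= z1) volw[idx] += val * seg;
    }
    t = tn;
    if (tnx <= tny && tnx <= tnz) {
      ix += stx; tnx += dtx;
      if (ix < 0 || ix >= nx) break;
    } else if (tny <= tnz) {
      iy += sty; tny += dty;
      if (iy < 0 || iy >= ny) break;
    } else {
      iz += stz; tnz += dtz;
      if (iz < 0 || iz >= nz) break;
    }
  }
  if (mode == 0) *out += acc;
}

static inline Ray make_ray(double theta, double sid, double sdd,
                           int nu, int nv, double pu, double pv,
                           int iu, int iv) {
  const double ct = std::cos(theta), st = std::sin(theta);
  Ray r;
  r.sx = sid * ct; r.sy = sid * st; r.sz = 0.0;
  const double cu = (iu - 0.5 * (nu - 1)) * pu;
  const double cv = (iv - 0.5 * (nv - 1)) * pv;
  const double dcx = -(sdd - sid) * ct, dcy = -(sdd - sid) * st;
  const double px = dcx - cu * st, py = dcy + cu * ct, pz = cv;
  r.dx = px - r.sx; r.dy = py - r.sy; r.dz = pz - r.sz;
  r.len = std::sqrt(r.dx * r.dx + r.dy * r.dy + r.dz * r.dz);
  return r;
}

// Ray-driven forward projection: line integral source->pixel per detector
// pixel, for the given angles (radians). Returns nu x nv x nangle array.
// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol,
                                  IntegerVector dims, double voxel_size,
                                  NumericVector angles_rad,
                                  double sid, double sdd,
                                  int nu, int nv, double pu, double pv) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = angles_rad.size();
  NumericVector out((R_xlen_t)nu * nv * na);
  const double* v = vol.begin();
  double* o = out.begin();
  for (int ia = 0; ia < na; ++ia) {
    const double th = angles_rad[ia];
    for (int iv = 0; iv < nv; ++iv) {
      for (int iu = 0; iu < nu; ++iu) {
        Ray r = make_ray(th, sid, sdd, nu, nv, pu, pv, iu, iv);
        double* cell = o + iu + (long)nu * iv + (long)nu * nv * ia;
        trace_ray(r, v, nullptr, nx, ny, nz, voxel_size, 0, 0.0, cell, 0, nz - 1);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nu, nv, na);
  return out;
}

// Exact transpose of cpp_forward_project (matched adjoint): scatter each
// detector value along its ray footprint, length-weighted. Only voxels with
// iz in [z0, z1] (0-based) are written, so z-slab chunking reproduces the
// unchunked result bit for bit.
// [[Rcpp::export]]
NumericVector cpp_back_project_matched(NumericVector proj,
                                       IntegerVector dims, double voxel_size,
                                       NumericVector angles_rad,
                                       double sid, double sdd,
                                       int nu, int nv, double pu, double pv,
                                       int z0, int z1) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = angles_rad.size();
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* w = out.begin();
  const double* p = proj.begin();
  for (int ia = 0; ia < na; ++ia) {
    const double th = angles_rad[ia];
    for (int iv = 0; iv < nv; ++iv) {
      for (int iu = 0; iu < nu; ++iu) {
        const double val = p[iu + (long)nu * iv + (long)nu * nv * ia];
        if (val == 0.0) continue;
        Ray r = make_ray(th, sid, sdd, nu, nv, pu, pv, iu, iv);
        trace_ray(r, nullptr, w, nx, ny, nz, voxel_size, 1, val, nullptr, z0, z1);
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Voxel-driven backprojection: each voxel center is projected onto the
// detector for every angle and the bilinearly interpolated detector value is
// accumulated. weight_mode 0: plain accumulation scaled by voxel_size
// (approximate intersection length; the classical unmatched A^T);
// weight_mode 1: FDK distance weighting sid^2/d^2, no voxel_size scale.
// Voxels projecting outside the detector contribute 0. z-slab [z0, z1].
// [[Rcpp::export]]
NumericVector cpp_back_project_voxel(NumericVector proj,
                                     IntegerVector dims, double voxel_size,
                                     NumericVector angles_rad,
                                     double sid, double sdd,
                                     int nu, int nv, double pu, double pv,
                                     int z0, int z1, int weight_mode) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = angles_rad.size();
  const double vs = voxel_size;
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* w = out.begin();
  const double* p = proj.begin();
  std::vector<double> ct(na), st(na);
  for (int ia = 0; ia < na; ++ia) { ct[ia] = std::cos(angles_rad[ia]); st[ia] = std::sin(angles_rad[ia]); }
  for (int iz = z0; iz <= z1; ++iz) {
    const double z = (iz - 0.5 * (nz - 1)) * vs;
    for (int iy = 0; iy < ny; ++iy) {
      const double y = (iy - 0.5 * (ny - 1)) * vs;
      for (int ix = 0; ix < nx; ++ix) {
        const double x = (ix - 0.5 * (nx - 1)) * vs;
        double acc = 0.0;
        for (int ia = 0; ia < na; ++ia) {
          // distance from source plane along the central-ray direction
          const double d = sid - (x * ct[ia] + y * st[ia]);
          if (d < 1e-9) continue;
          const double mag = sdd / d;
          const double tu = mag * (-x * st[ia] + y * ct[ia]);
          const double tv = mag * z;
          const double fu = tu / pu + 0.5 * (nu - 1);
          const double fv = (nv == 1) ? 0.0 : tv / pv + 0.5 * (nv - 1);
          if (fu < 0 || fu > nu - 1 || fv < 0 || fv > nv - 1) continue;
          const int ju = std::min((int)std::floor(fu), nu - 2 >= 0 ? nu - 2 : 0);
          const int jv = std::min((int)std::floor(fv), nv - 2 >= 0 ? nv - 2 : 0);
          const double au = fu - ju, av = fv - jv;
          const long base = (long)nu * nv * ia;
          double interp;
          if (nv == 1) {
            const double p0 = p[ju + base], p1 = p[std::min(ju + 1, nu - 1) + base];
            interp = (1 - au) * p0 + au * p1;
          } else {
            const double p00 = p[ju + (long)nu * jv + base];
            const double p10 = p[ju + 1 + (long)nu * jv + base];
            const double p01 = p[ju + (long)nu * (jv + 1) + base];
            const double p11 = p[ju + 1 + (long)nu * (jv + 1) + base];
            interp = (1 - au) * (1 - av) * p00 + au * (1 - av) * p10 +
                     (1 - au) * av * p01 + au * av * p11;
          }
          if (weight_mode == 1) acc += interp * (sid * sid) / (d * d);
          else acc += interp * vs;
        }
        w[ix + (long)nx * iy + (long)nx * ny * iz] = acc;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
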