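#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Small fixed sub-pixel offset of the sampling point breaks exact ties on
// shared triangle edges (a pixel centre lying exactly on an edge would be
// rasterised by both adjacent triangles and double-count the crossing).
static const double PX_OFF_X = 1.234e-4;
static const double PX_OFF_Y = 5.678e-5;

// Per-pixel chord length (mm) of rays through a closed, consistently wound
// triangle mesh given in camera coordinates (source at origin, detector at
// z = sid).  Signed ray crossings: a ray exits through a triangle whose
// outward normal has positive component along the ray, enters otherwise;
// thickness = sum(exit distances) - sum(entry distances).
// [[Rcpp::export]]
NumericMatrix render_thickness_cpp(NumericMatrix V, IntegerMatrix F,
                                   double sid, double pitch,
                                   double ppx, double ppy,
                                   int width, int height) {
  NumericMatrix out(height, width);
  const double f = sid / pitch;  // focal length in pixels
  const int nf = F.nrow();
  for (int t = 0; t < nf; ++t) {
    const int ia = F(t, 0), ib = F(t, 1), ic = F(t, 2);
    const double ax = V(ia,0), ay = V(ia,1), az = V(ia,2);
    const double bx = V(ib,0), by = V(ib,1), bz = V(ib,2);
    const double cx = V(ic,0), cy = V(ic,1), cz = V(ic,2);
    if (az <= 1e-9 || bz <= 1e-9 || cz <= 1e-9) continue;  // behind source
    // projected pixel coordinates
    const double ua = ppx + f*ax/az, va = ppy + f*ay/az;
    const double ub = ppx + f*bx/bz, vb = ppy + f*by/bz;
    const double uc = ppx + f*cx/cz, vc = ppy + f*cy/cz;
    int x0 = (int)std::floor(std::min(ua, std::min(ub, uc)));
    int x1 = (int)std::ceil (std::max(ua, std::max(ub, uc)));
    int y0 = (int)std::floor(std::min(va, std::min(vb, vc)));
    int y1 = (int)std::ceil (std::max(va, std::max(vb, vc)));
    if (x0 < 0) x0 = 0; if (y0 < 0) y0 = 0;
    if (x1 > width - 1)  x1 = width - 1;
    if (y1 > height - 1) y1 = height - 1;
    if (x0 > x1 || y0 > y1) continue;
    const double area2 = (ub-ua)*(vc-va) - (uc-ua)*(vb-va);
    if (std::fabs(area2) < 1e-14) continue;
    // triangle plane normal (winding orientation) and offset
    const double e1x = bx-ax, e1y = by-ay, e1z = bz-az;
    const double e2x = cx-ax, e2y = cy-ay, e2z = cz-az;
    const double nx = e1y*e2z - e1z*e2y;
    const double ny = e1z*e2x - e1x*e2z;
    const double nz = e1x*e2y - e1y*e2x;
    const double na = nx*ax + ny*ay + nz*az;
    for (int py = y0; py <= y1; ++py) {
      const double sy = py + PX_OFF_Y;
      for (int px = x0; px <= x1; ++px) {
        const double sx = px + PX_OFF_X;
        const double w0 = (ub-ua)*(sy-va) - (sx-ua)*(vb-va);
        const double w1 = (uc-ub)*(sy-vb) - (sx-ub)*(vc-vb);
        const double w2 = (ua-uc)*(sy-vc) - (sx-uc)*(va-vc);
        const bool inside = (area2 > 0.0)
          ? (w0 >= 0.0 && w1 >= 0.0 && w2 >= 0.0)
          : (w0 <= 0.0 && w1 <= 0.0 && w2 <= 0.0);
        if (!inside) continue;
        // ray through the pixel sample, in mm
        const double dx = (sx - ppx) * pitch;
        const double dy = (sy - ppy) * pitch;
        const double dz = sid;
        const double nd = nx*dx + ny*dy + nz*dz;
        if (std::fabs(nd) < 1e-14) continue;  // grazing
        const double tpar = na / nd;
        if (tpar <= 0.0) continue;
        const double dist = tpar * std::sqrt(dx*dx + dy*dy + dz*dz);
        out(py, px) += (nd > 0.0 ? dist : -dist);
      }
    }
  }
  for (int i = 0; i < out.size(); ++i) if (out[i] < 0.0) out[i] = 0.0;
  return out;
}

static inline int reflect_idx(int i, int n) {
  // symmetric boundary: ...2 1 0 | 0 1 2 ... n-1 | n-1 n-2...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2*n - i - 1;
  }
  return i;
}

// Separable convolution with odd-length 1-D kernels (vertical kv then
// horizontal kh), symmetric padding.  Column-major pointer walks keep
// this fast enough for the optimization hot loop.
// [[Rcpp::export]]
NumericMatrix conv_sep_cpp(NumericMatrix mat, NumericVector kv,
                           NumericVector kh) {
  const int nr = mat.nrow(), nc = mat.ncol();
  const int nkv = kv.size(), nkh = kh.size();
  const int rv = (nkv - 1) / 2, rh = (nkh - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double* kvp = kv.begin();
  const double* khp = kh.begin();
  for (int j = 0; j < nc; ++j) {        // vertical pass, per column
    const double* src = &mat[(size_t)j * nr];
    double* dst = &tmp[(size_t)j * nr];
    const int lo = rv, hi = nr - rv;
    for (int i = 0; i < lo && i < nr; ++i) {
      double s = 0.0;
      for (int q = 0; q < nkv; ++q) s += kvp[q] * src[reflect_idx(i + q - rv, nr)];
      dst[i] = s;
    }
    for (int i = lo; i < hi; ++i) {
      double s = 0.0;
      const double* sp = src + i - rv;
      for (int q = 0; q < nkv; ++q) s += kvp[q] * sp[q];
      dst[i] = s;
    }
    for (int i = hi > lo ? hi : lo; i < nr; ++i) {
      double s = 0.0;
      for (int q = 0; q < nkv; ++q) s += kvp[q] * src[reflect_idx(i + q - rv, nr)];
      dst[i] = s;
    }
  }
  for (int j = 0; j < nc; ++j) {        // horizontal pass, axpy columns
    double* dst = &out[(size_t)j * nr];
    for (int q = 0; q < nkh; ++q) {
      const int jj = reflect_idx(j + q - rh, nc);
      const double w = khp[q];
      const double* src = &tmp[(size_t)jj * nr];
      for (int i = 0; i < nr; ++i) dst[i] += w * src[i];
    }
  }
  return out;
}

// Bilateral filter: Gaussian in space (sigma_s px) and intensity (sigma_r).
// [[Rcpp::export]]
NumericMatrix bilateral_cpp(NumericMatrix img, double sigma_s, double sigma_r,
                            int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const double ws = -0.5 / (sigma_s * sigma_s);
  const double wr = -0.5 / (sigma_r * sigma_r);
  std::vector<double> gs((2*radius+1) * (2*radius+1));
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      gs[(dy+radius)*(2*radius+1) + dx+radius] = std::exp(ws * (dx*dx + dy*dy));
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      const double c = img(i, j);
      double acc = 0.0, wacc = 0.0;
      for (int dy = -radius; dy <= radius; ++dy) {
        const int ii = reflect_idx(i + dy, nr);
        for (int dx = -radius; dx <= radius; ++dx) {
          const int jj = reflect_idx(j + dx, nc);
          const double d = img(ii, jj) - c;
          const double w = gs[(dy+radius)*(2*radius+1) + dx+radius] *
                           std::exp(wr * d * d);
          acc += w * img(ii, jj);
          wacc += w;
        }
      }
      out(i, j) = acc / wacc;
    }
  return out;
}

// Contour-band homogeneity statistics.  band: 1 = interior band pixel,
// 2 = exterior band pixel, 0 = neither.  For each band pixel the mean
// absolute deviation of img over its (2r+1)^2 window restricted to the
// same side (inside/outside per `inside` mask) is accumulated.
// Returns c(sum_in, count_in, sum_out, count_out).
// [[Rcpp::export]]
NumericVector band_mad_cpp(NumericMatrix img, IntegerMatrix inside,
                           IntegerMatrix band, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  double sin_ = 0.0, sout = 0.0;
  int cin = 0, cout_ = 0;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      const int b = band(i, j);
      if (b == 0) continue;
      const int want = (b == 1) ? 1 : 0;
      double m = 0.0; int n = 0;
      for (int dy = -radius; dy <= radius; ++dy) {
        const int ii = i + dy; if (ii < 0 || ii >= nr) continue;
        for (int dx = -radius; dx <= radius; ++dx) {
          const int jj = j + dx; if (jj < 0 || jj >= nc) continue;
          if (inside(ii, jj) == want) { m += img(ii, jj); ++n; }
        }
      }
      if (n == 0) continue;
      m /= n;
      double mad = 0.0;
      for (int dy = -radius; dy <= radius; ++dy) {
        const int ii = i + dy; if (ii < 0 || ii >= nr) continue;
        for (int dx = -radius; dx <= radius; ++dx) {
          const int jj = j + dx; if (jj < 0 || jj >= nc) continue;
          if (inside(ii, jj) == want) mad += std::fabs(img(ii, jj) - m);
        }
      }
      mad /= n;
      if (b == 1) { sin_ += mad; ++cin; } else { sout += mad; ++cout_; }
    }
  return NumericVector::create(sin_, (double)cin, sout, (double)cout_);
}

// ---- triangle-triangle intersection (separating axis test) ----

static inline void cross3(const double a[3], const double b[3], double out[3]) {
  out[0] = a[1]*b[2] - a[2]*b[1];
  out[1] = a[2]*b[0] - a[0]*b[2];
  out[2] = a[0]*b[1] - a[1]*b[0];
}

static bool axis_separates(const double ax[3],
                           const double t1[3][3], const double t2[3][3],
                           double tol) {
  const double n2 = ax[0]*ax[0] + ax[1]*ax[1] + ax[2]*ax[2];
  if (n2 < 1e-18) return false;  // degenerate axis, no information
  double mn1 = 1e300, mx1 = -1e300, mn2 = 1e300, mx2 = -1e300;
  for (int k = 0; k < 3; ++k) {
    double p1 = ax[0]*t1[k][0] + ax[1]*t1[k][1] + ax[2]*t1[k][2];
    double p2 = ax[0]*t2[k][0] + ax[1]*t2[k][1] + ax[2]*t2[k][2];
    if (p1 < mn1) mn1 = p1; if (p1 > mx1) mx1 = p1;
    if (p2 < mn2) mn2 = p2; if (p2 > mx2) mx2 = p2;
  }
  const double eps = tol * std::sqrt(n2);
  return (mx1 < mn2 - eps) || (mx2 < mn1 - eps);
}

static bool tri_tri_overlap(const double t1[3][3], const double t2[3][3],
                            double tol) {
  double e1[3][3], e2[3][3], n1[3], n2[3], ax[3];
  for (int k = 0; k < 3; ++k)
    for (int d = 0; d < 3; ++d) {
      e1[k][d] = t1[(k+1)%3][d] - t1[k][d];
      e2[k][d] = t2[(k+1)%3][d] - t2[k][d];
    }
  cross3(e1[0], e1[1], n1);
  cross3(e2[0], e2[1], n2);
  if (axis_separates(n1, t1, t2, tol)) return false;
  if (axis_separates(n2, t1, t2, tol)) return false;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      cross3(e1[i], e2[j], ax);
      if (axis_separates(ax, t1, t2, tol)) return false;
    }
  // in-plane axes for (near-)coplanar configurations
  for (int i = 0; i < 3; ++i) {
    cross3(n1, e1[i], ax);
    if (axis_separates(ax, t1, t2, tol)) return false;
    cross3(n1, e2[i], ax);
    if (axis_separates(ax, t1, t2, tol)) return false;
  }
  return true;
}

// TRUE if any triangle of mesh 1 intersects any triangle of mesh 2.
// Brute force with per-pair bounding-box rejection; reference oracle for
// the fast paired-vertex collision test.
// [[Rcpp::export]]
bool meshes_intersect_cpp(NumericMatrix V1, IntegerMatrix F1,
                          NumericMatrix V2, IntegerMatrix F2, double tol) {
  const int n1 = F1.nrow(), n2 = F2.nrow();
  std::vector<double> bb1(n1 * 6), bb2(n2 * 6);
  for (int t = 0; t < n1; ++t)
    for (int d = 0; d < 3; ++d) {
      double a = V1(F1(t,0), d), b = V1(F1(t,1), d), c = V1(F1(t,2), d);
      bb1[t*6 + d]     = std::min(a, std::min(b, c)) - tol;
      bb1[t*6 + 3 + d] = std::max(a, std::max(b, c)) + tol;
    }
  for (int t = 0; t < n2; ++t)
    for (int d = 0; d < 3; ++d) {
      double a = V2(F2(t,0), d), b = V2(F2(t,1), d), c = V2(F2(t,2), d);
      bb2[t*6 + d]     = std::min(a, std::min(b, c)) - tol;
      bb2[t*6 + 3 + d] = std::max(a, std::max(b, c)) + tol;
    }
  double t1[3][3], t2[3][3];
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n2; ++j) {
      bool rej = false;
      for (int d = 0; d < 3; ++d)
        if (bb1[i*6+3+d] < bb2[j*6+d] || bb2[j*6+3+d] < bb1[i*6+d]) {
          rej = true; break;
        }
      if (rej) continue;
      for (int k = 0; k < 3; ++k)
        for (int d = 0; d < 3; ++d) {
          t1[k][d] = V1(F1(i,k), d);
          t2[k][d] = V2(F2(j,k), d);
        }
      if (tri_tri_overlap(t1, t2, tol)) return true;
    }
  }
  return false;
}

// closest point on triangle (Ericson, Real-Time Collision Detection)
static double point_tri_dist2(const double p[3], const double a[3],
                              const double b[3], const double c[3]) {
  double ab[3], ac[3], ap[3], bp[3], cp[3];
  for (int d = 0; d < 3; ++d) {
    ab[d] = b[d]-a[d]; ac[d] = c[d]-a[d]; ap[d] = p[d]-a[d];
  }
  const double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  const double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) { q[0]=a[0]; q[1]=a[1]; q[2]=a[2]; goto done; }
  {
    for (int d = 0; d < 3; ++d) bp[d] = p[d]-b[d];
    const double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
    const double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) { q[0]=b[0]; q[1]=b[1]; q[2]=b[2]; goto done; }
    const double vc = d1*d4 - d3*d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
      const double v = d1 / (d1 - d3);
      for (int d = 0; d < 3; ++d) q[d] = a[d] + v*ab[d];
      goto done;
    }
    for (int d = 0; d < 3; ++d) cp[d] = p[d]-c[d];
    const double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
    const double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
    if (d6 >= 0.0 && d5 <= d6) { q[0]=c[0]; q[1]=c[1]; q[2]=c[2]; goto done; }
    const double vb = d5*d2 - d1*d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
      const double w = d2 / (d2 - d6);
      for (int d = 0; d < 3; ++d) q[d] = a[d] + w*ac[d];
      goto done;
    }
    const double va = d3*d6 - d5*d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
      const double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      for (int d = 0; d < 3; ++d) q[d] = b[d] + w*(c[d]-b[d]);
      goto done;
    }
    {
      const double denom = 1.0 / (va + vb + vc);
      const double v = vb * denom, w = vc * denom;
      for (int d = 0; d < 3; ++d) q[d] = a[d] + ab[d]*v + ac[d]*w;
    }
  }
done:
  const double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

// Per-point distance from query points Q to the surface (triangles F of V).
// [[Rcpp::export]]
NumericVector surface_dist_cpp(NumericMatrix Q, NumericMatrix V,
                               IntegerMatrix F) {
  const int nq = Q.nrow(), nf = F.nrow();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    const double p[3] = { Q(i,0), Q(i,1), Q(i,2) };
    double best = 1e300;
    for (int t = 0; t < nf; ++t) {
      const double a[3] = { V(F(t,0),0), V(F(t,0),1), V(F(t,0),2) };
      const double b[3] = { V(F(t,1),0), V(F(t,1),1), V(F(t,1),2) };
      const double c[3] = { V(F(t,2),0), V(F(t,2),1), V(F(t,2),2) };
      const double d2 = point_tri_dist2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
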