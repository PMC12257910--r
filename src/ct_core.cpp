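// Ray-driven CT physics: scan geometry, ray generation, Beer-Lambert line
// integrals with (bi/tri)linear in-volume sampling, and weighted
// backprojection for fan-beam FBP and cone-beam FDK.
//
// Conventions (shared with the R layer):
//   * iso-center at the volume center; voxel (i,j,k) center at
//     ((i+0.5) - n/2) * voxel_size on each axis, 0-based indices;
//   * view angle beta = angle_start + view * angle_span / n_views;
//     source at SO*(cos b, sin b, 0), detector centered opposite the source
//     at distance SD from it, u along (-sin b, cos b, 0), v along +z;
//   * projection arrays are dim (n_views, n_rows, n_cols), R column-major.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Geom {
  bool fan2d;
  double SO, SD;
  int nviews;
  double ang0, angspan;
  int ncols, nrows;
  double pitch;
  int nx, ny, nz;
  double vx, vy, vz;
};

static Geom parse_geom(const List& g) {
  Geom G;
  std::string mode = as<std::string>(g["mode"]);
  G.fan2d = (mode == "fanbeam2d");
  G.SO = as<double>(g["source_to_iso_mm"]);
  G.SD = as<double>(g["source_to_detector_mm"]);
  G.nviews = as<int>(g["n_views"]);
  G.ang0 = as<double>(g["angle_start"]);
  G.angspan = as<double>(g["angle_span"]);
  G.ncols = as<int>(g["detector_cols"]);
  G.nrows = as<int>(g["detector_rows"]);
  G.pitch = as<double>(g["pixel_pitch_mm"]);
  IntegerVector vs = g["volume_shape"];
  G.nx = vs[0]; G.ny = vs[1]; G.nz = vs[2];
  NumericVector vox = g["voxel_size_mm"];
  G.vx = vox[0]; G.vy = vox[1]; G.vz = vox[2];
  return G;
}

// entry/exit parameters of ray o + t*d against the volume bounding box;
// returns false (and tn=tf=0) on a miss.  tn is clamped to >= 0.
static bool ray_box(const Geom& G, const double o[3], const double d[3],
                    double& tn, double& tf) {
  double hx = 0.5 * G.nx * G.vx, hy = 0.5 * G.ny * G.vy, hz = 0.5 * G.nz * G.vz;
  double lo[3] = {-hx, -hy, -hz}, hi[3] = {hx, hy, hz};
  tn = 0.0; tf = std::numeric_limits<double>::infinity();
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      if (o[a] < lo[a] || o[a] > hi[a]) { tn = tf = 0.0; return false; }
    } else {
      double t1 = (lo[a] - o[a]) / d[a], t2 = (hi[a] - o[a]) / d[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tn) tn = t1;
      if (t2 < tf) tf = t2;
    }
  }
  if (tf <= tn) { tn = tf = 0.0; return false; }
  return true;
}

static inline void view_frame(const Geom& G, int view, double src[3],
                              double uhat[3], double vhat[3], double what[3]) {
  double b = G.ang0 + G.angspan * (double)view / (double)G.nviews;
  double cb = std::cos(b), sb = std::sin(b);
  src[0] = G.SO * cb; src[1] = G.SO * sb; src[2] = 0.0;
  uhat[0] = -sb; uhat[1] = cb; uhat[2] = 0.0;
  vhat[0] = 0.0; vhat[1] = 0.0; vhat[2] = 1.0;
  what[0] = -cb; what[1] = -sb; what[2] = 0.0;
}

static inline void pixel_ray(const Geom& G, int view, int row, int col,
                             double o[3], double d[3]) {
  double src[3], uhat[3], vhat[3], what[3];
  view_frame(G, view, src, uhat, vhat, what);
  double uc = ((col + 0.5) - 0.5 * G.ncols) * G.pitch;
  double vc = ((row + 0.5) - 0.5 * G.nrows) * G.pitch;
  double nrm = 0.0;
  for (int a = 0; a < 3; ++a) {
    o[a] = src[a];
    d[a] = G.SD * what[a] + uc * uhat[a] + vc * vhat[a];
    nrm += d[a] * d[a];
  }
  nrm = std::sqrt(nrm);
  for (int a = 0; a < 3; ++a) d[a] /= nrm;
}

// trilinear sample of the attenuation volume at world point p, zero outside
static inline double sample_vol(const double* vol, const Geom& G,
                                double px, double py, double pz) {
  double fx = px / G.vx + 0.5 * G.nx - 0.5;
  double fy = py / G.vy + 0.5 * G.ny - 0.5;
  double fz = (G.nz == 1) ? 0.0 : pz / G.vz + 0.5 * G.nz - 0.5;
  int ix = (int)std::floor(fx), iy = (int)std::floor(fy), iz = (int)std::floor(fz);
  double ax = fx - ix, ay = fy - iy, az = fz - iz;
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz) {
    int kz = iz + dz;
    double wz = dz ? az : 1.0 - az;
    if (kz < 0 || kz >= G.nz || wz == 0.0) continue;
    for (int dy = 0; dy < 2; ++dy) {
      int ky = iy + dy;
      double wy = dy ? ay : 1.0 - ay;
      if (ky < 0 || ky >= G.ny || wy == 0.0) continue;
      for (int dx = 0; dx < 2; ++dx) {
        int kx = ix + dx;
        double wx = dx ? ax : 1.0 - ax;
        if (kx < 0 || kx >= G.nx || wx == 0.0) continue;
        acc += wx * wy * wz * vol[kx + (size_t)G.nx * (ky + (size_t)G.ny * kz)];
      }
    }
  }
  return acc;
}

static inline double march_ray(const double* vol, const Geom& G,
                               const double o[3], const double d[3],
                               double tn, double tf, double step) {
  if (tf <= tn) return 0.0;
  double len = tf - tn;
  int n = std::max(2, (int)std::ceil(len / step));
  double dl = len / n;
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double t = tn + (i + 0.5) * dl;
    acc += sample_vol(vol, G, o[0] + t * d[0], o[1] + t * d[1], o[2] + t * d[2]);
  }
  return acc * dl;
}

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, List geom, double step_mm) {
  Geom G = parse_geom(geom);
  if ((R_xlen_t)G.nx * G.ny * G.nz != vol.size())
    stop("volume size does not match geometry");
  NumericVector out((R_xlen_t)G.nviews * G.nrows * G.ncols);
  const double* v = REAL(vol);
  double* po = REAL(out);
  for (int col = 0; col < G.ncols; ++col) {
    for (int row = 0; row < G.nrows; ++row) {
      for (int view = 0; view < G.nviews; ++view) {
        double o[3], d[3], tn, tf;
        pixel_ray(G, view, row, col, o, d);
        double p = 0.0;
        if (ray_box(G, o, d, tn, tf)) p = march_ray(v, G, o, d, tn, tf, step_mm);
        po[view + (size_t)G.nviews * (row + (size_t)G.nrows * col)] = p;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(G.nviews, G.nrows, G.ncols);
  return out;
}

// rays for one view (or all views when view < 0), in projection-array
// linear order: view fastest, then row, then col.
// [[Rcpp::export]]
List cpp_rays(List geom, int view) {
  Geom G = parse_geom(geom);
  int v0 = 0, v1 = G.nviews;
  if (view >= 0) { v0 = view; v1 = view + 1; }
  size_t nview = v1 - v0;
  size_t n = nview * G.nrows * G.ncols;
  NumericMatrix origin(n, 3), dir(n, 3);
  NumericVector tnear(n), tfar(n);
  IntegerVector vidx(n), ridx(n), cidx(n);
  for (int col = 0; col < G.ncols; ++col)
    for (int row = 0; row < G.nrows; ++row)
      for (int vv = v0; vv < v1; ++vv) {
        size_t i = (vv - v0) + nview * (row + (size_t)G.nrows * col);
        double o[3], d[3], tn, tf;
        pixel_ray(G, vv, row, col, o, d);
        ray_box(G, o, d, tn, tf);
        for (int a = 0; a < 3; ++a) { origin(i, a) = o[a]; dir(i, a) = d[a]; }
        tnear[i] = tn; tfar[i] = tf;
        vidx[i] = vv; ridx[i] = row; cidx[i] = col;
      }
  return List::create(_["origin"] = origin, _["direction"] = dir,
                      _["t_near"] = tnear, _["t_far"] = tfar,
                      _["view"] = vidx, _["row"] = ridx, _["col"] = cidx);
}

// line integrals for explicitly supplied rays (oracle / prediction plumbing)
// [[Rcpp::export]]
NumericVector cpp_project_rays(NumericVector vol, List geom,
                               NumericMatrix origin, NumericMatrix dir,
                               NumericVector tnear, NumericVector tfar,
                               double step_mm) {
  Geom G = parse_geom(geom);
  R_xlen_t n = origin.nrow();
  NumericVector out(n);
  const double* v = REAL(vol);
  for (R_xlen_t i = 0; i < n; ++i) {
    double o[3] = {origin(i, 0), origin(i, 1), origin(i, 2)};
    double d[3] = {dir(i, 0), dir(i, 1), dir(i, 2)};
    out[i] = march_ray(v, G, o, d, tnear[i], tfar[i], step_mm);
  }
  return out;
}

// weighted backprojection of ramp-filtered, cosine-weighted projections.
// q has dim (n_views, n_rows, n_cols) and is parameterized by detector
// coordinates rescaled to the iso-center plane (u_iso = u * SO/SD).
// Accumulates  (angle_span/n_views)/2 * sum_views q(u_iso, v_iso) / U^2
// with U = L/SO, which for a full 360-degree scan is the standard
// flat-detector fan-beam FBP / FDK backprojection.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector q, List geom) {
  Geom G = parse_geom(geom);
  NumericVector out((R_xlen_t)G.nx * G.ny * G.nz);
  const double* pq = REAL(q);
  double* po = REAL(out);
  double mag = G.SO / G.SD;
  double du = G.pitch * mag, dv = G.pitch * mag;
  double dbeta = G.angspan / G.nviews;
  // per-view trig tables
  std::vector<double> cb(G.nviews), sb(G.nviews);
  for (int v = 0; v < G.nviews; ++v) {
    double b = G.ang0 + G.angspan * (double)v / (double)G.nviews;
    cb[v] = std::cos(b); sb[v] = std::sin(b);
  }
  for (int k = 0; k < G.nz; ++k) {
    double z = ((k + 0.5) - 0.5 * G.nz) * G.vz;
    for (int j = 0; j < G.ny; ++j) {
      double y = ((j + 0.5) - 0.5 * G.ny) * G.vy;
      for (int i = 0; i < G.nx; ++i) {
        double x = ((i + 0.5) - 0.5 * G.nx) * G.vx;
        double acc = 0.0;
        for (int v = 0; v < G.nviews; ++v) {
          double L = G.SO - x * cb[v] - y * sb[v];
          if (L < 1e-6) continue;
          double U = L / G.SO;
          double ui = G.SO * (-x * sb[v] + y * cb[v]) / L;
          double ci = ui / du + 0.5 * G.ncols - 0.5;
          if (ci < 0 || ci > G.ncols - 1) continue;
          int c0 = (int)std::floor(ci);
          int c1 = std::min(c0 + 1, G.ncols - 1);
          double ac = ci - c0;
          double val;
          if (G.nrows == 1) {
            val = (1 - ac) * pq[v + (size_t)G.nviews * (0 + (size_t)G.nrows * c0)] +
                  ac       * pq[v + (size_t)G.nviews * (0 + (size_t)G.nrows * c1)];
          } else {
            double vi = G.SO * z / L;
            double ri = vi / dv + 0.5 * G.nrows - 0.5;
            if (ri < 0 || ri > G.nrows - 1) continue;
            int r0 = (int)std::floor(ri);
            int r1 = std::min(r0 + 1, G.nrows - 1);
            double ar = ri - r0;
            double q00 = pq[v + (size_t)G.nviews * (r0 + (size_t)G.nrows * c0)];
            double q01 = pq[v + (size_t)G.nviews * (r0 + (size_t)G.nrows * c1)];
            double q10 = pq[v + (size_t)G.nviews * (r1 + (size_t)G.nrows * c0)];
            double q11 = pq[v + (size_t)G.nviews * (r1 + (size_t)G.nrows * c1)];
            val = (1 - ar) * ((1 - ac) * q00 + ac * q01) +
                  ar       * ((1 - ac) * q10 + ac * q11);
          }
          acc += val / (U * U);
        }
        po[i + (size_t)G.nx * (j + (size_t)G.ny * k)] = acc * dbeta * 0.5;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(G.nx, G.ny, G.nz);
  return out;
}

// exact squared Euclidean distance transform of a binary mask
// (Felzenszwalb & Huttenlocher two-pass), distances in pixels.
static void edt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix out(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // pass 1: along rows (within each column)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? 0.0 : INF;
    edt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) out(r, c) = d[r];
  }
  // pass 2: along columns
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = out(r, c);
    edt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = std::sqrt(d[c]);
  }
  return out;
}
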