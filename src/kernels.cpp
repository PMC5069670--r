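#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Volumes are R arrays with dim = c(nx, ny, nz); linear index
// x + nx * (y + ny * z), all 0-based here.

// Line-integral projector. For projection a and detector column j the ray
// direction is set by eff_angle(a, j) (radians), so a per-column effective
// angle models the fan-like beam; constant columns give parallel geometry.
// Sample points p(t) = center + s*e_s + t*e_t with e_s = (cos th, sin th),
// e_t = (-sin th, cos th) in the xz-plane, step 1 voxel.
// Returns array [n_angles, ny, det_x] of line integrals (voxel-length units).
// [[Rcpp::export]]
NumericVector cpp_project(NumericVector vol, IntegerVector dim,
                          NumericMatrix eff_angle, int det_x) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int na = eff_angle.nrow();
  if (eff_angle.ncol() != det_x) stop("eff_angle must be n_angles x det_x");
  double cx = (nx - 1) / 2.0, cz = (nz - 1) / 2.0;
  double cdet = (det_x - 1) / 2.0;
  int tmax = (int)std::ceil(std::sqrt((double)nx * nx + (double)nz * nz) / 2.0) + 1;
  NumericVector out((size_t)na * ny * det_x);
  const double* v = vol.begin();
  double* o = out.begin();
  for (int a = 0; a < na; ++a) {
    for (int j = 0; j < det_x; ++j) {
      double th = eff_angle(a, j);
      double cth = std::cos(th), sth = std::sin(th);
      double s = j - cdet;
      double bx = cx + s * cth, bz = cz + s * sth;
      for (int t = -tmax; t <= tmax; ++t) {
        double x = bx - t * sth;
        double z = bz + t * cth;
        if (x <= -1 || z <= -1 || x >= nx || z >= nz) continue;
        int x0 = (int)std::floor(x), z0 = (int)std::floor(z);
        double fx = x - x0, fz = z - z0;
        double w00 = (1 - fx) * (1 - fz), w10 = fx * (1 - fz);
        double w01 = (1 - fx) * fz, w11 = fx * fz;
        bool x0ok = x0 >= 0 && x0 < nx, x1ok = x0 + 1 >= 0 && x0 + 1 < nx;
        bool z0ok = z0 >= 0 && z0 < nz, z1ok = z0 + 1 >= 0 && z0 + 1 < nz;
        for (int y = 0; y < ny; ++y) {
          double acc = 0.0;
          size_t base0 = (size_t)nx * (y + (size_t)ny * z0);
          size_t base1 = (size_t)nx * (y + (size_t)ny * (z0 + 1));
          if (z0ok) {
            if (x0ok) acc += w00 * v[x0 + base0];
            if (x1ok) acc += w10 * v[x0 + 1 + base0];
          }
          if (z1ok) {
            if (x0ok) acc += w01 * v[x0 + base1];
            if (x1ok) acc += w11 * v[x0 + 1 + base1];
          }
          o[a + (size_t)na * (y + (size_t)ny * j)] += acc;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(na, ny, det_x);
  return out;
}

// Backproject one filtered sinogram slice [n_angles, det_x] onto an
// out_size^2 image (xz-plane), linear interpolation along the detector.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix filt, NumericVector theta,
                              int out_size, bool circle) {
  int na = filt.nrow(), det_x = filt.ncol();
  double c = (out_size - 1) / 2.0, cdet = (det_x - 1) / 2.0;
  double r2 = (out_size / 2.0) * (out_size / 2.0);
  NumericMatrix out(out_size, out_size); // [x, z]
  for (int a = 0; a < na; ++a) {
    double cth = std::cos(theta[a]), sth = std::sin(theta[a]);
    for (int iz = 0; iz < out_size; ++iz) {
      double dz = iz - c;
      for (int ix = 0; ix < out_size; ++ix) {
        double dx = ix - c;
        if (circle && dx * dx + dz * dz > r2) continue;
        double s = dx * cth + dz * sth + cdet;
        if (s <= -1 || s >= det_x) continue;
        int s0 = (int)std::floor(s);
        double fs = s - s0;
        double val = 0.0;
        if (s0 >= 0) val += (1 - fs) * filt(a, s0);
        if (s0 + 1 < det_x) val += fs * filt(a, s0 + 1);
        out(ix, iz) += val;
      }
    }
  }
  return out;
}

// As cpp_backproject but with nearest-neighbour detector sampling,
// for exactness experiments.
// [[Rcpp::export]]
NumericMatrix cpp_backproject_nearest(NumericMatrix filt, NumericVector theta,
                                      int out_size, bool circle) {
  int na = filt.nrow(), det_x = filt.ncol();
  double c = (out_size - 1) / 2.0, cdet = (det_x - 1) / 2.0;
  double r2 = (out_size / 2.0) * (out_size / 2.0);
  NumericMatrix out(out_size, out_size);
  for (int a = 0; a < na; ++a) {
    double cth = std::cos(theta[a]), sth = std::sin(theta[a]);
    for (int iz = 0; iz < out_size; ++iz) {
      double dz = iz - c;
      for (int ix = 0; ix < out_size; ++ix) {
        double dx = ix - c;
        if (circle && dx * dx + dz * dz > r2) continue;
        int s = (int)std::lround(dx * cth + dz * sth + cdet);
        if (s < 0 || s >= det_x) continue;
        out(ix, iz) += filt(a, s);
      }
    }
  }
  return out;
}

// Affine resample: for each output voxel o (0-based), input coordinate
// p = A %*% (o - c_out) + c_in; trilinear (method 0) or nearest (method 1).
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector vol, IntegerVector dim,
                             NumericMatrix A, NumericVector c_in,
                             NumericVector c_out, IntegerVector out_dim,
                             int method) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((size_t)ox * oy * oz);
  const double* v = vol.begin();
  double* o = out.begin();
  for (int k = 0; k < oz; ++k) {
    double wz = k - c_out[2];
    for (int j = 0; j < oy; ++j) {
      double wy = j - c_out[1];
      for (int i = 0; i < ox; ++i) {
        double wx = i - c_out[0];
        double px = A(0, 0) * wx + A(0, 1) * wy + A(0, 2) * wz + c_in[0];
        double py = A(1, 0) * wx + A(1, 1) * wy + A(1, 2) * wz + c_in[1];
        double pz = A(2, 0) * wx + A(2, 1) * wy + A(2, 2) * wz + c_in[2];
        double val = 0.0;
        if (method == 1) {
          int xi = (int)std::lround(px), yi = (int)std::lround(py),
              zi = (int)std::lround(pz);
          if (xi >= 0 && xi < nx && yi >= 0 && yi < ny && zi >= 0 && zi < nz)
            val = v[xi + (size_t)nx * (yi + (size_t)ny * zi)];
        } else {
          if (px > -1 && py > -1 && pz > -1 && px < nx && py < ny && pz < nz) {
            int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
                z0 = (int)std::floor(pz);
            double fx = px - x0, fy = py - y0, fz = pz - z0;
            for (int dz = 0; dz <= 1; ++dz) {
              int zz = z0 + dz;
              if (zz < 0 || zz >= nz) continue;
              double wfz = dz ? fz : 1 - fz;
              for (int dy = 0; dy <= 1; ++dy) {
                int yy = y0 + dy;
                if (yy < 0 || yy >= ny) continue;
                double wfy = dy ? fy : 1 - fy;
                for (int dx = 0; dx <= 1; ++dx) {
                  int xx = x0 + dx;
                  if (xx < 0 || xx >= nx) continue;
                  double wfx = dx ? fx : 1 - fx;
                  val += wfz * wfy * wfx *
                         v[xx + (size_t)nx * (yy + (size_t)ny * zz)];
                }
              }
            }
          }
        }
        o[i + (size_t)ox * (j + (size_t)oy * k)] = val;
      }
    }
  }
  out.attr("dim") = out_dim;
  return out;
}

// Trilinear (or nearest) sampling at arbitrary 0-based continuous points.
// pts is n x 3; values outside the volume are 0.
// [[Rcpp::export]]
NumericVector cpp_sample3d(NumericVector vol, IntegerVector dim,
                           NumericMatrix pts, int method) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  for (int p = 0; p < n; ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double val = 0.0;
    if (method == 1) {
      int xi = (int)std::lround(px), yi = (int)std::lround(py),
          zi = (int)std::lround(pz);
      if (xi >= 0 && xi < nx && yi >= 0 && yi < ny && zi >= 0 && zi < nz)
        val = v[xi + (size_t)nx * (yi + (size_t)ny * zi)];
    } else if (px > -1 && py > -1 && pz > -1 && px < nx && py < ny && pz < nz) {
      int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
          z0 = (int)std::floor(pz);
      double fx = px - x0, fy = py - y0, fz = pz - z0;
      for (int dz = 0; dz <= 1; ++dz) {
        int zz = z0 + dz;
        if (zz < 0 || zz >= nz) continue;
        double wfz = dz ? fz : 1 - fz;
        for (int dy = 0; dy <= 1; ++dy) {
          int yy = y0 + dy;
          if (yy < 0 || yy >= ny) continue;
          double wfy = dy ? fy : 1 - fy;
          for (int dx = 0; dx <= 1; ++dx) {
            int xx = x0 + dx;
            if (xx < 0 || xx >= nx) continue;
            double wfx = dx ? fx : 1 - fx;
            val += wfz * wfy * wfx * v[xx + (size_t)nx * (yy + (size_t)ny * zz)];
          }
        }
      }
    }
    out[p] = val;
  }
  return out;
}

struct WsNode {
  double value;
  long long order;
  int index;
  int label;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.value != b.value) return a.value > b.value; // min-heap on value
    return a.order > b.order;                          // FIFO on ties
  }
};

// Marker-based watershed by priority flooding on a gradient image,
// 6-connectivity. Ties broken by insertion order; markers are seeded in
// linear-index order so the lowest-index (hence lowest marker id for
// equal-value fronts seeded together) wins deterministically.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector grad, IntegerVector dim,
                            IntegerVector markers) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector labels(clone(markers));
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long counter = 0;
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  for (size_t i = 0; i < n; ++i) {
    if (labels[i] > 0) pq.push(WsNode{grad[i], counter++, (int)i, labels[i]});
  }
  if (pq.empty()) stop("watershed requires at least one marker voxel");
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    int i = nd.index;
    int z = i / (nx * ny), rem = i % (nx * ny), y = rem / nx, x = rem % nx;
    for (int d = 0; d < 6; ++d) {
      int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      int j = xx + nx * (yy + ny * zz);
      if (labels[j] == 0) {
        labels[j] = nd.label;
        double v = grad[j] > nd.value ? grad[j] : nd.value;
        pq.push(WsNode{v, counter++, j, nd.label});
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// 6-connected component labelling of a logical mask; labels assigned in
// scan order starting at 1.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector labels(n);
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  int next = 0;
  std::vector<int> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    stack.push_back((int)s);
    while (!stack.empty()) {
      int i = stack.back();
      stack.pop_back();
      int z = i / (nx * ny), rem = i % (nx * ny), y = rem / nx, x = rem % nx;
      for (int d = 0; d < 6; ++d) {
        int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int j = xx + nx * (yy + ny * zz);
        if (mask[j] && labels[j] == 0) {
          labels[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}
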