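// Low-level 3D image and network kernels.
// Volumes are R arrays dim (nx, ny, nz), column-major: idx = x + nx*(y + ny*z).
// Network tensors are dim (X, Y, Z, C). All indices 0-based here, 1-based in R.
#include <Rcpp.h>
#include <queue>
#include <map>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 26-neighborhood offsets filtered by connectivity class (6/18/26).
static std::vector<int> neigh_offsets(int conn, int nx, int ny,
                                      std::vector<IntegerVector> &delta) {
  std::vector<int> offs;
  delta.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int d = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (d == 0) continue;
        if (conn == 6 && d > 1) continue;
        if (conn == 18 && d > 2) continue;
        offs.push_back(dx + nx * (dy + ny * dz));
        delta.push_back(IntegerVector::create(dx, dy, dz));
      }
  return offs;
}

// [[Rcpp::export]]
LogicalVector cpp_flood_fill(NumericVector vol, IntegerVector dim,
                             IntegerMatrix seeds, double lo, double hi,
                             int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector mask(n, false);
  std::vector<IntegerVector> delta;
  neigh_offsets(connectivity, nx, ny, delta);
  std::queue<int> q;
  for (int s = 0; s < seeds.nrow(); ++s) {
    int x = seeds(s, 0), y = seeds(s, 1), z = seeds(s, 2); // 0-based
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) continue;
    int idx = x + nx * (y + ny * z);
    double v = vol[idx];
    if (v < lo || v > hi || mask[idx]) continue;
    mask[idx] = true;
    q.push(idx);
  }
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int z = idx / (nx * ny), rem = idx % (nx * ny);
    int y = rem / nx, x = rem % nx;
    for (size_t k = 0; k < delta.size(); ++k) {
      int xx = x + delta[k][0], yy = y + delta[k][1], zz = z + delta[k][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      int j = xx + nx * (yy + ny * zz);
      if (mask[j]) continue;
      double v = vol[j];
      if (v >= lo && v <= hi) { mask[j] = true; q.push(j); }
    }
  }
  return mask;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<IntegerVector> delta;
  neigh_offsets(connectivity, nx, ny, delta);
  int cur = 0;
  std::queue<int> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++cur;
    q.push((int)i);
    while (!q.empty()) {
      int idx = q.front(); q.pop();
      int z = idx / (nx * ny), rem = idx % (nx * ny);
      int y = rem / nx, x = rem % nx;
      for (size_t k = 0; k < delta.size(); ++k) {
        int xx = x + delta[k][0], yy = y + delta[k][1], zz = z + delta[k][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        int j = xx + nx * (yy + ny * zz);
        if (mask[j] && !lab[j]) { lab[j] = cur; q.push(j); }
      }
    }
  }
  return lab;
}

// Morphological dilation with the Euclidean ball {d : ||d||_2 <= radius}.
// [[Rcpp::export]]
LogicalVector cpp_dilate_ball(LogicalVector mask, IntegerVector dim,
                              double radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  int r = (int)std::floor(radius);
  std::vector<int> dxs, dys, dzs;
  double r2 = radius * radius;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if ((double)dx * dx + (double)dy * dy + (double)dz * dz <= r2) {
          dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
        }
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int z = (int)(i / (nx * ny)), rem = (int)(i % (nx * ny));
    int y = rem / nx, x = rem % nx;
    for (size_t k = 0; k < dxs.size(); ++k) {
      int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      out[xx + nx * (yy + ny * zz)] = true;
    }
  }
  return out;
}

// Count of integer offsets with ||.||_2 <= radius (lattice ball cardinality).
// [[Rcpp::export]]
double cpp_ball_count(double radius) {
  int r = (int)std::floor(radius);
  double r2 = radius * radius, cnt = 0;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if ((double)dx * dx + (double)dy * dy + (double)dz * dz <= r2) cnt += 1;
  return cnt;
}

// General axis-separable resize: in_index = out_index * scale + offset.
// mode 0 = trilinear (clamped), 1 = nearest.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dim,
                           IntegerVector odim, NumericVector scale,
                           NumericVector offset, int mode) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  for (int z = 0; z < oz; ++z) {
    double fz = z * scale[2] + offset[2];
    for (int y = 0; y < oy; ++y) {
      double fy = y * scale[1] + offset[1];
      for (int x = 0; x < ox; ++x) {
        double fx = x * scale[0] + offset[0];
        double val;
        if (mode == 1) {
          int ix = clampi((int)std::lround(fx), 0, nx - 1);
          int iy = clampi((int)std::lround(fy), 0, ny - 1);
          int iz = clampi((int)std::lround(fz), 0, nz - 1);
          val = vol[ix + nx * (iy + ny * (R_xlen_t)iz)];
        } else {
          double cx = fx < 0 ? 0 : (fx > nx - 1 ? nx - 1 : fx);
          double cy = fy < 0 ? 0 : (fy > ny - 1 ? ny - 1 : fy);
          double cz = fz < 0 ? 0 : (fz > nz - 1 ? nz - 1 : fz);
          int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy),
              z0 = (int)std::floor(cz);
          int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
              z1 = std::min(z0 + 1, nz - 1);
          double tx = cx - x0, ty = cy - y0, tz = cz - z0;
          double c000 = vol[x0 + nx * (y0 + ny * (R_xlen_t)z0)];
          double c100 = vol[x1 + nx * (y0 + ny * (R_xlen_t)z0)];
          double c010 = vol[x0 + nx * (y1 + ny * (R_xlen_t)z0)];
          double c110 = vol[x1 + nx * (y1 + ny * (R_xlen_t)z0)];
          double c001 = vol[x0 + nx * (y0 + ny * (R_xlen_t)z1)];
          double c101 = vol[x1 + nx * (y0 + ny * (R_xlen_t)z1)];
          double c011 = vol[x0 + nx * (y1 + ny * (R_xlen_t)z1)];
          double c111 = vol[x1 + nx * (y1 + ny * (R_xlen_t)z1)];
          double c00 = c000 * (1 - tx) + c100 * tx;
          double c10 = c010 * (1 - tx) + c110 * tx;
          double c01 = c001 * (1 - tx) + c101 * tx;
          double c11 = c011 * (1 - tx) + c111 * tx;
          double c0 = c00 * (1 - ty) + c10 * ty;
          double c1 = c01 * (1 - ty) + c11 * ty;
          val = c0 * (1 - tz) + c1 * tz;
        }
        out[x + ox * (y + oy * (R_xlen_t)z)] = val;
      }
    }
  }
  return out;
}

// Separable Gaussian smoothing, replicate boundary, kernel truncated to
// max_width taps per axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, IntegerVector dim,
                               double sigma, int max_width) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sigma <= 0) return clone(vol);
  int h = (int)std::ceil(4.0 * sigma);
  int hmax = (max_width - 1) / 2;
  if (h > hmax) h = hmax;
  if (h < 1) h = 1;
  std::vector<double> k(2 * h + 1);
  double s = 0;
  for (int i = -h; i <= h; ++i) {
    k[i + h] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + h];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
  NumericVector a = clone(vol), b(n);
  const int dims[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    const int len = dims[axis];
    const int strides[3] = {1, nx, nx * ny};
    const int st = strides[axis];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int pos[3] = {x, y, z};
          R_xlen_t base = x + nx * (y + ny * (R_xlen_t)z);
          double acc = 0;
          for (int i = -h; i <= h; ++i) {
            int p = clampi(pos[axis] + i, 0, len - 1);
            acc += k[i + h] * a[base + (R_xlen_t)(p - pos[axis]) * st];
          }
          b[base] = acc;
        }
    std::swap(a, b);
  }
  return a;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra over the Kuhn (6-tet) decomposition of each grid cube.
// Field values live on voxel centers; iso-surface at `iso`. Vertices are
// deduplicated by the grid edge they lie on, so the mesh is watertight for a
// field whose boundary does not touch the grid border.
// ---------------------------------------------------------------------------
struct VKey {
  int a, b;
  bool operator<(const VKey &o) const {
    return a < o.a || (a == o.a && b < o.b);
  }
};

// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dim,
                    NumericVector spacing, NumericVector origin, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::map<VKey, int> vmap;
  std::vector<double> verts; // x,y,z triples
  std::vector<int> faces;    // 0-based triples
  // six tets along monotone lattice paths from corner 0 to corner 7
  const int tets[6][4] = {{0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
                          {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  const int cdx[8] = {0, 1, 0, 1, 0, 1, 0, 1};
  const int cdy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  const int cdz[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  auto node_id = [&](int x, int y, int z) { return x + nx * (y + ny * z); };
  auto emit_vertex = [&](int na, int nb, double fa, double fb) {
    VKey key = na < nb ? VKey{na, nb} : VKey{nb, na};
    std::map<VKey, int>::iterator it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double t = (iso - fa) / (fb - fa);
    if (na > nb) t = 1.0 - t; // parameterize along the canonical direction
    int a = key.a, b = key.b;
    int az = a / (nx * ny), ar = a % (nx * ny), ay = ar / nx, ax = ar % nx;
    int bz = b / (nx * ny), br = b % (nx * ny), by = br / nx, bx = br % nx;
    double px = origin[0] + spacing[0] * (ax + t * (bx - ax));
    double py = origin[1] + spacing[1] * (ay + t * (by - ay));
    double pz = origin[2] + spacing[2] * (az + t * (bz - az));
    int id = (int)verts.size() / 3;
    verts.push_back(px); verts.push_back(py); verts.push_back(pz);
    vmap[key] = id;
    return id;
  };
  auto tri = [&](int v0, int v1, int v2, const double *inw, const double *outw) {
    // orient so the normal points from the inside toward the outside
    double ax = verts[3 * v1] - verts[3 * v0];
    double ay = verts[3 * v1 + 1] - verts[3 * v0 + 1];
    double az = verts[3 * v1 + 2] - verts[3 * v0 + 2];
    double bx = verts[3 * v2] - verts[3 * v0];
    double by = verts[3 * v2 + 1] - verts[3 * v0 + 1];
    double bz = verts[3 * v2 + 2] - verts[3 * v0 + 2];
    double nxv = ay * bz - az * by, nyv = az * bx - ax * bz,
           nzv = ax * by - ay * bx;
    double dot = nxv * (outw[0] - inw[0]) + nyv * (outw[1] - inw[1]) +
                 nzv * (outw[2] - inw[2]);
    if (dot >= 0) {
      faces.push_back(v0); faces.push_back(v1); faces.push_back(v2);
    } else {
      faces.push_back(v0); faces.push_back(v2); faces.push_back(v1);
    }
  };
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        int nid[8]; double f[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          nid[c] = node_id(x + cdx[c], y + cdy[c], z + cdz[c]);
          f[c] = field[nid[c]];
          if (f[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4]; double fv[4]; bool in[4]; int nin = 0;
          for (int c = 0; c < 4; ++c) {
            vi[c] = tets[t][c];
            fv[c] = f[vi[c]];
            in[c] = fv[c] > iso;
            if (in[c]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          // world centroids of inside / outside corners for orientation
          double inw[3] = {0, 0, 0}, outw[3] = {0, 0, 0};
          int cin = 0, cout = 0;
          for (int c = 0; c < 4; ++c) {
            double w[3] = {
              origin[0] + spacing[0] * (x + cdx[vi[c]]),
              origin[1] + spacing[1] * (y + cdy[vi[c]]),
              origin[2] + spacing[2] * (z + cdz[vi[c]])};
            if (in[c]) { for (int d = 0; d < 3; ++d) inw[d] += w[d]; ++cin; }
            else { for (int d = 0; d < 3; ++d) outw[d] += w[d]; ++cout; }
          }
          for (int d = 0; d < 3; ++d) { inw[d] /= cin; outw[d] /= cout; }
          int A = -1, B = -1, C = -1, D = -1;
          if (nin == 1 || nin == 3) {
            bool want = (nin == 1);
            for (int c = 0; c < 4; ++c)
              if (in[c] == want) A = c;
            int others[3], k = 0;
            for (int c = 0; c < 4; ++c)
              if (c != A) others[k++] = c;
            int e0 = emit_vertex(nid[vi[A]], nid[vi[others[0]]], fv[A],
                                 fv[others[0]]);
            int e1 = emit_vertex(nid[vi[A]], nid[vi[others[1]]], fv[A],
                                 fv[others[1]]);
            int e2 = emit_vertex(nid[vi[A]], nid[vi[others[2]]], fv[A],
                                 fv[others[2]]);
            tri(e0, e1, e2, inw, outw);
          } else { // nin == 2
            int k = 0, m = 0;
            int ins[2], outs[2];
            for (int c = 0; c < 4; ++c)
              (in[c] ? ins[k++] : outs[m++]) = c;
            A = ins[0]; B = ins[1]; C = outs[0]; D = outs[1];
            int eAC = emit_vertex(nid[vi[A]], nid[vi[C]], fv[A], fv[C]);
            int eAD = emit_vertex(nid[vi[A]], nid[vi[D]], fv[A], fv[D]);
            int eBD = emit_vertex(nid[vi[B]], nid[vi[D]], fv[B], fv[D]);
            int eBC = emit_vertex(nid[vi[B]], nid[vi[C]], fv[B], fv[C]);
            tri(eAC, eAD, eBD, inw, outw);
            tri(eAC, eBD, eBC, inw, outw);
          }
        }
      }
  NumericMatrix V(verts.size() / 3, 3);
  for (size_t i = 0; i < verts.size() / 3; ++i) {
    V(i, 0) = verts[3 * i]; V(i, 1) = verts[3 * i + 1];
    V(i, 2) = verts[3 * i + 2];
  }
  IntegerMatrix F(faces.size() / 3, 3);
  for (size_t i = 0; i < faces.size() / 3; ++i) {
    F(i, 0) = faces[3 * i] + 1; F(i, 1) = faces[3 * i + 1] + 1;
    F(i, 2) = faces[3 * i + 2] + 1; // 1-based for R
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// 3D convolution kernels for the detection network.
// Tensor layout: dim (X, Y, Z, C) column-major.
// Weights: dim (k, k, k, Cin, Cout); "same" padding p = (k-1)/2.
// ---------------------------------------------------------------------------

// Valid output range [lo, hi) along one axis for a given kernel offset:
// input index = out * stride + koff - p must lie in [0, len).
static inline void axis_range(int len, int olen, int stride, int koff, int p,
                              int &lo, int &hi) {
  int shift = koff - p;
  lo = 0;
  while (lo < olen && lo * stride + shift < 0) ++lo;
  hi = olen;
  while (hi > lo && (hi - 1) * stride + shift >= len) --hi;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector input, IntegerVector idim,
                             NumericVector w, NumericVector bias, int k,
                             int stride) {
  const int X = idim[0], Y = idim[1], Z = idim[2], Cin = idim[3];
  const int Cout = bias.size();
  const int p = (k - 1) / 2;
  const int Xo = (X + 2 * p - k) / stride + 1;
  const int Yo = (Y + 2 * p - k) / stride + 1;
  const int Zo = (Z + 2 * p - k) / stride + 1;
  NumericVector out((R_xlen_t)Xo * Yo * Zo * Cout);
  const double *in = input.begin();
  const double *W = w.begin();
  double *O = out.begin();
  const R_xlen_t splane = (R_xlen_t)X * Y;
  const R_xlen_t svol = splane * Z;
  const R_xlen_t oplane = (R_xlen_t)Xo * Yo;
  const R_xlen_t ovol = oplane * Zo;
  for (int co = 0; co < Cout; ++co) {
    double *oc = O + ovol * co;
    const double b = bias[co];
    for (R_xlen_t i = 0; i < ovol; ++i) oc[i] = b;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *inc = in + ci * svol;
      const double *wc = W + (R_xlen_t)k * k * k * (ci + (R_xlen_t)Cin * co);
      for (int kz = 0; kz < k; ++kz) {
        int zlo, zhi; axis_range(Z, Zo, stride, kz, p, zlo, zhi);
        for (int ky = 0; ky < k; ++ky) {
          int ylo, yhi; axis_range(Y, Yo, stride, ky, p, ylo, yhi);
          for (int kx = 0; kx < k; ++kx) {
            int xlo, xhi; axis_range(X, Xo, stride, kx, p, xlo, xhi);
            const double wv = wc[kx + k * (ky + k * kz)];
            if (wv == 0) continue;
            for (int zo = zlo; zo < zhi; ++zo) {
              const int z = zo * stride + kz - p;
              for (int yo = ylo; yo < yhi; ++yo) {
                const int y = yo * stride + ky - p;
                const double *row = inc + splane * z + (R_xlen_t)X * y +
                                    (kx - p);
                double *orow = oc + oplane * zo + (R_xlen_t)Xo * yo;
                if (stride == 1) {
                  for (int xo = xlo; xo < xhi; ++xo)
                    orow[xo] += wv * row[xo];
                } else {
                  for (int xo = xlo; xo < xhi; ++xo)
                    orow[xo] += wv * row[xo * stride];
                }
              }
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Cout);
  return out;
}

// Returns list(gin, gw, gb).
// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector input, IntegerVector idim, NumericVector w,
                    NumericVector gout, int k, int stride, int Cout) {
  const int X = idim[0], Y = idim[1], Z = idim[2], Cin = idim[3];
  const int p = (k - 1) / 2;
  const int Xo = (X + 2 * p - k) / stride + 1;
  const int Yo = (Y + 2 * p - k) / stride + 1;
  const int Zo = (Z + 2 * p - k) / stride + 1;
  NumericVector gin((R_xlen_t)X * Y * Z * Cin);
  NumericVector gw((R_xlen_t)k * k * k * Cin * Cout);
  NumericVector gb(Cout);
  const double *in = input.begin();
  const double *W = w.begin();
  const double *G = gout.begin();
  double *GI = gin.begin();
  double *GW = gw.begin();
  const R_xlen_t splane = (R_xlen_t)X * Y;
  const R_xlen_t svol = splane * Z;
  const R_xlen_t oplane = (R_xlen_t)Xo * Yo;
  const R_xlen_t ovol = oplane * Zo;
  for (int co = 0; co < Cout; ++co) {
    const double *gc = G + ovol * co;
    double bacc = 0;
    for (R_xlen_t i = 0; i < ovol; ++i) bacc += gc[i];
    gb[co] = bacc;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *inc = in + ci * svol;
      double *ginc = GI + ci * svol;
      double *gwc = GW + (R_xlen_t)k * k * k * (ci + (R_xlen_t)Cin * co);
      for (int kz = 0; kz < k; ++kz) {
        int zlo, zhi; axis_range(Z, Zo, stride, kz, p, zlo, zhi);
        for (int ky = 0; ky < k; ++ky) {
          int ylo, yhi; axis_range(Y, Yo, stride, ky, p, ylo, yhi);
          for (int kx = 0; kx < k; ++kx) {
            int xlo, xhi; axis_range(X, Xo, stride, kx, p, xlo, xhi);
            const double wv = W[(R_xlen_t)k * k * k *
                                    (ci + (R_xlen_t)Cin * co) +
                                kx + k * (ky + k * kz)];
            double wacc = 0;
            for (int zo = zlo; zo < zhi; ++zo) {
              const int z = zo * stride + kz - p;
              for (int yo = ylo; yo < yhi; ++yo) {
                const int y = yo * stride + ky - p;
                const double *irow = inc + splane * z + (R_xlen_t)X * y +
                                     (kx - p);
                double *girow = ginc + splane * z + (R_xlen_t)X * y +
                                (kx - p);
                const double *grow = gc + oplane * zo + (R_xlen_t)Xo * yo;
                if (stride == 1) {
                  for (int xo = xlo; xo < xhi; ++xo) {
                    const double g = grow[xo];
                    wacc += irow[xo] * g;
                    girow[xo] += wv * g;
                  }
                } else {
                  for (int xo = xlo; xo < xhi; ++xo) {
                    const double g = grow[xo];
                    wacc += irow[xo * stride] * g;
                    girow[xo * stride] += wv * g;
                  }
                }
              }
            }
            gwc[kx + k * (ky + k * kz)] += wacc;
          }
        }
      }
    }
  }
  gin.attr("dim") = IntegerVector::create(X, Y, Z, Cin);
  gw.attr("dim") = IntegerVector::create(k, k, k, Cin, Cout);
  return List::create(_["gin"] = gin, _["gw"] = gw, _["gb"] = gb);
}

// Nearest-neighbour x2 upsampling along the three spatial axes.
// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector input, IntegerVector idim) {
  const int X = idim[0], Y = idim[1], Z = idim[2], C = idim[3];
  const int X2 = 2 * X, Y2 = 2 * Y, Z2 = 2 * Z;
  NumericVector out((R_xlen_t)X2 * Y2 * Z2 * C);
  const double *in = input.begin();
  double *O = out.begin();
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < Z2; ++z)
      for (int y = 0; y < Y2; ++y) {
        const double *row =
            in + ((R_xlen_t)X * ((y / 2) + (R_xlen_t)Y * ((z / 2) + (R_xlen_t)Z * c)));
        double *orow =
            O + ((R_xlen_t)X2 * (y + (R_xlen_t)Y2 * (z + (R_xlen_t)Z2 * c)));
        for (int x = 0; x < X2; ++x) orow[x] = row[x / 2];
      }
  out.attr("dim") = IntegerVector::create(X2, Y2, Z2, C);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gout, IntegerVector odim) {
  const int X2 = odim[0], Y2 = odim[1], Z2 = odim[2], C = odim[3];
  const int X = X2 / 2, Y = Y2 / 2, Z = Z2 / 2;
  NumericVector gin((R_xlen_t)X * Y * Z * C);
  const double *G = gout.begin();
  double *GI = gin.begin();
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < Z2; ++z)
      for (int y = 0; y < Y2; ++y) {
        double *irow =
            GI + ((R_xlen_t)X * ((y / 2) + (R_xlen_t)Y * ((z / 2) + (R_xlen_t)Z * c)));
        const double *grow =
            G + ((R_xlen_t)X2 * (y + (R_xlen_t)Y2 * (z + (R_xlen_t)Z2 * c)));
        for (int x = 0; x < X2; ++x) irow[x / 2] += grow[x];
      }
  gin.attr("dim") = IntegerVector::create(X, Y, Z, C);
  return gin;
}
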