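#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Linear index into an R array of dim (d1, d2, d3), 0-based i/j/k.
static inline R_xlen_t lin(int i, int j, int k, int d1, int d2) {
  return (R_xlen_t)i + (R_xlen_t)d1 * ((R_xlen_t)j + (R_xlen_t)d2 * (R_xlen_t)k);
}

// Marching tetrahedra over a 3D scalar array. Each cell is split into six
// tetrahedra around the main diagonal; face diagonals match between
// neighbouring cells so the extracted surface is crack-free. Vertices are
// returned in fractional (1-based) array-index coordinates; de-duplicated
// by the global edge they sit on.
// [[Rcpp::export]]
List march_tets_cpp(NumericVector vol, IntegerVector dims, double level) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  // cube corner offsets in (i, j, k)
  static const int off[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}
  };
  // six tetrahedra sharing the 0-7 diagonal
  static const int tets[6][4] = {
    {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}
  };
  std::vector<double> verts;          // x1,x2,x3 per vertex (index coords)
  std::vector<int> tris;              // 1-based vertex ids
  std::unordered_map<uint64_t, int> edge_id;
  const double *v = REAL(vol);

  R_xlen_t n_total = (R_xlen_t)d1 * d2 * d3;
  auto edge_vertex = [&](R_xlen_t ga, R_xlen_t gb, double va, double vb,
                         const int pa[3], const int pb[3],
                         int ci, int cj, int ck) -> int {
    uint64_t a = (uint64_t)ga, b = (uint64_t)gb;
    if (a > b) { std::swap(a, b); std::swap(va, vb);
                 const int *tmp = pa; pa = pb; pb = tmp; }
    uint64_t key = a * (uint64_t)n_total + b;
    auto it = edge_id.find(key);
    if (it != edge_id.end()) return it->second;
    double t = (vb == va) ? 0.5 : (level - va) / (vb - va);
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
    // recover 0-based corner coords from global indices
    int ia = (int)(a % d1), ja = (int)((a / d1) % d2), ka = (int)(a / ((R_xlen_t)d1 * d2));
    int ib = (int)(b % d1), jb = (int)((b / d1) % d2), kb = (int)(b / ((R_xlen_t)d1 * d2));
    (void)pa; (void)pb; (void)ci; (void)cj; (void)ck;
    verts.push_back(1.0 + ia + t * (ib - ia));
    verts.push_back(1.0 + ja + t * (jb - ja));
    verts.push_back(1.0 + ka + t * (kb - ka));
    int id = (int)(verts.size() / 3);   // 1-based
    edge_id.emplace(key, id);
    return id;
  };

  for (int k = 0; k < d3 - 1; ++k) {
    for (int j = 0; j < d2 - 1; ++j) {
      for (int i = 0; i < d1 - 1; ++i) {
        double cv[8];
        R_xlen_t gi[8];
        double lo = R_PosInf, hi = R_NegInf;
        for (int c = 0; c < 8; ++c) {
          gi[c] = lin(i + off[c][0], j + off[c][1], k + off[c][2], d1, d2);
          cv[c] = v[gi[c]];
          if (cv[c] < lo) lo = cv[c];
          if (cv[c] > hi) hi = cv[c];
        }
        if (lo > level || hi <= level) continue;  // no crossing in this cell
        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          int in[4], nin = 0;
          for (int c = 0; c < 4; ++c) {
            in[c] = cv[T[c]] > level;
            nin += in[c];
          }
          if (nin == 0 || nin == 4) continue;
          // order so the "minority" corners come first
          int idx[4]; int na = 0, nb = 3;
          bool minority_inside = (nin == 1 || nin == 2);
          (void)minority_inside;
          if (nin == 1 || nin == 3) {
            int flag = (nin == 1) ? 1 : 0;
            for (int c = 0; c < 4; ++c) (in[c] == flag) ? idx[na++] = c : idx[nb--] = c;
            int A = T[idx[0]], B = T[idx[3]], C = T[idx[2]], D = T[idx[1]];
            int vA = edge_vertex(gi[A], gi[B], cv[A], cv[B], off[A], off[B], i, j, k);
            int vB = edge_vertex(gi[A], gi[C], cv[A], cv[C], off[A], off[C], i, j, k);
            int vC = edge_vertex(gi[A], gi[D], cv[A], cv[D], off[A], off[D], i, j, k);
            tris.push_back(vA); tris.push_back(vB); tris.push_back(vC);
          } else { // nin == 2
            for (int c = 0; c < 4; ++c) (in[c] == 1) ? idx[na++] = c : idx[nb--] = c;
            int A = T[idx[0]], B = T[idx[1]], C = T[idx[3]], D = T[idx[2]];
            int vAC = edge_vertex(gi[A], gi[C], cv[A], cv[C], off[A], off[C], i, j, k);
            int vAD = edge_vertex(gi[A], gi[D], cv[A], cv[D], off[A], off[D], i, j, k);
            int vBC = edge_vertex(gi[B], gi[C], cv[B], cv[C], off[B], off[C], i, j, k);
            int vBD = edge_vertex(gi[B], gi[D], cv[B], cv[D], off[B], off[D], i, j, k);
            tris.push_back(vAC); tris.push_back(vAD); tris.push_back(vBD);
            tris.push_back(vAC); tris.push_back(vBD); tris.push_back(vBC);
          }
        }
      }
    }
  }
  int nv = (int)(verts.size() / 3), nf = (int)(tris.size() / 3);
  NumericMatrix V(nv, 3);
  for (int r = 0; r < nv; ++r)
    for (int c = 0; c < 3; ++c) V(r, c) = verts[3 * (R_xlen_t)r + c];
  IntegerMatrix F(nf, 3);
  for (int r = 0; r < nf; ++r)
    for (int c = 0; c < 3; ++c) F(r, c) = tris[3 * (R_xlen_t)r + c];
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Separable Gaussian filter over a 3D array (truncated at 3 sigma,
// renormalized at the borders). sigma in voxels.
// [[Rcpp::export]]
NumericVector gauss_smooth3d_cpp(NumericVector vol, IntegerVector dims, double sigma) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int rad = (int)std::ceil(3.0 * sigma);
  if (rad < 1) rad = 1;
  std::vector<double> kern(2 * rad + 1);
  double s = 0.0;
  for (int t = -rad; t <= rad; ++t) {
    kern[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += kern[t + rad];
  }
  for (auto &k : kern) k /= s;

  R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(n);
  std::vector<double> buf(vol.begin(), vol.end());
  std::vector<double> tmp(n);
  const int dd[3] = {d1, d2, d3};
  const R_xlen_t stride[3] = {1, (R_xlen_t)d1, (R_xlen_t)d1 * d2};

  for (int axis = 0; axis < 3; ++axis) {
    const int len = dd[axis];
    const R_xlen_t st = stride[axis];
    for (R_xlen_t p = 0; p < n; ++p) {
      int pos = (int)((p / st) % len);
      double acc = 0.0, wsum = 0.0;
      int t0 = std::max(-rad, -pos), t1 = std::min(rad, len - 1 - pos);
      for (int t = t0; t <= t1; ++t) {
        acc += kern[t + rad] * buf[p + (R_xlen_t)t * st];
        wsum += kern[t + rad];
      }
      tmp[p] = acc / wsum;
    }
    buf.swap(tmp);
  }
  for (R_xlen_t p = 0; p < n; ++p) out[p] = buf[p];
  out.attr("dim") = dims;
  return out;
}

// Orthographic triangle rasterizer with a z-buffer. px is n x 2 pixel
// coordinates (x = column, y = row, both 1-based continuous), depth is the
// camera-space depth per vertex (smaller = closer), faces is m x 3 (1-based).
// Returns the depth buffer and the index of the nearest face per pixel
// (NA where no face covers the pixel center).
// [[Rcpp::export]]
List rasterize_mesh_cpp(NumericMatrix px, NumericVector depth,
                        IntegerMatrix faces, int width, int height) {
  NumericMatrix zbuf(height, width);
  IntegerMatrix fbuf(height, width);
  std::fill(zbuf.begin(), zbuf.end(), R_PosInf);
  std::fill(fbuf.begin(), fbuf.end(), NA_INTEGER);
  const int nf = faces.nrow();
  for (int f = 0; f < nf; ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    double x0 = px(a, 0), y0 = px(a, 1), z0 = depth[a];
    double x1 = px(b, 0), y1 = px(b, 1), z1 = depth[b];
    double x2 = px(c, 0), y2 = px(c, 1), z2 = depth[c];
    double area = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (area == 0.0) continue;
    int cmin = std::max(1, (int)std::ceil(std::min({x0, x1, x2})));
    int cmax = std::min(width, (int)std::floor(std::max({x0, x1, x2})));
    int rmin = std::max(1, (int)std::ceil(std::min({y0, y1, y2})));
    int rmax = std::min(height, (int)std::floor(std::max({y0, y1, y2})));
    if (cmin > cmax || rmin > rmax) continue;
    double inv = 1.0 / area;
    for (int r = rmin; r <= rmax; ++r) {
      for (int cc = cmin; cc <= cmax; ++cc) {
        double pxx = (double)cc, pyy = (double)r;
        double w0 = ((x1 - pxx) * (y2 - pyy) - (x2 - pxx) * (y1 - pyy)) * inv;
        double w1 = ((x2 - pxx) * (y0 - pyy) - (x0 - pxx) * (y2 - pyy)) * inv;
        double w2 = 1.0 - w0 - w1;
        if (w0 < 0.0 || w1 < 0.0 || w2 < 0.0) continue;
        double z = w0 * z0 + w1 * z1 + w2 * z2;
        if (z < zbuf(r - 1, cc - 1)) {
          zbuf(r - 1, cc - 1) = z;
          fbuf(r - 1, cc - 1) = f + 1;
        }
      }
    }
  }
  return List::create(_["depth"] = zbuf, _["face"] = fbuf);
}

// Trilinear interpolation of a 3D array at fractional (1-based) index
// coordinates; points outside the array return NA.
// [[Rcpp::export]]
NumericVector trilinear_cpp(NumericVector vol, IntegerVector dims,
                            NumericMatrix pts) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const double *v = REAL(vol);
  const int n = pts.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0) - 1.0, y = pts(p, 1) - 1.0, z = pts(p, 2) - 1.0;
    if (x < 0 || y < 0 || z < 0 || x > d1 - 1 || y > d2 - 1 || z > d3 - 1) {
      out[p] = NA_REAL;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == d1 - 1) i0--;
    if (j0 == d2 - 1) j0--;
    if (k0 == d3 - 1) k0--;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double acc = 0.0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          if (w > 0.0)
            acc += w * v[lin(i0 + di, j0 + dj, k0 + dk, d1, d2)];
        }
    out[p] = acc;
  }
  return out;
}
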