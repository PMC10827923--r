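#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Brute-force nearest neighbour: for each row of A, the closest row of B.
// Meshes here are a few hundred vertices, so O(nA * nB) is the right tool.
// [[Rcpp::export]]
List cpp_nearest(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  NumericVector d(na);
  IntegerVector idx(na);
  for (int i = 0; i < na; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bj = 0;
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) { best = dd; bj = j; }
    }
    d[i] = std::sqrt(best);
    idx[i] = bj + 1; // 1-based for R
  }
  return List::create(_["dist"] = d, _["index"] = idx);
}

static inline void sh_basis(double x, double y, double z, double *Y) {
  Y[0] = 0.2820947917738781;
  Y[1] = 0.4886025119029199 * y;
  Y[2] = 0.4886025119029199 * z;
  Y[3] = 0.4886025119029199 * x;
  Y[4] = 1.0925484305920792 * x * y;
  Y[5] = 1.0925484305920792 * y * z;
  Y[6] = 0.3153915652525200 * (3.0 * z * z - 1.0);
  Y[7] = 1.0925484305920792 * x * z;
  Y[8] = 0.5462742152960396 * (x * x - y * y);
}

// Z-buffered triangle rasterizer with per-pixel normal interpolation and
// order-2 spherical-harmonics Lambertian shading.
//  P   : N x 3 screen coords (u px, v px, camera depth z > 0 visible)
//  Nrm : N x 3 unit normals (camera frame, toward-camera component < 0 front)
//  Alb : N x 3 per-vertex albedo in [0,1]
//  F   : T x 3 0-based triangle indices
//  L   : 9 x 3 SH coefficients (columns R,G,B)
// Returns image (H x W x 3), depth, face (1-based, 0 = background),
// barycentric weights per pixel.
// [[Rcpp::export]]
List cpp_rasterize(NumericMatrix P, NumericMatrix Nrm, NumericMatrix Alb,
                   IntegerMatrix F, NumericMatrix L,
                   int W, int H, NumericVector bg, bool cull) {
  NumericVector img(H * W * 3);
  NumericMatrix bary(H * W, 3);
  NumericVector depth(H * W, NA_REAL);
  IntegerVector face(H * W, 0);
  std::vector<double> zbuf(H * W, std::numeric_limits<double>::infinity());
  for (int p = 0; p < H * W; ++p) {
    img[p] = bg[0]; img[p + H * W] = bg[1]; img[p + 2 * H * W] = bg[2];
  }
  int T = F.nrow();
  for (int t = 0; t < T; ++t) {
    int a = F(t, 0), b = F(t, 1), c = F(t, 2);
    double ua = P(a, 0), va = P(a, 1), za = P(a, 2);
    double ub = P(b, 0), vb = P(b, 1), zb = P(b, 2);
    double uc = P(c, 0), vc = P(c, 1), zc = P(c, 2);
    if (za <= 0 || zb <= 0 || zc <= 0) continue; // behind camera
    double area = (ub - ua) * (vc - va) - (uc - ua) * (vb - va);
    if (cull && area >= 0) continue; // back face (y-down screen, CCW front)
    if (std::fabs(area) < 1e-12) continue;
    int x0 = std::max(0, (int)std::floor(std::min(ua, std::min(ub, uc))));
    int x1 = std::min(W - 1, (int)std::ceil(std::max(ua, std::max(ub, uc))));
    int y0 = std::max(0, (int)std::floor(std::min(va, std::min(vb, vc))));
    int y1 = std::min(H - 1, (int)std::ceil(std::max(va, std::max(vb, vc))));
    for (int y = y0; y <= y1; ++y) {
      for (int x = x0; x <= x1; ++x) {
        double px = x + 0.5, py = y + 0.5;
        double w0 = ((ub - px) * (vc - py) - (uc - px) * (vb - py)) / area;
        double w1 = ((uc - px) * (va - py) - (ua - px) * (vc - py)) / area;
        double w2 = 1.0 - w0 - w1;
        if (w0 < 0 || w1 < 0 || w2 < 0) continue;
        double z = w0 * za + w1 * zb + w2 * zc;
        int p = y + H * x; // column-major H x W
        if (z >= zbuf[p]) continue;
        zbuf[p] = z;
        double nx = w0 * Nrm(a, 0) + w1 * Nrm(b, 0) + w2 * Nrm(c, 0);
        double ny = w0 * Nrm(a, 1) + w1 * Nrm(b, 1) + w2 * Nrm(c, 1);
        double nz = w0 * Nrm(a, 2) + w1 * Nrm(b, 2) + w2 * Nrm(c, 2);
        double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
        if (nn > 1e-12) { nx /= nn; ny /= nn; nz /= nn; }
        double Y[9];
        sh_basis(nx, ny, nz, Y);
        for (int ch = 0; ch < 3; ++ch) {
          double irr = 0.0;
          for (int j = 0; j < 9; ++j) irr += L(j, ch) * Y[j];
          double alb = w0 * Alb(a, ch) + w1 * Alb(b, ch) + w2 * Alb(c, ch);
          double col = alb * irr;
          if (col < 0) col = 0;
          if (col > 1) col = 1;
          img[p + ch * H * W] = col;
        }
        depth[p] = z;
        face[p] = t + 1;
        bary(p, 0) = w0; bary(p, 1) = w1; bary(p, 2) = w2;
      }
    }
  }
  img.attr("dim") = IntegerVector::create(H, W, 3);
  depth.attr("dim") = IntegerVector::create(H, W);
  face.attr("dim") = IntegerVector::create(H, W);
  return List::create(_["image"] = img, _["depth"] = depth,
                      _["face"] = face, _["bary"] = bary);
}

// Moller-Trumbore ray/mesh intersection, nearest hit by |t| over both ray
// directions. origins/dirs: M x 3; V: N x 3; F: T x 3 (0-based).
// [[Rcpp::export]]
List cpp_ray_mesh(NumericMatrix O, NumericMatrix D,
                  NumericMatrix V, IntegerMatrix F) {
  int M = O.nrow(), T = F.nrow();
  NumericVector tout(M, NA_REAL);
  IntegerVector fout(M, 0);
  NumericMatrix bout(M, 3);
  const double eps = 1e-9;
  for (int i = 0; i < M; ++i) {
    double ox = O(i, 0), oy = O(i, 1), oz = O(i, 2);
    double dx = D(i, 0), dy = D(i, 1), dz = D(i, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int t = 0; t < T; ++t) {
      int a = F(t, 0), b = F(t, 1), c = F(t, 2);
      double e1x = V(b, 0) - V(a, 0), e1y = V(b, 1) - V(a, 1), e1z = V(b, 2) - V(a, 2);
      double e2x = V(c, 0) - V(a, 0), e2y = V(c, 1) - V(a, 1), e2z = V(c, 2) - V(a, 2);
      double hx = dy * e2z - dz * e2y;
      double hy = dz * e2x - dx * e2z;
      double hz = dx * e2y - dy * e2x;
      double det = e1x * hx + e1y * hy + e1z * hz;
      if (std::fabs(det) < eps) continue;
      double sx = ox - V(a, 0), sy = oy - V(a, 1), sz = oz - V(a, 2);
      double u = (sx * hx + sy * hy + sz * hz) / det;
      if (u < -1e-9 || u > 1.0 + 1e-9) continue;
      double qx = sy * e1z - sz * e1y;
      double qy = sz * e1x - sx * e1z;
      double qz = sx * e1y - sy * e1x;
      double v = (dx * qx + dy * qy + dz * qz) / det;
      if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
      double tt = (e2x * qx + e2y * qy + e2z * qz) / det;
      if (std::fabs(tt) < best) {
        best = std::fabs(tt);
        tout[i] = tt;
        fout[i] = t + 1;
        bout(i, 0) = 1.0 - u - v; bout(i, 1) = u; bout(i, 2) = v;
      }
    }
  }
  return List::create(_["t"] = tout, _["face"] = fout, _["bary"] = bout);
}

// Backpropagate a gradient w.r.t. unit vertex normals to vertex positions.
// Vertex normal n_i = normalize(m_i), m_i = sum of adjacent unnormalized
// face normals h_f = (vb - va) x (vc - va).
// G: N x 3 gradient dE/dn. Returns N x 3 dE/dV.
// [[Rcpp::export]]
NumericMatrix cpp_normal_grad(NumericMatrix V, IntegerMatrix F, NumericMatrix G) {
  int N = V.nrow(), T = F.nrow();
  NumericMatrix M(N, 3), GM(N, 3), out(N, 3);
  // accumulate unnormalized vertex normals
  for (int t = 0; t < T; ++t) {
    int a = F(t, 0), b = F(t, 1), c = F(t, 2);
    double e1x = V(b, 0) - V(a, 0), e1y = V(b, 1) - V(a, 1), e1z = V(b, 2) - V(a, 2);
    double e2x = V(c, 0) - V(a, 0), e2y = V(c, 1) - V(a, 1), e2z = V(c, 2) - V(a, 2);
    double hx = e1y * e2z - e1z * e2y;
    double hy = e1z * e2x - e1x * e2z;
    double hz = e1x * e2y - e1y * e2x;
    int vid[3] = {a, b, c};
    for (int k = 0; k < 3; ++k) {
      M(vid[k], 0) += hx; M(vid[k], 1) += hy; M(vid[k], 2) += hz;
    }
  }
  // dE/dm_i = (I - n n^T) / |m| * dE/dn
  for (int i = 0; i < N; ++i) {
    double mx = M(i, 0), my = M(i, 1), mz = M(i, 2);
    double nn = std::sqrt(mx * mx + my * my + mz * mz);
    if (nn < 1e-12) continue;
    double nx = mx / nn, ny = my / nn, nz = mz / nn;
    double gx = G(i, 0), gy = G(i, 1), gz = G(i, 2);
    double dot = nx * gx + ny * gy + nz * gz;
    GM(i, 0) = (gx - dot * nx) / nn;
    GM(i, 1) = (gy - dot * ny) / nn;
    GM(i, 2) = (gz - dot * nz) / nn;
  }
  // h_f feeds m of its three vertices; g_f = sum of their dE/dm.
  // dE/de1 = e2 x g, dE/de2 = g x e1; va gets minus both.
  for (int t = 0; t < T; ++t) {
    int a = F(t, 0), b = F(t, 1), c = F(t, 2);
    double e1x = V(b, 0) - V(a, 0), e1y = V(b, 1) - V(a, 1), e1z = V(b, 2) - V(a, 2);
    double e2x = V(c, 0) - V(a, 0), e2y = V(c, 1) - V(a, 1), e2z = V(c, 2) - V(a, 2);
    double gx = GM(a, 0) + GM(b, 0) + GM(c, 0);
    double gy = GM(a, 1) + GM(b, 1) + GM(c, 1);
    double gz = GM(a, 2) + GM(b, 2) + GM(c, 2);
    double d1x = e2y * gz - e2z * gy;
    double d1y = e2z * gx - e2x * gz;
    double d1z = e2x * gy - e2y * gx;
    double d2x = gy * e1z - gz * e1y;
    double d2y = gz * e1x - gx * e1z;
    double d2z = gx * e1y - gy * e1x;
    out(b, 0) += d1x; out(b, 1) += d1y; out(b, 2) += d1z;
    out(c, 0) += d2x; out(c, 1) += d2y; out(c, 2) += d2z;
    out(a, 0) -= d1x + d2x; out(a, 1) -= d1y + d2y; out(a, 2) -= d1z + d2z;
  }
  return out;
}
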