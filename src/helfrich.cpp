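// Discrete Helfrich bending energy on a triangle mesh.
//
// E = sum_i (kappa/2) * |K_i|^2 * A_i with the cotangent mean-curvature
// normal K_i = (1/(2 A_i)) sum_j (cot a_ij + cot b_ij) (x_i - x_j) and
// barycentric vertex areas A_i (one third of incident face areas). Supports
// periodic boundaries in x and y via minimum-image edge vectors (triangles
// must be smaller than half the box). The gradient uses central finite
// differences with exact sparsity: perturbing vertex p only changes the
// vertex energies of p and its one-ring.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct MeshCtx {
  int nv, nf;
  const double* V;       // 3 x nv column-major
  const int* F;          // nf x 3 (R matrix layout: column-major)
  bool periodic;
  double Lx, Ly;
  std::vector<std::vector<int>> vfaces;   // incident faces per vertex

  double fx(int f, int c) const { return F[f + c * nf]; }
  int fv(int f, int c) const { return F[f + c * nf]; }

  void edge(const double* a, const double* b, double* e) const {
    e[0] = b[0] - a[0]; e[1] = b[1] - a[1]; e[2] = b[2] - a[2];
    if (periodic) {
      if (e[0] > 0.5 * Lx) e[0] -= Lx; else if (e[0] < -0.5 * Lx) e[0] += Lx;
      if (e[1] > 0.5 * Ly) e[1] -= Ly; else if (e[1] < -0.5 * Ly) e[1] += Ly;
    }
  }
};

inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// bending energy attributed to vertex i (needs i's incident faces only);
// vertex positions may be overridden via `ov` (index -> 3 coords) for FD
double vertex_energy(const MeshCtx& M, int i, double kappa,
                     int ov_idx = -1, const double* ov = nullptr) {
  const double* Vi = (i == ov_idx && ov) ? ov : M.V + 3 * i;
  double K[3] = {0, 0, 0};
  double A = 0;
  for (int f : M.vfaces[i]) {
    int a = M.fv(f, 0), b = M.fv(f, 1), c = M.fv(f, 2);
    // rotate so that the face reads (i, j, k)
    int j, k;
    if (a == i) { j = b; k = c; }
    else if (b == i) { j = c; k = a; }
    else { j = a; k = b; }
    const double* Vj = (j == ov_idx && ov) ? ov : M.V + 3 * j;
    const double* Vk = (k == ov_idx && ov) ? ov : M.V + 3 * k;
    double eij[3], eik[3], ejk[3];
    M.edge(Vi, Vj, eij);
    M.edge(Vi, Vk, eik);
    M.edge(Vj, Vk, ejk);
    double n[3];
    cross3(eij, eik, n);
    double dn = std::sqrt(dot3(n, n));
    if (dn < 1e-12) continue;
    A += dn / 6.0;                       // one third of face area
    // cot of angle at k (opposite edge i-j): between (k->i) and (k->j)
    double vki[3] = {-eik[0], -eik[1], -eik[2]};
    double vkj[3] = {-ejk[0], -ejk[1], -ejk[2]};
    double cr[3];
    cross3(vki, vkj, cr);
    double cot_k = dot3(vki, vkj) / std::sqrt(dot3(cr, cr));
    // cot of angle at j (opposite edge i-k): between (j->i) and (j->k)
    double vji[3] = {-eij[0], -eij[1], -eij[2]};
    double vjk[3] = {ejk[0], ejk[1], ejk[2]};
    cross3(vji, vjk, cr);
    double cot_j = dot3(vji, vjk) / std::sqrt(dot3(cr, cr));
    // face contribution to K_i: cot_k * (x_i - x_j) + cot_j * (x_i - x_k)
    K[0] += cot_k * (-eij[0]) + cot_j * (-eik[0]);
    K[1] += cot_k * (-eij[1]) + cot_j * (-eik[1]);
    K[2] += cot_k * (-eij[2]) + cot_j * (-eik[2]);
  }
  if (A <= 1e-12) return 0.0;
  // K accumulated = sum w_ij (x_i - x_j) over both incident faces of each
  // edge; mean-curvature normal = K / (2A) * ... E_i = kappa/2 |K/(2A)|^2 A
  double k2 = dot3(K, K) / (4.0 * A * A);
  return 0.5 * kappa * k2 * A;
}

MeshCtx make_ctx(const NumericVector& V, const IntegerMatrix& F,
                 bool periodic, double Lx, double Ly) {
  MeshCtx M;
  M.nv = V.size() / 3;
  M.nf = F.nrow();
  M.V = V.begin();
  M.F = F.begin();
  M.periodic = periodic;
  M.Lx = Lx; M.Ly = Ly;
  M.vfaces.assign(M.nv, {});
  for (int f = 0; f < M.nf; ++f)
    for (int c = 0; c < 3; ++c) M.vfaces[F(f, c)].push_back(f);
  return M;
}

}  // namespace

// [[Rcpp::export]]
double helfrich_energy_cpp(NumericVector V, IntegerMatrix F, double kappa,
                           bool periodic, double Lx, double Ly) {
  MeshCtx M = make_ctx(V, F, periodic, Lx, Ly);
  double E = 0;
  for (int i = 0; i < M.nv; ++i) E += vertex_energy(M, i, kappa);
  return E;
}

// [[Rcpp::export]]
NumericVector helfrich_gradient_cpp(NumericVector V, IntegerMatrix F,
                                    double kappa, bool periodic, double Lx,
                                    double Ly, double h = 1e-4) {
  MeshCtx M = make_ctx(V, F, periodic, Lx, Ly);
  NumericVector grad(V.size());
  // one-ring vertex sets
  std::vector<std::vector<int>> ring(M.nv);
  for (int i = 0; i < M.nv; ++i) {
    std::vector<int>& r = ring[i];
    r.push_back(i);
    for (int f : M.vfaces[i])
      for (int c = 0; c < 3; ++c) {
        int v = F(f, c);
        bool found = false;
        for (int x : r) if (x == v) { found = true; break; }
        if (!found) r.push_back(v);
      }
  }
  double ov[3];
  for (int p = 0; p < M.nv; ++p) {
    for (int d = 0; d < 3; ++d) {
      double e_plus = 0, e_minus = 0;
      ov[0] = V[3 * p]; ov[1] = V[3 * p + 1]; ov[2] = V[3 * p + 2];
      ov[d] += h;
      for (int i : ring[p]) e_plus += vertex_energy(M, i, kappa, p, ov);
      ov[d] -= 2 * h;
      for (int i : ring[p]) e_minus += vertex_energy(M, i, kappa, p, ov);
      grad[3 * p + d] = (e_plus - e_minus) / (2 * h);
    }
    if (p % 512 == 0) Rcpp::checkUserInterrupt();
  }
  return grad;
}
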