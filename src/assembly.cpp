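// Total-Lagrangian assembly for 4-node tetrahedra (single quadrature point):
// internal force, consistent (symmetrized) tangent stiffness, follower or
// dead pressure on boundary triangles, and penalty tied-contact springs.
//
// The sparse pattern over free DOFs is precomputed once (fe_setup); each
// Newton iteration only refills the CSC value array, which the R side wraps
// into a dgCMatrix template.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace aaamech {
void pk2_d(const double* C, int type, const double* p, const double* M4,
           const double* M6, double* S);
void tangent_d(const double* C, int type, const double* p, const double* M4,
               const double* M6, double* D);
double det3_d(const double* A);
void ctf_d(const double* F, double* C);
void push_forward_d(const double* F, const double* S, double* sig);
}  // namespace aaamech

namespace {

inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

// shape-function gradients and reference volume of one tet
bool tet_grads(const double* X /*4x3 row-major*/, double* G /*4x3*/,
               double* vol) {
  double D[9];
  for (int a = 0; a < 3; ++a)
    for (int j = 0; j < 3; ++j) D[3 * a + j] = X[3 * (a + 1) + j] - X[j];
  double det = aaamech::det3_d(D);
  *vol = det / 6.0;
  if (det <= 0) return false;
  double Di[9];
  // inverse of D
  Di[0] = (D[4] * D[8] - D[5] * D[7]) / det;
  Di[1] = -(D[1] * D[8] - D[2] * D[7]) / det;
  Di[2] = (D[1] * D[5] - D[2] * D[4]) / det;
  Di[3] = -(D[3] * D[8] - D[5] * D[6]) / det;
  Di[4] = (D[0] * D[8] - D[2] * D[6]) / det;
  Di[5] = -(D[0] * D[5] - D[2] * D[3]) / det;
  Di[6] = (D[3] * D[7] - D[4] * D[6]) / det;
  Di[7] = -(D[0] * D[7] - D[1] * D[6]) / det;
  Di[8] = -(-(D[0] * D[4] - D[1] * D[3])) / det;
  // grad N_{a+1} = column a of inv(D): (X - X1) = D^T xi
  for (int a = 0; a < 3; ++a)
    for (int j = 0; j < 3; ++j) G[3 * (a + 1) + j] = Di[3 * j + a];
  for (int j = 0; j < 3; ++j)
    G[j] = -(G[3 + j] + G[6 + j] + G[9 + j]);
  return true;
}

struct Pattern {
  std::vector<int> p, i;                 // CSC over free dofs
  std::vector<int> emap, fmap, pmap;     // slot -> position in x (-1 skip)
  int nf;
};

}  // namespace

// [[Rcpp::export]]
List cpp_fe_setup(NumericMatrix nodes, IntegerMatrix tets, IntegerVector dofmap,
                  IntegerMatrix faces, IntegerMatrix pairs) {
  int ne = tets.nrow(), nfc = faces.nrow(), np = pairs.nrow();
  int nf = 0;
  for (int k = 0; k < dofmap.size(); ++k) nf = std::max(nf, dofmap[k] + 1);

  NumericMatrix G(ne, 12);
  NumericVector V0(ne);
  for (int e = 0; e < ne; ++e) {
    double X[12], Ge[12], vol;
    for (int a = 0; a < 4; ++a)
      for (int j = 0; j < 3; ++j) X[3 * a + j] = nodes(tets(e, a) - 1, j);
    if (!tet_grads(X, Ge, &vol))
      stop("element %d has non-positive reference volume", e + 1);
    for (int k = 0; k < 12; ++k) G(e, k) = Ge[k];
    V0[e] = vol;
  }

  // collect (col, row) keys for all potential stiffness entries
  std::vector<int64_t> keys;
  keys.reserve((size_t)ne * 144 + (size_t)nfc * 81 + (size_t)np * 12);
  auto add = [&](int r, int c) {
    if (r >= 0 && c >= 0) keys.push_back((int64_t)c * nf + r);
  };
  std::vector<int> ed(12), fd(9);
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 4; ++a)
      for (int d = 0; d < 3; ++d) ed[3 * a + d] = dofmap[3 * (tets(e, a) - 1) + d];
    for (int a = 0; a < 12; ++a)
      for (int b = 0; b < 12; ++b) add(ed[a], ed[b]);
  }
  for (int f = 0; f < nfc; ++f) {
    for (int a = 0; a < 3; ++a)
      for (int d = 0; d < 3; ++d) fd[3 * a + d] = dofmap[3 * (faces(f, a) - 1) + d];
    for (int a = 0; a < 9; ++a)
      for (int b = 0; b < 9; ++b) add(fd[a], fd[b]);
  }
  for (int q = 0; q < np; ++q) {
    for (int d = 0; d < 3; ++d) {
      int da = dofmap[3 * (pairs(q, 0) - 1) + d];
      int db = dofmap[3 * (pairs(q, 1) - 1) + d];
      add(da, da); add(da, db); add(db, da); add(db, db);
    }
  }
  std::sort(keys.begin(), keys.end());
  keys.erase(std::unique(keys.begin(), keys.end()), keys.end());
  size_t nnz = keys.size();

  Pattern pat;
  pat.nf = nf;
  pat.p.assign(nf + 1, 0);
  pat.i.resize(nnz);
  for (size_t k = 0; k < nnz; ++k) {
    int col = (int)(keys[k] / nf);
    pat.i[k] = (int)(keys[k] % nf);
    pat.p[col + 1]++;
  }
  for (int c = 0; c < nf; ++c) pat.p[c + 1] += pat.p[c];

  auto pos = [&](int r, int c) -> int {
    if (r < 0 || c < 0) return -1;
    int64_t key = (int64_t)c * nf + r;
    auto it = std::lower_bound(keys.begin(), keys.end(), key);
    return (int)(it - keys.begin());
  };
  IntegerVector emap((R_xlen_t)ne * 144), fmap((R_xlen_t)nfc * 81),
      pmap((R_xlen_t)np * 12);
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 4; ++a)
      for (int d = 0; d < 3; ++d) ed[3 * a + d] = dofmap[3 * (tets(e, a) - 1) + d];
    for (int a = 0; a < 12; ++a)
      for (int b = 0; b < 12; ++b)
        emap[(R_xlen_t)e * 144 + 12 * a + b] = pos(ed[a], ed[b]);
  }
  for (int f = 0; f < nfc; ++f) {
    for (int a = 0; a < 3; ++a)
      for (int d = 0; d < 3; ++d) fd[3 * a + d] = dofmap[3 * (faces(f, a) - 1) + d];
    for (int a = 0; a < 9; ++a)
      for (int b = 0; b < 9; ++b)
        fmap[(R_xlen_t)f * 81 + 9 * a + b] = pos(fd[a], fd[b]);
  }
  for (int q = 0; q < np; ++q)
    for (int d = 0; d < 3; ++d) {
      int da = dofmap[3 * (pairs(q, 0) - 1) + d];
      int db = dofmap[3 * (pairs(q, 1) - 1) + d];
      pmap[(R_xlen_t)q * 12 + 4 * d + 0] = pos(da, da);
      pmap[(R_xlen_t)q * 12 + 4 * d + 1] = pos(da, db);
      pmap[(R_xlen_t)q * 12 + 4 * d + 2] = pos(db, da);
      pmap[(R_xlen_t)q * 12 + 4 * d + 3] = pos(db, db);
    }

  return List::create(
      _["nf"] = nf, _["p"] = IntegerVector(pat.p.begin(), pat.p.end()),
      _["i"] = IntegerVector(pat.i.begin(), pat.i.end()), _["nnz"] = (double)nnz,
      _["emap"] = emap, _["fmap"] = fmap, _["pmap"] = pmap, _["G"] = G,
      _["V0"] = V0);
}

// [[Rcpp::export]]
List cpp_fe_assemble(List prep, NumericMatrix nodes, IntegerMatrix tets,
                     NumericVector u, IntegerVector dofmap, IntegerVector mtype,
                     NumericMatrix mparams, NumericMatrix M4, NumericMatrix M6,
                     IntegerMatrix faces, double pressure, bool follower,
                     IntegerMatrix pairs, NumericVector pair_stiff,
                     bool want_matrix, bool symmetrize,
                     bool load_stiffness) {
  int ne = tets.nrow(), nfc = faces.nrow(), np = pairs.nrow();
  int nf = as<int>(prep["nf"]);
  NumericMatrix G = prep["G"];
  NumericVector V0 = prep["V0"];
  IntegerVector emap = prep["emap"], fmap = prep["fmap"], pmap = prep["pmap"];
  size_t nnz = (size_t)as<double>(prep["nnz"]);

  std::vector<double> x(want_matrix ? nnz : 0, 0.0);
  std::vector<double> resid(nf, 0.0);
  double fext_max = 0.0, minJ = R_PosInf;
  bool inverted = false;

  const int vi[6] = {0, 1, 2, 0, 1, 0};
  const int vj[6] = {0, 1, 2, 1, 2, 2};

  std::vector<int> ed(12);
  double S[9], D6[36], C[9], F[9], B[72], Ke[144], BtD[72];
  for (int e = 0; e < ne; ++e) {
    double Ge[12];
    for (int k = 0; k < 12; ++k) Ge[k] = G(e, k);
    double ue[12];
    for (int a = 0; a < 4; ++a) {
      int n = tets(e, a) - 1;
      for (int d = 0; d < 3; ++d) {
        ue[3 * a + d] = u[3 * n + d];
        ed[3 * a + d] = dofmap[3 * n + d];
      }
    }
    // F = I + sum_a u_a (x) grad N_a
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = (i == j) ? 1.0 : 0.0;
        for (int a = 0; a < 4; ++a) s += ue[3 * a + i] * Ge[3 * a + j];
        F[3 * i + j] = s;
      }
    double J = aaamech::det3_d(F);
    minJ = std::min(minJ, J);
    if (J <= 0) { inverted = true; continue; }
    aaamech::ctf_d(F, C);
    double mp[6];
    for (int k = 0; k < 6; ++k) mp[k] = mparams(e, k);
    double m4[3] = {M4(e, 0), M4(e, 1), M4(e, 2)};
    double m6[3] = {M6(e, 0), M6(e, 1), M6(e, 2)};
    aaamech::pk2_d(C, mtype[e], mp, m4, m6, S);
    // internal force: f_a = V0 (F S) gradN_a
    double P[9];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += F[3 * i + k] * S[3 * k + j];
        P[3 * i + j] = s;
      }
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) {
        int d = ed[3 * a + i];
        if (d >= 0) {
          double s = 0;
          for (int j = 0; j < 3; ++j) s += P[3 * i + j] * Ge[3 * a + j];
          resid[d] += V0[e] * s;
        }
      }
    if (!want_matrix) continue;
    aaamech::tangent_d(C, mtype[e], mp, m4, m6, D6);
    // B (6 x 12): dE_voigt = B du
    for (int b = 0; b < 4; ++b)
      for (int k = 0; k < 3; ++k) {
        int col = 3 * b + k;
        for (int r = 0; r < 6; ++r) {
          int i = vi[r], j = vj[r];
          double v = F[3 * k + i] * Ge[3 * b + j];
          if (i != j) v += F[3 * k + j] * Ge[3 * b + i];
          B[12 * r + col] = v;
        }
      }
    for (int col = 0; col < 12; ++col)
      for (int r = 0; r < 6; ++r) {
        double s = 0;
        for (int q = 0; q < 6; ++q) s += B[12 * q + col] * D6[6 * q + r];
        BtD[6 * col + r] = s;
      }
    for (int a = 0; a < 12; ++a)
      for (int b = 0; b < 12; ++b) {
        double s = 0;
        for (int q = 0; q < 6; ++q) s += BtD[6 * a + q] * B[12 * q + b];
        Ke[12 * a + b] = V0[e] * s;
      }
    // geometric part: (gradN_a . S gradN_b) I3
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        double s = 0;
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            s += Ge[3 * a + i] * S[3 * i + j] * Ge[3 * b + j];
        s *= V0[e];
        for (int d = 0; d < 3; ++d) Ke[12 * (3 * a + d) + 3 * b + d] += s;
      }
    const int* em = &emap[(R_xlen_t)e * 144];
    for (int a = 0; a < 12; ++a)
      for (int b = 0; b < 12; ++b) {
        double v = Ke[12 * a + b];
        if (v == 0.0) continue;
        int pab = em[12 * a + b], pba = em[12 * b + a];
        if (symmetrize) {
          if (pab >= 0) x[pab] += 0.5 * v;
          if (pba >= 0) x[pba] += 0.5 * v;
        } else if (pab >= 0) {
          x[pab] += v;
        }
      }
  }

  // pressure faces: f_node = -p/6 (y21 x y31), y deformed (follower) or ref
  for (int f = 0; f < nfc; ++f) {
    int n1 = faces(f, 0) - 1, n2 = faces(f, 1) - 1, n3 = faces(f, 2) - 1;
    double y[9];
    int nn[3] = {n1, n2, n3};
    for (int a = 0; a < 3; ++a)
      for (int j = 0; j < 3; ++j)
        y[3 * a + j] = nodes(nn[a], j) + (follower ? u[3 * nn[a] + j] : 0.0);
    double e21[3], e31[3], an[3];
    for (int j = 0; j < 3; ++j) {
      e21[j] = y[3 + j] - y[j];
      e31[j] = y[6 + j] - y[j];
    }
    cross3(e21, e31, an);
    for (int a = 0; a < 3; ++a)
      for (int j = 0; j < 3; ++j) {
        double fe = -pressure / 6.0 * an[j];
        fext_max = std::max(fext_max, std::fabs(fe));
        int d = dofmap[3 * nn[a] + j];
        if (d >= 0) resid[d] -= fe;
      }
    if (want_matrix && follower && load_stiffness && pressure != 0.0) {
      // dR/du block (same for each force node a): p/6 * M_b
      // M_1 = -skew(y2-y3), M_2 = -skew(y3-y1), M_3 = skew(y2-y1)
      double w[3][3];
      for (int j = 0; j < 3; ++j) {
        w[0][j] = y[3 + j] - y[6 + j];
        w[1][j] = y[6 + j] - y[j];
        w[2][j] = y[3 + j] - y[j];
      }
      double sgn[3] = {-1.0, -1.0, 1.0};
      const int* fm = &fmap[(R_xlen_t)f * 81];
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) {
          // block(i,j) = p/6 * sgn_b * skew(w_b)(i,j)
          for (int i = 0; i < 3; ++i)
            for (int j = 0; j < 3; ++j) {
              double sk = 0.0;
              if (i != j) {
                // skew(v)(i,j): [[0,-v3,v2],[v3,0,-v1],[-v2,v1,0]]
                if (i == 0 && j == 1) sk = -w[b][2];
                else if (i == 0 && j == 2) sk = w[b][1];
                else if (i == 1 && j == 0) sk = w[b][2];
                else if (i == 1 && j == 2) sk = -w[b][0];
                else if (i == 2 && j == 0) sk = -w[b][1];
                else if (i == 2 && j == 1) sk = w[b][0];
              }
              double v = pressure / 6.0 * sgn[b] * sk;
              if (v == 0.0) continue;
              int pab = fm[9 * (3 * a + i) + 3 * b + j];
              int pba = fm[9 * (3 * b + j) + 3 * a + i];
              if (symmetrize) {
                if (pab >= 0) x[pab] += 0.5 * v;
                if (pba >= 0) x[pba] += 0.5 * v;
              } else if (pab >= 0) {
                x[pab] += v;
              }
            }
        }
    }
  }

  // tied-contact penalty springs
  for (int q = 0; q < np; ++q) {
    int a = pairs(q, 0) - 1, b = pairs(q, 1) - 1;
    double k = pair_stiff[q];
    for (int d = 0; d < 3; ++d) {
      double g = u[3 * a + d] - u[3 * b + d];
      int da = dofmap[3 * a + d], db = dofmap[3 * b + d];
      if (da >= 0) resid[da] += k * g;
      if (db >= 0) resid[db] -= k * g;
      if (want_matrix) {
        const int* pm = &pmap[(R_xlen_t)q * 12 + 4 * d];
        if (pm[0] >= 0) x[pm[0]] += k;
        if (pm[1] >= 0) x[pm[1]] -= k;
        if (pm[2] >= 0) x[pm[2]] -= k;
        if (pm[3] >= 0) x[pm[3]] += k;
      }
    }
  }

  List out = List::create(
      _["resid"] = NumericVector(resid.begin(), resid.end()),
      _["fext_max"] = fext_max, _["minJ"] = minJ, _["inverted"] = inverted);
  if (want_matrix) out["x"] = NumericVector(x.begin(), x.end());
  return out;
}

// nodal forces from pressure on a triangulated face set (full vector)
// [[Rcpp::export]]
NumericMatrix cpp_pressure_forces(NumericMatrix coords, IntegerMatrix faces,
                                  double pressure) {
  int n = coords.nrow();
  NumericMatrix out(n, 3);
  for (int f = 0; f < faces.nrow(); ++f) {
    double y[9];
    int nn[3] = {faces(f, 0) - 1, faces(f, 1) - 1, faces(f, 2) - 1};
    for (int a = 0; a < 3; ++a)
      for (int j = 0; j < 3; ++j) y[3 * a + j] = coords(nn[a], j);
    double e21[3], e31[3], an[3];
    for (int j = 0; j < 3; ++j) {
      e21[j] = y[3 + j] - y[j];
      e31[j] = y[6 + j] - y[j];
    }
    cross3(e21, e31, an);
    for (int a = 0; a < 3; ++a)
      for (int j = 0; j < 3; ++j) out(nn[a], j) += -pressure / 6.0 * an[j];
  }
  return out;
}

// per-element Cauchy stress and Green-Lagrange strain at displacement u
// [[Rcpp::export]]
List cpp_element_fields(NumericMatrix nodes, IntegerMatrix tets, NumericVector u,
                        IntegerVector mtype, NumericMatrix mparams,
                        NumericMatrix M4, NumericMatrix M6) {
  int ne = tets.nrow();
  NumericMatrix sig(ne, 9), gl(ne, 9);
  NumericVector Jv(ne), vol0(ne);
  for (int e = 0; e < ne; ++e) {
    double X[12], Ge[12], vol;
    for (int a = 0; a < 4; ++a)
      for (int j = 0; j < 3; ++j) X[3 * a + j] = nodes(tets(e, a) - 1, j);
    if (!tet_grads(X, Ge, &vol)) stop("inverted reference element");
    vol0[e] = vol;
    double F[9], C[9], S[9], s9[9];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = (i == j) ? 1.0 : 0.0;
        for (int a = 0; a < 4; ++a)
          s += u[3 * (tets(e, a) - 1) + i] * Ge[3 * a + j];
        F[3 * i + j] = s;
      }
    Jv[e] = aaamech::det3_d(F);
    aaamech::ctf_d(F, C);
    double mp[6];
    for (int k = 0; k < 6; ++k) mp[k] = mparams(e, k);
    double m4[3] = {M4(e, 0), M4(e, 1), M4(e, 2)};
    double m6[3] = {M6(e, 0), M6(e, 1), M6(e, 2)};
    aaamech::pk2_d(C, mtype[e], mp, m4, m6, S);
    aaamech::push_forward_d(F, S, s9);
    for (int k = 0; k < 9; ++k) {
      sig(e, k) = s9[k];
      gl(e, k) = 0.5 * (C[k] - ((k % 4 == 0) ? 1.0 : 0.0));
    }
  }
  return List::create(_["sigma"] = sig, _["green"] = gl, _["J"] = Jv,
                      _["vol0"] = vol0);
}
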