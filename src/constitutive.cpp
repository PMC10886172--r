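// Constitutive kernels: Saint Venant-Kirchhoff (compressible, used for the
// thrombus), decoupled two-parameter Mooney-Rivlin, and Holzapfel-Gasser-Ogden
// with two dispersed, tension-only fiber families.
//
// Second Piola-Kirchhoff stress S = 2 dPsi/dC is hand-derived and templated on
// the scalar type; the material tangent D = dS/dE (6x6 Voigt, engineering
// shears) is obtained by complex-step differentiation of S, which is exact to
// machine precision and symmetric after symmetrization.
//
// Model encodings (see R/materials.R):
//   type 1 SVK : params = {lambda, mu}
//   type 2 MR  : params = {c1, c2, K}
//   type 3 HGO : params = {c, k1, k2, kappa, K, full_invariants(0/1)}
//   type 4 NH  : params = {lambda, mu}   (compressible neo-Hookean,
//                W = mu/2 (I1-3) - mu ln J + lambda/2 (ln J)^2; the stable
//                large-strain extension of linear elasticity)
#include <Rcpp.h>
#include <complex>
#include <cmath>
using namespace Rcpp;

typedef std::complex<double> cplx;

namespace {

inline double re(double x) { return x; }
inline double re(const cplx& x) { return x.real(); }

template <typename T>
inline T det3(const T* A) {
  return A[0] * (A[4] * A[8] - A[5] * A[7])
       - A[1] * (A[3] * A[8] - A[5] * A[6])
       + A[2] * (A[3] * A[7] - A[4] * A[6]);
}

template <typename T>
inline void inv3(const T* A, T* Ai) {
  T d = det3(A);
  Ai[0] =  (A[4] * A[8] - A[5] * A[7]) / d;
  Ai[1] = -(A[1] * A[8] - A[2] * A[7]) / d;
  Ai[2] =  (A[1] * A[5] - A[2] * A[4]) / d;
  Ai[3] = -(A[3] * A[8] - A[5] * A[6]) / d;
  Ai[4] =  (A[0] * A[8] - A[2] * A[6]) / d;
  Ai[5] = -(A[0] * A[5] - A[2] * A[3]) / d;
  Ai[6] =  (A[3] * A[7] - A[4] * A[6]) / d;
  Ai[7] = -(A[0] * A[7] - A[1] * A[6]) / d;
  Ai[8] =  (A[0] * A[4] - A[1] * A[3]) / d;
}

// S = 2 dPsi/dC for the three models; C row-major 3x3.
template <typename T>
void pk2_kernel(const T* C, int type, const double* p,
                const double* M4, const double* M6, T* S) {
  const double I3[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
  if (type == 1) {  // SVK: S = lambda tr(E) I + 2 mu E
    double lambda = p[0], mu = p[1];
    T trE = T(0);
    for (int k = 0; k < 3; ++k) trE += (C[4 * k] - 1.0) * 0.5;
    for (int k = 0; k < 9; ++k) {
      T E = (C[k] - I3[k]) * 0.5;
      S[k] = lambda * trE * I3[k] + 2.0 * mu * E;
    }
    return;
  }
  T dC = det3(C);
  T Ci[9];
  inv3(C, Ci);
  T lnJ = T(0.5) * std::log(dC);
  T Jm23 = std::pow(dC, -1.0 / 3.0);
  T I1 = C[0] + C[4] + C[8];
  if (type == 4) {  // neo-Hookean: S = mu (I - Cinv) + lambda lnJ Cinv
    double lambda = p[0], mu = p[1];
    for (int k = 0; k < 9; ++k)
      S[k] = mu * (I3[k] - Ci[k]) + lambda * lnJ * Ci[k];
    return;
  }
  if (type == 2) {  // decoupled Mooney-Rivlin + U(J) = K/2 (ln J)^2
    double c1 = p[0], c2 = p[1], K = p[2];
    // dIb1/dC = Jm23 I - (1/3) Ib1 Cinv
    // dIb2/dC = Jm43 (I1 I - C) - (2/3) Ib2 Cinv
    T Jm43 = Jm23 * Jm23;
    T trC2 = T(0);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) trC2 += C[3 * i + j] * C[3 * j + i];
    T I2 = T(0.5) * (I1 * I1 - trC2);
    T Ib1 = Jm23 * I1, Ib2 = Jm43 * I2;
    for (int k = 0; k < 9; ++k) {
      T dIb1 = Jm23 * I3[k] - (Ib1 / 3.0) * Ci[k];
      T dIb2 = Jm43 * (I1 * I3[k] - C[k]) - (2.0 * Ib2 / 3.0) * Ci[k];
      S[k] = 2.0 * c1 * dIb1 + 2.0 * c2 * dIb2 + K * lnJ * Ci[k];
    }
    return;
  }
  if (type == 3) {  // HGO: ground + two dispersed tension-only fiber families
    double c = p[0], k1 = p[1], k2 = p[2], kap = p[3], K = p[4];
    bool full = p[5] > 0.5;
    T I1u = full ? I1 : Jm23 * I1;  // invariant actually used
    const double* Ms[2] = {M4, M6};
    T S4[2][9];
    T Eal[2];
    for (int f = 0; f < 2; ++f) {
      const double* M = Ms[f];
      T I4 = T(0);
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) I4 += M[i] * C[3 * i + j] * M[j];
      T I4u = full ? I4 : Jm23 * I4;
      Eal[f] = kap * (I1u - 3.0) + (1.0 - 3.0 * kap) * (I4u - 1.0);
      for (int k = 0; k < 9; ++k) {
        int i = k / 3, j = k % 3;
        T dI4 = full ? T(M[i] * M[j])
                     : Jm23 * M[i] * M[j] - (I4u / 3.0) * Ci[k];
        T dI1 = full ? T(I3[k]) : Jm23 * I3[k] - (I1u / 3.0) * Ci[k];
        S4[f][k] = kap * dI1 + (1.0 - 3.0 * kap) * dI4;  // dEalpha/dC
      }
    }
    for (int k = 0; k < 9; ++k) {
      T dI1 = full ? T(I3[k]) : Jm23 * I3[k] - (I1u / 3.0) * Ci[k];
      S[k] = c * dI1 + K * lnJ * Ci[k];
      for (int f = 0; f < 2; ++f) {
        if (re(Eal[f]) > 0.0) {  // Macaulay: compressed fibers carry no load
          T psi = k1 * Eal[f] * std::exp(k2 * Eal[f] * Eal[f]);
          S[k] += 2.0 * psi * S4[f][k];
        }
      }
    }
    return;
  }
  stop("unknown material type");
}

// Strain energy density (double only; the FD-of-energy oracle lives in R).
double energy_kernel(const double* C, int type, const double* p,
                     const double* M4, const double* M6) {
  const double I3[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
  if (type == 1) {
    double lambda = p[0], mu = p[1];
    double trE = 0, EE = 0;
    for (int k = 0; k < 9; ++k) {
      double E = (C[k] - I3[k]) * 0.5;
      EE += E * E;
      if (k % 4 == 0) trE += E;
    }
    return 0.5 * lambda * trE * trE + mu * EE;
  }
  double dC = det3(C);
  if (dC <= 0) stop("deformation state has non-positive det(C)");
  double lnJ = 0.5 * std::log(dC);
  double Jm23 = std::pow(dC, -1.0 / 3.0);
  double I1 = C[0] + C[4] + C[8];
  if (type == 4) {
    double lambda = p[0], mu = p[1];
    return 0.5 * mu * (I1 - 3.0) - mu * lnJ + 0.5 * lambda * lnJ * lnJ;
  }
  if (type == 2) {
    double c1 = p[0], c2 = p[1], K = p[2];
    double trC2 = 0;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) trC2 += C[3 * i + j] * C[3 * j + i];
    double I2 = 0.5 * (I1 * I1 - trC2);
    return c1 * (Jm23 * I1 - 3.0) + c2 * (Jm23 * Jm23 * I2 - 3.0) +
           0.5 * K * lnJ * lnJ;
  }
  if (type == 3) {
    double c = p[0], k1 = p[1], k2 = p[2], kap = p[3], K = p[4];
    bool full = p[5] > 0.5;
    double I1u = full ? I1 : Jm23 * I1;
    double W = 0.5 * c * (I1u - 3.0) + 0.5 * K * lnJ * lnJ;
    const double* Ms[2] = {M4, M6};
    for (int f = 0; f < 2; ++f) {
      double I4 = 0;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) I4 += Ms[f][i] * C[3 * i + j] * Ms[f][j];
      double I4u = full ? I4 : Jm23 * I4;
      double Eal = kap * (I1u - 3.0) + (1.0 - 3.0 * kap) * (I4u - 1.0);
      if (Eal > 0)
        W += k1 / (2.0 * k2) * (std::exp(k2 * Eal * Eal) - 1.0);
    }
    return W;
  }
  stop("unknown material type");
}

// 6x6 tangent dS/dE (Voigt order 11,22,33,12,23,13; engineering shear) by
// complex step on C: dC = 2 dE on diagonal, dC_ij = dE_ij(engineering) off.
void tangent_kernel(const double* C, int type, const double* p,
                    const double* M4, const double* M6, double* D /*36*/) {
  if (type == 1) {  // SVK: constant tangent, closed form
    double lambda = p[0], mu = p[1];
    for (int k = 0; k < 36; ++k) D[k] = 0.0;
    for (int a = 0; a < 3; ++a) {
      for (int b = 0; b < 3; ++b) D[6 * a + b] = lambda;
      D[6 * a + a] += 2.0 * mu;
      D[6 * (a + 3) + (a + 3)] = mu;  // engineering shear columns
    }
    return;
  }
  const int vi[6] = {0, 1, 2, 0, 1, 0};
  const int vj[6] = {0, 1, 2, 1, 2, 2};
  const double h = 1e-20;
  cplx Cc[9], S[9];
  for (int col = 0; col < 6; ++col) {
    for (int k = 0; k < 9; ++k) Cc[k] = cplx(C[k], 0.0);
    int i = vi[col], j = vj[col];
    if (i == j) {
      Cc[3 * i + j] += cplx(0.0, 2.0 * h);
    } else {
      Cc[3 * i + j] += cplx(0.0, h);
      Cc[3 * j + i] += cplx(0.0, h);
    }
    pk2_kernel<cplx>(Cc, type, p, M4, M6, S);
    for (int row = 0; row < 6; ++row)
      D[6 * row + col] = S[3 * vi[row] + vj[row]].imag() / h;
  }
  // hyperelastic major symmetry holds analytically; enforce it exactly
  for (int a = 0; a < 6; ++a)
    for (int b = a + 1; b < 6; ++b) {
      double m = 0.5 * (D[6 * a + b] + D[6 * b + a]);
      D[6 * a + b] = m;
      D[6 * b + a] = m;
    }
}

inline void ctf(const double* F, double* C) {  // C = F^T F
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += F[3 * k + i] * F[3 * k + j];
      C[3 * i + j] = s;
    }
}

inline void push_forward(const double* F, const double* S, double* sig) {
  double J = det3(F);
  double FS[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += F[3 * i + k] * S[3 * k + j];
      FS[3 * i + j] = s;
    }
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += FS[3 * i + k] * F[3 * j + k];
      sig[3 * i + j] = s / J;
    }
}

void get9(const NumericMatrix& M, double* out) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) out[3 * i + j] = M(i, j);
}

}  // namespace

// [[Rcpp::export]]
double cpp_energy(NumericMatrix F, int type, NumericVector params,
                  NumericVector M4, NumericVector M6) {
  double Fm[9], C[9];
  get9(F, Fm);
  if (det3(Fm) <= 0) stop("deformation state has non-positive J");
  ctf(Fm, C);
  return energy_kernel(C, type, &params[0], &M4[0], &M6[0]);
}

// [[Rcpp::export]]
NumericMatrix cpp_pk2(NumericMatrix Cm, int type, NumericVector params,
                      NumericVector M4, NumericVector M6) {
  double C[9], S[9];
  get9(Cm, C);
  if (det3(C) <= 0) stop("deformation state has non-positive det(C)");
  pk2_kernel<double>(C, type, &params[0], &M4[0], &M6[0], S);
  NumericMatrix out(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = S[3 * i + j];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_cauchy(NumericMatrix F, int type, NumericVector params,
                         NumericVector M4, NumericVector M6) {
  double Fm[9], C[9], S[9], sig[9];
  get9(F, Fm);
  if (det3(Fm) <= 0) stop("deformation state has non-positive J");
  ctf(Fm, C);
  pk2_kernel<double>(C, type, &params[0], &M4[0], &M6[0], S);
  push_forward(Fm, S, sig);
  NumericMatrix out(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = sig[3 * i + j];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_tangent6(NumericMatrix Cm, int type, NumericVector params,
                           NumericVector M4, NumericVector M6) {
  double C[9], D[36];
  get9(Cm, C);
  tangent_kernel(C, type, &params[0], &M4[0], &M6[0], D);
  NumericMatrix out(6, 6);
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) out(a, b) = D[6 * a + b];
  return out;
}

namespace aaamech {
// internal hooks used by the assembly translation unit
void pk2_d(const double* C, int type, const double* p, const double* M4,
           const double* M6, double* S) {
  pk2_kernel<double>(C, type, p, M4, M6, S);
}
void tangent_d(const double* C, int type, const double* p, const double* M4,
               const double* M6, double* D) {
  tangent_kernel(C, type, p, M4, M6, D);
}
double det3_d(const double* A) { return det3(A); }
void ctf_d(const double* F, double* C) { ctf(F, C); }
void push_forward_d(const double* F, const double* S, double* sig) {
  push_forward(F, S, sig);
}
}  // namespace aaamech
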