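#include <Rcpp.h>
using namespace Rcpp;

// Total neo-Hookean energy and its gradient for a plane-strain trilayer
// under multiplicative uniaxial growth F = F_e F_g, F_g = diag(1+g, 1) in
// growing layers and I in the substrate. Linear (constant-strain) triangles:
// F is constant per element, the one-point quadrature is exact.
//
// Inputs (precomputed by the mesher):
//   u      : 2n displacement vector, (u1_1..u1_n, u2_1..u2_n)
//   tri    : m x 3 node indices (0-based)
//   bx, by : m x 3 shape-function gradients dN_a/dX1, dN_a/dX2
//   area   : m element reference areas
//   mu, lam: m Lame parameters per element
//   grows  : m 0/1 flag, 1 where the growth tensor applies
//   g      : growth parameter
// Returns list(energy, grad) where grad is the 2n gradient dPi/du.
// Elements with det F_e <= 0 contribute a large penalty so that line
// searches back off instead of crashing.
// [[Rcpp::export(name = ".nh_energy_grad")]]
List nh_energy_grad(NumericVector u, IntegerMatrix tri,
                    NumericMatrix bx, NumericMatrix by,
                    NumericVector area, NumericVector mu, NumericVector lam,
                    IntegerVector grows, double g,
                    bool want_grad = true) {
  const int m = tri.nrow();
  const int n = u.size() / 2;
  double E = 0.0;
  NumericVector grad(want_grad ? 2 * n : 0);
  bool inverted = false;
  const double ainv_g = 1.0 / (1.0 + g);
  const double Jg_g = 1.0 + g;

  for (int e = 0; e < m; ++e) {
    const int i0 = tri(e, 0), i1 = tri(e, 1), i2 = tri(e, 2);
    const double u1a = u[i0], u1b = u[i1], u1c = u[i2];
    const double u2a = u[n + i0], u2b = u[n + i1], u2c = u[n + i2];
    const double b0x = bx(e, 0), b1x = bx(e, 1), b2x = bx(e, 2);
    const double b0y = by(e, 0), b1y = by(e, 1), b2y = by(e, 2);

    double F11 = 1.0 + u1a * b0x + u1b * b1x + u1c * b2x;
    double F12 =       u1a * b0y + u1b * b1y + u1c * b2y;
    double F21 =       u2a * b0x + u2b * b1x + u2c * b2x;
    double F22 = 1.0 + u2a * b0y + u2b * b1y + u2c * b2y;

    const bool gr = grows[e] != 0;
    const double a = gr ? ainv_g : 1.0;   // F_e = F * diag(a, 1)
    const double Jg = gr ? Jg_g : 1.0;

    const double e11 = F11 * a, e21 = F21 * a, e12 = F12, e22 = F22;
    const double J = e11 * e22 - e12 * e21;
    if (J <= 1e-12) { inverted = true; E += 1e8 * area[e]; continue; }
    const double IC = e11 * e11 + e12 * e12 + e21 * e21 + e22 * e22;
    const double lnJ = std::log(J);
    const double psi = 0.5 * mu[e] * (IC - 2.0 - 2.0 * lnJ)
                     + 0.5 * lam[e] * lnJ * lnJ;
    const double w = area[e] * Jg;
    E += w * psi;

    if (want_grad) {
      // P = dPsi/dF_e = mu (F_e - F_e^{-T}) + lam lnJ F_e^{-T}
      const double iJ = 1.0 / J;
      const double iT11 =  e22 * iJ, iT12 = -e21 * iJ;
      const double iT21 = -e12 * iJ, iT22 =  e11 * iJ;
      const double c = lam[e] * lnJ - mu[e];
      const double P11 = mu[e] * e11 + c * iT11;
      const double P12 = mu[e] * e12 + c * iT12;
      const double P21 = mu[e] * e21 + c * iT21;
      const double P22 = mu[e] * e22 + c * iT22;
      // dPi/dF = w * P * F_g^{-T}; F_g^{-1} = diag(a, 1)
      const double G11 = w * P11 * a, G12 = w * P12;
      const double G21 = w * P21 * a, G22 = w * P22;
      grad[i0]     += G11 * b0x + G12 * b0y;
      grad[i1]     += G11 * b1x + G12 * b1y;
      grad[i2]     += G11 * b2x + G12 * b2y;
      grad[n + i0] += G21 * b0x + G22 * b0y;
      grad[n + i1] += G21 * b1x + G22 * b1y;
      grad[n + i2] += G21 * b2x + G22 * b2y;
    }
  }
  return List::create(_["energy"] = E, _["grad"] = grad,
                      _["inverted"] = inverted);
}

// Per-element deformation and strain measures for post-processing.
// Returns m x 10 matrix: F11,F12,F21,F22,J,IC,e11,e12,e22,evm
// where e is the Green-Lagrange strain of F_e and evm the von Mises
// equivalent strain of its (2D) deviator.
// [[Rcpp::export(name = ".nh_strains")]]
NumericMatrix nh_strains(NumericVector u, IntegerMatrix tri,
                         NumericMatrix bx, NumericMatrix by,
                         IntegerVector grows, double g) {
  const int m = tri.nrow();
  const int n = u.size() / 2;
  NumericMatrix out(m, 10);
  const double ainv_g = 1.0 / (1.0 + g);
  for (int e = 0; e < m; ++e) {
    const int i0 = tri(e, 0), i1 = tri(e, 1), i2 = tri(e, 2);
    double F11 = 1.0, F12 = 0.0, F21 = 0.0, F22 = 1.0;
    const int idx[3] = {i0, i1, i2};
    for (int a = 0; a < 3; ++a) {
      F11 += u[idx[a]] * bx(e, a);
      F12 += u[idx[a]] * by(e, a);
      F21 += u[n + idx[a]] * bx(e, a);
      F22 += u[n + idx[a]] * by(e, a);
    }
    const double sc = grows[e] ? ainv_g : 1.0;
    const double e11f = F11 * sc, e21f = F21 * sc, e12f = F12, e22f = F22;
    const double J = e11f * e22f - e12f * e21f;
    const double IC = e11f * e11f + e12f * e12f + e21f * e21f + e22f * e22f;
    // Green-Lagrange e = (F_e^T F_e - I)/2
    const double C11 = e11f * e11f + e21f * e21f;
    const double C12 = e11f * e12f + e21f * e22f;
    const double C22 = e12f * e12f + e22f * e22f;
    const double gl11 = 0.5 * (C11 - 1.0);
    const double gl12 = 0.5 * C12;
    const double gl22 = 0.5 * (C22 - 1.0);
    const double tr = gl11 + gl22;
    const double d11 = gl11 - 0.5 * tr, d22 = gl22 - 0.5 * tr, d12 = gl12;
    const double evm = std::sqrt(2.0 * (d11 * d11 + d22 * d22 + 2.0 * d12 * d12) / 3.0);
    out(e, 0) = F11; out(e, 1) = F12; out(e, 2) = F21; out(e, 3) = F22;
    out(e, 4) = J;   out(e, 5) = IC;
    out(e, 6) = gl11; out(e, 7) = gl12; out(e, 8) = gl22; out(e, 9) = evm;
  }
  return out;
}
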