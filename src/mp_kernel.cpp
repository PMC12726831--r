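// Penalized mass-preserving transport objective and gradient.
//
// Evaluates, in two passes over the voxel grid, the functional
//   J(u) = sum (I0 + attach) |u|^2
//        + mp_pen * ||det(Df) I1(f) - I0||^2 / ||I0||^2
//        + curl_pen * mean |curl u|^2
//        + smooth_pen * mean |Du|^2
//        + fold_pen * sum (I0 + attach) max(det_min - det, 0)^2
//        + mass_pen * (sum det(Df) I1(f) - sum I0)^2
// with f = id + u, Jacobians by clamped central differences and I1 sampled
// by trilinear interpolation, plus its exact gradient (adjoint central
// differences of the nine divergence-form integrands). Mirrors the R
// reference implementation bit-for-bit in semantics; kept in C++ because
// this kernel dominates solver runtime.

#include <Rcpp.h>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export(name = ".cpp_mp_objective")]]
List cpp_mp_objective(NumericVector u, NumericVector I0, NumericVector I1,
                      IntegerVector dim, double attach, double I0_ss,
                      double mp_pen, double curl_pen, double smooth_pen,
                      double fold_pen, double det_min, double mass_pen,
                      bool want_grad) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const double *u1 = u.begin(), *u2 = u.begin() + N, *u3 = u.begin() + 2 * N;

  double cost = 0.0, mp = 0.0, curl = 0.0, elas = 0.0, fold = 0.0;
  double rsum = 0.0;
  double min_det = R_PosInf;

  std::vector<double> S(want_grad ? (size_t)(9 * N) : 0);
  std::vector<double> G0(want_grad ? (size_t)(3 * N) : 0);
  std::vector<double> A(want_grad ? (size_t)(3 * N) : 0);
  std::vector<double> B(want_grad ? (size_t)(9 * N) : 0);

  const double k_mp = 2.0 * mp_pen / I0_ss;
  const double k_c = 2.0 * curl_pen / (double)N;
  const double k_e = 2.0 * smooth_pen / (double)N;
  const double k_f = 2.0 * fold_pen;

  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      R_xlen_t row = sy * y + sz * z;
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = row + x;
        // clamped neighbour offsets
        R_xlen_t xp = i + (x < nx - 1 ? sx : 0), xm = i - (x > 0 ? sx : 0);
        R_xlen_t yp = i + (y < ny - 1 ? sy : 0), ym = i - (y > 0 ? sy : 0);
        R_xlen_t zp = i + (z < nz - 1 ? sz : 0), zm = i - (z > 0 ? sz : 0);

        // Jacobian of displacement: g[a][b] = D_b u_a
        double g11 = 0.5 * (u1[xp] - u1[xm]);
        double g12 = 0.5 * (u1[yp] - u1[ym]);
        double g13 = 0.5 * (u1[zp] - u1[zm]);
        double g21 = 0.5 * (u2[xp] - u2[xm]);
        double g22 = 0.5 * (u2[yp] - u2[ym]);
        double g23 = 0.5 * (u2[zp] - u2[zm]);
        double g31 = 0.5 * (u3[xp] - u3[xm]);
        double g32 = 0.5 * (u3[yp] - u3[ym]);
        double g33 = 0.5 * (u3[zp] - u3[zm]);

        double m11 = 1.0 + g11, m12 = g12, m13 = g13;
        double m21 = g21, m22 = 1.0 + g22, m23 = g23;
        double m31 = g31, m32 = g32, m33 = 1.0 + g33;

        double C11 = m22 * m33 - m23 * m32;
        double C12 = -(m21 * m33 - m23 * m31);
        double C13 = m21 * m32 - m22 * m31;
        double C21 = -(m12 * m33 - m13 * m32);
        double C22 = m11 * m33 - m13 * m31;
        double C23 = -(m11 * m32 - m12 * m31);
        double C31 = m12 * m23 - m13 * m22;
        double C32 = -(m11 * m23 - m13 * m21);
        double C33 = m11 * m22 - m12 * m21;

        double det = m11 * C11 + m12 * C12 + m13 * C13;
        if (det < min_det) min_det = det;

        // trilinear sample of I1 at f = (x,y,z) + u (0-based continuous)
        double fx = x + u1[i], fy = y + u2[i], fz = z + u3[i];
        fx = fx < 0 ? 0 : (fx > nx - 1 ? nx - 1 : fx);
        fy = fy < 0 ? 0 : (fy > ny - 1 ? ny - 1 : fy);
        fz = fz < 0 ? 0 : (fz > nz - 1 ? nz - 1 : fz);
        int i0 = clampi((int)std::floor(fx), 0, nx - 2);
        int j0 = clampi((int)std::floor(fy), 0, ny - 2);
        int k0 = clampi((int)std::floor(fz), 0, nz - 2);
        double ax = fx - i0, ay = fy - j0, az = fz - k0;
        R_xlen_t b = sx * i0 + sy * j0 + sz * k0;
        double v000 = I1[b], v100 = I1[b + sx];
        double v010 = I1[b + sy], v110 = I1[b + sy + sx];
        double v001 = I1[b + sz], v101 = I1[b + sz + sx];
        double v011 = I1[b + sz + sy], v111 = I1[b + sz + sy + sx];
        double c00 = v000 * (1 - ax) + v100 * ax;
        double c10 = v010 * (1 - ax) + v110 * ax;
        double c01 = v001 * (1 - ax) + v101 * ax;
        double c11 = v011 * (1 - ax) + v111 * ax;
        double c0 = c00 * (1 - ay) + c10 * ay;
        double c1 = c01 * (1 - ay) + c11 * ay;
        double W = c0 * (1 - az) + c1 * az;

        double r = det * W - I0[i];
        rsum += r;
        double Wc = I0[i] + attach;
        cost += Wc * (u1[i] * u1[i] + u2[i] * u2[i] + u3[i] * u3[i]);
        mp += r * r;

        double w1 = g32 - g23, w2 = g13 - g31, w3 = g21 - g12;
        curl += w1 * w1 + w2 * w2 + w3 * w3;
        elas += g11 * g11 + g12 * g12 + g13 * g13 + g21 * g21 + g22 * g22 +
                g23 * g23 + g31 * g31 + g32 * g32 + g33 * g33;
        double h = det_min - det;
        if (h < 0) h = 0;
        fold += Wc * h * h;

        if (want_grad) {
          // exact partials of the interpolant
          double gWx = (v100 - v000) * (1 - ay) * (1 - az) +
                       (v110 - v010) * ay * (1 - az) +
                       (v101 - v001) * (1 - ay) * az + (v111 - v011) * ay * az;
          double gWy = (v010 - v000) * (1 - ax) * (1 - az) +
                       (v110 - v100) * ax * (1 - az) +
                       (v011 - v001) * (1 - ax) * az + (v111 - v101) * ax * az;
          double gWz = (v001 - v000) * (1 - ax) * (1 - ay) +
                       (v101 - v100) * ax * (1 - ay) +
                       (v011 - v010) * (1 - ax) * ay + (v111 - v110) * ax * ay;
          double cof_mult = -k_mp * r * W + k_f * Wc * h;
          double *Sv = S.data();
          Sv[i] = cof_mult * C11 - k_e * g11;
          Sv[N + i] = cof_mult * C12 - k_e * g12 + k_c * w3;
          Sv[2 * N + i] = cof_mult * C13 - k_e * g13 - k_c * w2;
          Sv[3 * N + i] = cof_mult * C21 - k_e * g21 - k_c * w3;
          Sv[4 * N + i] = cof_mult * C22 - k_e * g22;
          Sv[5 * N + i] = cof_mult * C23 - k_e * g23 + k_c * w1;
          Sv[6 * N + i] = cof_mult * C31 - k_e * g31 + k_c * w2;
          Sv[7 * N + i] = cof_mult * C32 - k_e * g32 - k_c * w1;
          Sv[8 * N + i] = cof_mult * C33 - k_e * g33;
          double rdet = k_mp * r * det;
          G0[i] = 2.0 * Wc * u1[i] + rdet * gWx;
          G0[N + i] = 2.0 * Wc * u2[i] + rdet * gWy;
          G0[2 * N + i] = 2.0 * Wc * u3[i] + rdet * gWz;
          A[i] = det * gWx;
          A[N + i] = det * gWy;
          A[2 * N + i] = det * gWz;
          B[i] = W * C11; B[N + i] = W * C12; B[2 * N + i] = W * C13;
          B[3 * N + i] = W * C21; B[4 * N + i] = W * C22;
          B[5 * N + i] = W * C23; B[6 * N + i] = W * C31;
          B[7 * N + i] = W * C32; B[8 * N + i] = W * C33;
        }
      }
    }
  }

  double J = cost + mp_pen * mp / I0_ss + curl_pen * curl / (double)N +
             smooth_pen * elas / (double)N + fold_pen * fold +
             mass_pen * rsum * rsum;

  List out = List::create(
      _["J"] = J, _["cost"] = cost, _["mp"] = mp / I0_ss,
      _["curl"] = curl / (double)N, _["elas"] = elas / (double)N,
      _["fold"] = fold,
      _["mp_residual"] = std::sqrt(mp / I0_ss), _["min_det"] = min_det,
      _["mass_dev"] = rsum);
  if (!want_grad) return out;

  // fold the total-mass term into the divergence-form integrands and the
  // pointwise gradient part
  const double cm = 2.0 * mass_pen * rsum;
  if (cm != 0.0) {
    for (R_xlen_t i = 0; i < N; ++i) {
      G0[i] += cm * A[i];
      G0[N + i] += cm * A[N + i];
      G0[2 * N + i] += cm * A[2 * N + i];
      for (int q = 0; q < 9; ++q) S[q * N + i] += -cm * B[q * N + i];
    }
  }

  NumericVector grad(3 * N);
  double *gu1 = grad.begin(), *gu2 = grad.begin() + N,
         *gu3 = grad.begin() + 2 * N;
  const double *Sv = S.data();
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      R_xlen_t row = sy * y + sz * z;
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = row + x;
        R_xlen_t xp = i + (x < nx - 1 ? sx : 0), xm = i - (x > 0 ? sx : 0);
        R_xlen_t yp = i + (y < ny - 1 ? sy : 0), ym = i - (y > 0 ? sy : 0);
        R_xlen_t zp = i + (z < nz - 1 ? sz : 0), zm = i - (z > 0 ? sz : 0);
        gu1[i] = G0[i] + 0.5 * (Sv[xp] - Sv[xm]) +
                 0.5 * (Sv[N + yp] - Sv[N + ym]) +
                 0.5 * (Sv[2 * N + zp] - Sv[2 * N + zm]);
        gu2[i] = G0[N + i] + 0.5 * (Sv[3 * N + xp] - Sv[3 * N + xm]) +
                 0.5 * (Sv[4 * N + yp] - Sv[4 * N + ym]) +
                 0.5 * (Sv[5 * N + zp] - Sv[5 * N + zm]);
        gu3[i] = G0[2 * N + i] + 0.5 * (Sv[6 * N + xp] - Sv[6 * N + xm]) +
                 0.5 * (Sv[7 * N + yp] - Sv[7 * N + ym]) +
                 0.5 * (Sv[8 * N + zp] - Sv[8 * N + zm]);
      }
    }
  }
  out["grad"] = grad;
  return out;
}
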