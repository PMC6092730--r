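#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Levenberg-Marquardt refinement of an object->camera pose over 6 params
// (rotation increment in so(3) around R0, translation), with the analytic
// reprojection Jacobian.  Mirrors the reference R implementation in
// R/camera.R (kept there as documentation/oracle).

static void rot_exp3(const double* w, double R[9]) {
  const double th = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  double K[9] = {0, w[2], -w[1], -w[2], 0, w[0], w[1], -w[0], 0}; // column-major
  if (th < 1e-12) {
    for (int i = 0; i < 9; ++i) R[i] = K[i];
    R[0] += 1; R[4] += 1; R[8] += 1;
    return;
  }
  const double a = std::sin(th) / th;
  const double b = (1 - std::cos(th)) / (th * th);
  double K2[9];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += K[k * 3 + r] * K[c * 3 + k];
      K2[c * 3 + r] = s;
    }
  for (int i = 0; i < 9; ++i) R[i] = a * K[i] + b * K2[i];
  R[0] += 1; R[4] += 1; R[8] += 1;
}

static void matmul3(const double* A, const double* B, double* C) {
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += A[k * 3 + r] * B[c * 3 + k];
      C[c * 3 + r] = s;
    }
}

// residuals for pose (R, t); returns false if any point is behind the camera
static bool residuals(const double* R, const double* t,
                      const NumericMatrix& P, const NumericMatrix& uv,
                      double f, double cx, double cy, double* r) {
  const int n = P.nrow();
  for (int i = 0; i < n; ++i) {
    const double X = P(i, 0), Y = P(i, 1), Z = P(i, 2);
    const double x = R[0] * X + R[3] * Y + R[6] * Z + t[0];
    const double y = R[1] * X + R[4] * Y + R[7] * Z + t[1];
    const double z = R[2] * X + R[5] * Y + R[8] * Z + t[2];
    if (z <= 1e-9) return false;
    r[i] = f * x / z + cx - uv(i, 0);
    r[n + i] = f * y / z + cy - uv(i, 1);
  }
  return true;
}

static bool solve6(double A[36], double b[6], double x[6]) {
  int piv[6];
  for (int i = 0; i < 6; ++i) piv[i] = i;
  for (int c = 0; c < 6; ++c) {
    int best = c;
    for (int r = c + 1; r < 6; ++r)
      if (std::fabs(A[c * 6 + r]) > std::fabs(A[c * 6 + best])) best = r;
    if (std::fabs(A[c * 6 + best]) < 1e-300) return false;
    if (best != c)
      for (int k = 0; k < 6; ++k) std::swap(A[k * 6 + c], A[k * 6 + best]);
    std::swap(b[c], b[best]);
    for (int r = c + 1; r < 6; ++r) {
      const double m = A[c * 6 + r] / A[c * 6 + c];
      for (int k = c; k < 6; ++k) A[k * 6 + r] -= m * A[k * 6 + c];
      b[r] -= m * b[c];
    }
  }
  for (int r = 5; r >= 0; --r) {
    double s = b[r];
    for (int k = r + 1; k < 6; ++k) s -= A[k * 6 + r] * x[k];
    x[r] = s / A[r * 6 + r];
  }
  return true;
}

// [[Rcpp::export(name = ".refine_pose_lm")]]
List refine_pose_lm(NumericMatrix R_init, NumericVector t_init,
                    NumericMatrix layout, NumericMatrix uv,
                    double f, NumericVector cc,
                    int max_iter = 100, double reltol = 1e-10) {
  const int n = layout.nrow();
  std::vector<double> r(2 * n), rc(2 * n);
  double R0[9], Rw[9], Rcur[9];
  for (int i = 0; i < 9; ++i) R0[i] = R_init[i];
  double t[3] = {t_init[0], t_init[1], t_init[2]};
  double lambda = 1e-3;
  bool converged = false;

  if (!residuals(R0, t, layout, uv, f, cc[0], cc[1], r.data()))
    return List::create(_["R"] = R_init, _["t"] = t_init,
                        _["rms"] = 1e6, _["converged"] = false);
  double cost = 0;
  for (int i = 0; i < 2 * n; ++i) cost += r[i] * r[i];

  std::vector<double> J(2 * n * 6);
  for (int it = 0; it < max_iter; ++it) {
    // analytic Jacobian at w = 0 around R0
    for (int i = 0; i < n; ++i) {
      const double X = layout(i, 0), Y = layout(i, 1), Z = layout(i, 2);
      const double x = R0[0] * X + R0[3] * Y + R0[6] * Z + t[0];
      const double y = R0[1] * X + R0[4] * Y + R0[7] * Z + t[1];
      const double z = R0[2] * X + R0[5] * Y + R0[8] * Z + t[2];
      const double iz = 1.0 / z, iz2 = iz * iz;
      // d p_cam / d w = -R0 * [P]x ; d p_cam / d t = I
      double dp[18];
      // columns w1..w3: R0 * (e_k x P) with (w x P) linearisation: d(exp(w)P)/dw|0 = -[P]x
      const double PX[9] = {0, Z, -Y, -Z, 0, X, Y, -X, 0}; // [P]x column-major
      for (int c2 = 0; c2 < 3; ++c2)
        for (int r2 = 0; r2 < 3; ++r2) {
          double s = 0;
          for (int k = 0; k < 3; ++k) s += R0[k * 3 + r2] * PX[c2 * 3 + k];
          dp[c2 * 3 + r2] = -s;
        }
      dp[9] = 1; dp[10] = 0; dp[11] = 0;
      dp[12] = 0; dp[13] = 1; dp[14] = 0;
      dp[15] = 0; dp[16] = 0; dp[17] = 1;
      for (int p = 0; p < 6; ++p) {
        const double dx = dp[p * 3], dy = dp[p * 3 + 1], dz = dp[p * 3 + 2];
        J[p * 2 * n + i] = f * (dx * iz - x * dz * iz2);
        J[p * 2 * n + n + i] = f * (dy * iz - y * dz * iz2);
      }
    }
    double A[36], g[6];
    for (int p = 0; p < 6; ++p) {
      g[p] = 0;
      for (int i = 0; i < 2 * n; ++i) g[p] += J[p * 2 * n + i] * r[i];
      for (int q = 0; q < 6; ++q) {
        double s = 0;
        for (int i = 0; i < 2 * n; ++i)
          s += J[p * 2 * n + i] * J[q * 2 * n + i];
        A[q * 6 + p] = s;
      }
    }
    bool improved = false;
    for (int k = 0; k < 12; ++k) {
      double Ad[36], b[6], step[6];
      for (int i = 0; i < 36; ++i) Ad[i] = A[i];
      for (int p = 0; p < 6; ++p) {
        Ad[p * 6 + p] += lambda * (A[p * 6 + p] + 1e-12);
        b[p] = g[p];
      }
      if (!solve6(Ad, b, step)) { lambda *= 10; continue; }
      const double w[3] = {-step[0], -step[1], -step[2]};
      rot_exp3(w, Rw);
      matmul3(R0, Rw, Rcur);
      double tc[3] = {t[0] - step[3], t[1] - step[4], t[2] - step[5]};
      if (!residuals(Rcur, tc, layout, uv, f, cc[0], cc[1], rc.data())) {
        lambda *= 10; continue;
      }
      double cost_c = 0;
      for (int i = 0; i < 2 * n; ++i) cost_c += rc[i] * rc[i];
      if (cost_c < cost) {
        const double rel = (cost - cost_c) / std::max(cost, 1e-300);
        for (int i = 0; i < 9; ++i) R0[i] = Rcur[i];
        t[0] = tc[0]; t[1] = tc[1]; t[2] = tc[2];
        r = rc;
        cost = cost_c;
        lambda = std::max(lambda / 10, 1e-12);
        improved = true;
        if (rel < reltol) converged = true;
        break;
      }
      lambda *= 10;
    }
    if (!improved) { converged = true; break; }
    if (converged) break;
  }
  NumericMatrix Rout(3, 3);
  for (int i = 0; i < 9; ++i) Rout[i] = R0[i];
  return List::create(_["R"] = Rout,
                      _["t"] = NumericVector::create(t[0], t[1], t[2]),
                      _["rms"] = std::sqrt(cost / n / 2.0),
                      _["converged"] = converged);
}
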