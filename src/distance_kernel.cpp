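#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Grid scan kernels for the inter-profile distance.
//
// Both profiles enter as relative copy numbers (u, v) on harmonized
// intervals with shared weights w. A grid point g of a sample is the affine
// correction q = A[g] * r + B[g]. The distance at a pair (i, j) is
//
//   d = mean_w |q1 - q2| / s,
//
// where s is the weighted population SD of the pooled corrected values of
// both profiles. Because the correction is affine, the pooled SD has a
// closed form in the first two weighted moments of u and v:
//
//   m1 = A1*mu_u + B1,  V1 = A1^2 * var_u   (same for sample 2)
//   s^2 = (V1 + V2)/2 + ((m1 - m2)/2)^2
//
// which is exact algebra (not an E[x^2]-m^2 shortcut), so only the weighted
// mean absolute difference needs the O(J) inner loop.
//
// Degenerate rule: s < eps means both corrected profiles are flat; the
// point contributes d = 0 when they are also equal (numerator < eps) and
// +Inf otherwise, excluding it from the minimization.

static void weighted_moments(const double* x, const double* w, int n,
                             double W, double& mean, double& var) {
  double m = 0.0;
  for (int k = 0; k < n; ++k) m += w[k] * x[k];
  m /= W;
  double s = 0.0;
  for (int k = 0; k < n; ++k) {
    double d = x[k] - m;
    s += w[k] * d * d;
  }
  mean = m;
  var = s / W;
}

// [[Rcpp::export]]
NumericMatrix cpp_dist_grid_matrix(NumericVector u, NumericVector v,
                                   NumericVector w,
                                   NumericVector A1, NumericVector B1,
                                   NumericVector A2, NumericVector B2,
                                   double eps) {
  const int J = u.size(), G1 = A1.size(), G2 = A2.size();
  const double* up = u.begin();
  const double* vp = v.begin();
  const double* wp = w.begin();
  double W = 0.0;
  for (int k = 0; k < J; ++k) W += wp[k];

  double mu_u, var_u, mu_v, var_v;
  weighted_moments(up, wp, J, W, mu_u, var_u);
  weighted_moments(vp, wp, J, W, mu_v, var_v);

  std::vector<double> m2(G2), V2(G2);
  for (int j = 0; j < G2; ++j) {
    m2[j] = A2[j] * mu_v + B2[j];
    V2[j] = A2[j] * A2[j] * var_v;
  }

  NumericMatrix out(G1, G2);
  for (int i = 0; i < G1; ++i) {
    const double a1 = A1[i], b1 = B1[i];
    const double m1 = a1 * mu_u + b1;
    const double V1 = a1 * a1 * var_u;
    for (int j = 0; j < G2; ++j) {
      const double a2 = A2[j], c = b1 - B2[j];
      double num = 0.0;
      for (int k = 0; k < J; ++k) {
        num += wp[k] * std::fabs(a1 * up[k] - a2 * vp[k] + c);
      }
      num /= W;
      const double dm = m1 - m2[j];
      const double s = std::sqrt(0.5 * (V1 + V2[j]) + 0.25 * dm * dm);
      double d;
      if (s < eps) {
        d = (num < eps) ? 0.0 : R_PosInf;
      } else {
        d = num / s;
      }
      out(i, j) = d;
    }
  }
  return out;
}

// Minimum-tracking scan with branch-and-bound pruning: because the pooled
// SD s of a pair is available in closed form *before* the O(J) loop, a pair
// can only beat the running best when its weighted absolute-difference sum
// stays below (best + tie_tol) * s * W; the accumulation is abandoned as
// soon as it crosses that threshold. `init_bound` seeds the running best
// (e.g. with the coarse-stage minimum); when no scanned pair beats it the
// function returns i = j = 0.
// [[Rcpp::export]]
List cpp_dist_grid_min(NumericVector u, NumericVector v, NumericVector w,
                       NumericVector A1, NumericVector B1,
                       NumericVector tau1, NumericVector alpha1,
                       NumericVector A2, NumericVector B2,
                       NumericVector tau2, NumericVector alpha2,
                       double eps, double tie_tol, double init_bound) {
  const int J = u.size(), G1 = A1.size(), G2 = A2.size();
  const double* up = u.begin();
  const double* vp = v.begin();
  const double* wp = w.begin();
  double W = 0.0;
  for (int k = 0; k < J; ++k) W += wp[k];

  double mu_u, var_u, mu_v, var_v;
  weighted_moments(up, wp, J, W, mu_u, var_u);
  weighted_moments(vp, wp, J, W, mu_v, var_v);

  std::vector<double> m2(G2), V2(G2);
  for (int j = 0; j < G2; ++j) {
    m2[j] = A2[j] * mu_v + B2[j];
    V2[j] = A2[j] * A2[j] * var_v;
  }

  double best_d = init_bound;
  int best_i = -1, best_j = -1;
  for (int i = 0; i < G1; ++i) {
    const double a1 = A1[i], b1 = B1[i];
    const double m1 = a1 * mu_u + b1;
    const double V1 = a1 * a1 * var_u;
    for (int j = 0; j < G2; ++j) {
      const double a2 = A2[j], c = b1 - B2[j];
      const double dm = m1 - m2[j];
      const double s = std::sqrt(0.5 * (V1 + V2[j]) + 0.25 * dm * dm);
      // largest raw sum that could still matter for min or tie-break
      double thr = R_PosInf;
      if (R_FINITE(best_d)) {
        thr = (s < eps) ? eps * W : (best_d + tie_tol) * s * W;
      }
      double num = 0.0;
      bool pruned = false;
      int k = 0;
      while (k < J) {
        const int kend = (k + 32 < J) ? k + 32 : J;
        for (; k < kend; ++k) {
          num += wp[k] * std::fabs(a1 * up[k] - a2 * vp[k] + c);
        }
        if (num > thr) { pruned = true; break; }
      }
      if (pruned && s >= eps) continue;
      num /= W;
      double d;
      if (s < eps) {
        d = (num < eps) ? 0.0 : R_PosInf;
      } else {
        d = num / s;
      }
      if (best_i < 0 && d <= best_d) {
        best_d = d; best_i = i; best_j = j;
        continue;
      }
      if (best_i < 0) continue;
      const bool tied = std::isfinite(d) && std::isfinite(best_d) &&
        std::fabs(d - best_d) <= tie_tol;
      if (!tied && d < best_d) {
        best_d = d; best_i = i; best_j = j;
      } else if (tied) {
        // lexicographic tie-break on (tau_a, -alpha_a, tau_b, -alpha_b)
        double ka[4] = {tau1[i], -alpha1[i], tau2[j], -alpha2[j]};
        double kb[4] = {tau1[best_i], -alpha1[best_i],
                        tau2[best_j], -alpha2[best_j]};
        bool better = false;
        for (int t = 0; t < 4; ++t) {
          if (ka[t] < kb[t]) { better = true; break; }
          if (ka[t] > kb[t]) break;
        }
        if (better || d < best_d) {
          if (better) { best_i = i; best_j = j; }
          if (d < best_d) best_d = d;
        }
      }
    }
  }
  return List::create(_["d"] = best_d,
                      _["i"] = best_i + 1,
                      _["j"] = best_j + 1);
}
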