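#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Longitudinal partial credit model, marginal likelihood kernel.
//
// Conditional model: theta[n,t] = beta*time_t + gamma*arm_n*time_t + u_n +
// v_n*time_t, with (u_n, v_n) ~ N(0, Sigma), Sigma = L L' parameterized by
// its Cholesky factor (log l11, l21, log l22). Item responses follow the
// adjacent-category partial credit model with per-item difficulty vectors.
// The per-patient integral over (u, v) is evaluated by mode/curvature
// adaptive Gauss-Hermite quadrature; everything runs in log space.
//
// Parameter packing: par = (beta, gamma, delta[item1], ..., delta[itemI],
//                           log l11, l21, log l22),
// each delta block of length J-1.

struct ObsDeriv {
  double s;   // dlogP/dtheta = (x-1) - E[K-1 | theta]
  double w;   // -d2logP/dtheta2 = Var(K-1 | theta)
  double lp;  // logP(x | theta)
};

// PCM log-probability of response x (1..J) plus theta-derivatives.
// steps[k] = sum_{l<=k} delta_l, steps[0] = 0.
static inline ObsDeriv pcm_obs(double theta, const double* steps, int J,
                               int x, double* tail /* size J, may be null */) {
  double psi[16];
  double mx = -1e300;
  for (int k = 0; k < J; ++k) {
    psi[k] = k * theta - steps[k];
    if (psi[k] > mx) mx = psi[k];
  }
  double sum = 0.0, m1 = 0.0, m2 = 0.0;
  double p[16];
  for (int k = 0; k < J; ++k) {
    p[k] = std::exp(psi[k] - mx);
    sum += p[k];
    m1 += k * p[k];
    m2 += double(k) * k * p[k];
  }
  const double inv = 1.0 / sum;
  m1 *= inv; m2 *= inv;
  if (tail) {
    // tail[l] = P(K-1 >= l), l = 1..J-1
    double acc = 0.0;
    for (int k = J - 1; k >= 1; --k) {
      acc += p[k] * inv;
      tail[k] = acc;
    }
  }
  ObsDeriv o;
  o.s = (x - 1) - m1;
  o.w = m2 - m1 * m1;
  o.lp = psi[x - 1] - mx - std::log(sum);
  return o;
}

// [[Rcpp::export]]
List lpcm_loglik_cpp(IntegerVector resp, int N, int T, int I, int J,
                     IntegerVector arm, NumericVector time,
                     NumericVector par, NumericVector gh_nodes,
                     NumericVector gh_logw, NumericMatrix modes,
                     bool want_grad) {
  const int K = J - 1;
  const int npar = 2 + I * K + 3;
  if (par.size() != npar) stop("parameter vector has wrong length");
  if (J > 15) stop("at most 15 response categories supported");

  const double beta = par[0], gamma = par[1];
  const double lam1 = par[2 + I * K], l21 = par[3 + I * K],
               lam2 = par[4 + I * K];
  const double l11 = std::exp(lam1), l22 = std::exp(lam2);
  // Sigma = L L'; Om = Sigma^{-1}
  const double s11 = l11 * l11, s12 = l11 * l21,
               s22 = l21 * l21 + l22 * l22;
  const double det = s11 * s22 - s12 * s12;
  if (!(det > 0) || !std::isfinite(det))
    stop("random-effect covariance is not positive definite");
  const double o11 = s22 / det, o12 = -s12 / det, o22 = s11 / det;

  // per-item cumulative difficulty steps
  std::vector<double> steps(I * J);
  for (int i = 0; i < I; ++i) {
    steps[i * J] = 0.0;
    for (int k = 1; k < J; ++k)
      steps[i * J + k] = steps[i * J + k - 1] + par[2 + i * K + (k - 1)];
  }

  const int nq = gh_nodes.size();
  const int nq2 = nq * nq;
  const double LOG2PI = 1.8378770664093453;

  double total = 0.0;
  NumericVector grad(npar);
  std::vector<double> term(nq2), du(nq2), dv(nq2);
  std::vector<double> nodegrad(want_grad ? (size_t)nq2 * npar : 0);
  std::vector<double> tail(J);

  for (int n = 0; n < N; ++n) {
    const int a = arm[n];
    // ---- Newton search for the posterior mode of (u, v) ----
    // h is strictly concave in (u, v); backtracking keeps ascent monotone.
    double u = modes(n, 0), v = modes(n, 1);
    double huu = 0, huv = 0, hvv = 0; // negative Hessian at mode
    auto eval_h = [&](double uu, double vv, double* g1, double* g2,
                      double* auu, double* auv, double* avv) -> double {
      double hv = -0.5 * (o11 * uu * uu + 2 * o12 * uu * vv +
                          o22 * vv * vv);
      if (g1) { *g1 = -(o11 * uu + o12 * vv); *g2 = -(o12 * uu + o22 * vv);
                *auu = o11; *auv = o12; *avv = o22; }
      for (int t = 0; t < T; ++t) {
        const double tim = time[t];
        const double th = beta * tim + gamma * a * tim + uu + vv * tim;
        for (int i = 0; i < I; ++i) {
          const int x = resp[n + (size_t)N * (t + (size_t)T * i)];
          if (x == NA_INTEGER) continue;
          ObsDeriv o = pcm_obs(th, &steps[i * J], J, x, nullptr);
          hv += o.lp;
          if (g1) {
            *g1 += o.s;   *g2 += o.s * tim;
            *auu += o.w;  *auv += o.w * tim;  *avv += o.w * tim * tim;
          }
        }
      }
      return hv;
    };
    double g1, g2;
    double hcur = eval_h(u, v, &g1, &g2, &huu, &huv, &hvv);
    for (int iter = 0; iter < 100; ++iter) {
      if (std::fabs(g1) < 1e-10 && std::fabs(g2) < 1e-10) break;
      const double hd = huu * hvv - huv * huv;
      double su = (hvv * g1 - huv * g2) / hd;
      double sv = (-huv * g1 + huu * g2) / hd;
      double stepnorm = std::sqrt(su * su + sv * sv);
      if (stepnorm < 1e-12) break;
      double step = 1.0, hnew = 0.0, un = u, vn = v;
      bool accepted = false;
      for (int ls = 0; ls < 40; ++ls) {
        un = u + step * su; vn = v + step * sv;
        hnew = eval_h(un, vn, nullptr, nullptr, nullptr, nullptr, nullptr);
        if (hnew >= hcur - 1e-14) { accepted = true; break; }
        step *= 0.5;
      }
      if (!accepted) break;
      u = un; v = vn;
      hcur = eval_h(u, v, &g1, &g2, &huu, &huv, &hvv);
      if (hnew - hcur > -1e-14 && std::fabs(g1) < 1e-8 &&
          std::fabs(g2) < 1e-8) break;
    }
    modes(n, 0) = u; modes(n, 1) = v;

    // scale matrix C: lower Cholesky of (-H)^{-1}
    const double hd = huu * hvv - huv * huv;
    const double p11 = hvv / hd, p12 = -huv / hd, p22 = huu / hd;
    const double c11 = std::sqrt(p11);
    const double c21 = p12 / c11;
    const double c22 = std::sqrt(p22 - c21 * c21);
    const double sqrt2 = 1.4142135623730951;

    // ---- quadrature ----
    double tmax = -1e300;
    for (int k1 = 0; k1 < nq; ++k1) {
      const double z1 = gh_nodes[k1];
      for (int k2 = 0; k2 < nq; ++k2) {
        const double z2 = gh_nodes[k2];
        const int k = k1 * nq + k2;
        const double bu = u + sqrt2 * c11 * z1;
        const double bv = v + sqrt2 * (c21 * z1 + c22 * z2);
        du[k] = bu; dv[k] = bv;
        // log prior
        const double a1 = bu / l11, a2 = (bv - l21 * a1) / l22;
        double lk = -LOG2PI - lam1 - lam2 - 0.5 * (a1 * a1 + a2 * a2);
        double* ng = want_grad ? &nodegrad[(size_t)k * npar] : nullptr;
        if (want_grad) {
          std::fill(ng, ng + npar, 0.0);
          // prior derivatives wrt (log l11, l21, log l22), b fixed
          double q2 = a2 / l22, q1 = (a1 - l21 * q2) / l11;
          ng[2 + I * K]     = l11 * q1 * a1 - 1.0;
          ng[3 + I * K]     = q2 * a1;
          ng[4 + I * K]     = l22 * q2 * a2 - 1.0;
        }
        for (int t = 0; t < T; ++t) {
          const double tim = time[t];
          const double th = beta * tim + gamma * a * tim + bu + bv * tim;
          for (int i = 0; i < I; ++i) {
            const int x = resp[n + (size_t)N * (t + (size_t)T * i)];
            if (x == NA_INTEGER) continue;
            ObsDeriv o = pcm_obs(th, &steps[i * J], J, x,
                                 want_grad ? tail.data() : nullptr);
            lk += o.lp;
            if (want_grad) {
              ng[0] += o.s * tim;
              ng[1] += o.s * tim * a;
              const int kx = x - 1;
              double* gd = ng + 2 + i * K;
              for (int l = 1; l < J; ++l)
                gd[l - 1] += tail[l] - (kx >= l ? 1.0 : 0.0);
            }
          }
        }
        term[k] = gh_logw[k1] + gh_logw[k2] + z1 * z1 + z2 * z2 + lk;
        if (term[k] > tmax) tmax = term[k];
      }
    }
    double ssum = 0.0;
    for (int k = 0; k < nq2; ++k) {
      term[k] = std::exp(term[k] - tmax);
      ssum += term[k];
    }
    total += std::log(2.0 * c11 * c22) + tmax + std::log(ssum);
    if (want_grad) {
      const double inv = 1.0 / ssum;
      for (int k = 0; k < nq2; ++k) {
        const double r = term[k] * inv;
        if (r < 1e-14) continue;
        const double* ng = &nodegrad[(size_t)k * npar];
        for (int p = 0; p < npar; ++p) grad[p] += r * ng[p];
      }
    }
  }

  if (want_grad)
    return List::create(_["loglik"] = total, _["gradient"] = grad);
  return List::create(_["loglik"] = total);
}
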