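#include <Rcpp.h>
using namespace Rcpp;

double pbvn1(double h, double k, double r);

// Full-information pair log-likelihood for the causal-contingent-common
// (CCC) liability model.  Latent structure per pair, with initiation
// liability L standardized to unit variance (identification constraint):
//
//   (L1, Q1, L2, Q2) ~ N(mean = (0, mu1, 0, mu2), Sigma) where
//   Var(L)      = 1
//   Var(Q)      = b^2 + A_q + C_q + E_q
//   Cov(L, Q)   = b                      (within person)
//   Cov(L1, L2) = rLL = rA * A_init + C_init
//   Cov(Q1, Q2) = b^2 * rLL + rA * A_q + C_q
//   Cov(L1, Q2) = b * rLL
//
// Twin i initiates iff L_i >= t_i; quantity Q_i is observed only for
// initiators, and may still be missing.  Observation patterns:
//
//   0  (no, no)                       6  (yes no-q, yes no-q)
//   1  (yes q1, no)                   7  (yes q1, yes no-q)
//   2  (no, yes q2)                   8  (yes no-q, yes q2)
//   3  (yes q1, yes q2)               9  singleton no
//   4  (yes no-q, no)                10  singleton yes with q1
//   5  (no, yes no-q)                11  singleton yes no-q
//
// Singleton patterns use the twin-1 slots; a co-twin with missing
// initiation is marginalized upstream into a singleton pattern.

struct CCCConfig {
  bool ok;
  double Vq, cQQ, detQ;
  double m1c, m2c;          // slopes of E[L1|Q1], E[L2|Q1] in (q1 - mu1)
  double v1c, v2c, rho1;    // Var(L1|Q1), Var(L2|Q1), Corr(L1,L2|Q1)
  double al, be;            // E[L|Q1,Q2] coefficients
  double v11g, rhog;        // Var(L_i|Q), Corr(L1,L2|Q)
  double rLL;
};

static CCCConfig make_config(double rLL, double b, double Aq, double Cq,
                             double Eq, double rA) {
  CCCConfig c;
  c.rLL = rLL;
  c.Vq = b * b + Aq + Cq + Eq;
  c.cQQ = b * b * rLL + rA * Aq + Cq;
  c.ok = R_FINITE(c.Vq) && c.Vq > 0 && std::fabs(rLL) < 1 &&
         std::fabs(c.cQQ) < c.Vq;
  if (!c.ok) return c;
  c.v1c = 1.0 - b * b / c.Vq;
  c.v2c = 1.0 - (b * rLL) * (b * rLL) / c.Vq;
  double c12c = rLL - b * (b * rLL) / c.Vq;
  c.detQ = c.Vq * c.Vq - c.cQQ * c.cQQ;
  c.al = (b * c.Vq - b * rLL * c.cQQ) / c.detQ;
  c.be = (b * rLL * c.Vq - b * c.cQQ) / c.detQ;
  c.v11g = 1.0 - (b * c.al + b * rLL * c.be);
  double c12g = rLL - (b * c.be + b * rLL * c.al);
  c.ok = c.v1c > 0 && c.v2c > 0 && c.v11g > 0 && c.detQ > 0;
  if (!c.ok) return c;
  c.rho1 = c12c / std::sqrt(c.v1c * c.v2c);
  c.rhog = c12g / c.v11g;  // equal conditional variances by symmetry
  c.ok = std::fabs(c.rho1) < 1 && std::fabs(c.rhog) < 1;
  c.m1c = b / c.Vq;
  c.m2c = b * rLL / c.Vq;
  return c;
}

static inline double lnphi(double e, double v) {
  return -0.5 * (std::log(2.0 * M_PI * v) + e * e / v);
}

static inline double phid(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }

// P(L1 in side1, L2 in side2) with L ~ BVN(m, v, rho); side +1 means > t.
static inline double rect2(double t1, double m1, double v1, double t2,
                           double m2, double v2, double rho, int s1,
                           int s2) {
  double a1 = (t1 - m1) / std::sqrt(v1);
  double a2 = (t2 - m2) / std::sqrt(v2);
  double p11 = pbvn1(a1, a2, rho);
  double p;
  if (s1 < 0 && s2 < 0) p = p11;
  else if (s1 > 0 && s2 < 0) p = phid(a2) - p11;
  else if (s1 < 0 && s2 > 0) p = phid(a1) - p11;
  else p = 1.0 - phid(a1) - phid(a2) + p11;
  return std::max(p, 0.0);
}

static double row_loglik(int pat, double t1, double t2, double q1,
                         double q2, double mu1, double mu2,
                         const CCCConfig &c) {
  double ll = 0, p = 1;
  double e1, e2, mc1, mc2;
  switch (pat) {
  case 0:  // (no, no)
    p = pbvn1(t1, t2, c.rLL);
    ll = std::log(p);
    break;
  case 1:  // (yes q1, no)
    e1 = q1 - mu1;
    ll = lnphi(e1, c.Vq);
    p = rect2(t1, c.m1c * e1, c.v1c, t2, c.m2c * e1, c.v2c, c.rho1,
              +1, -1);
    ll += std::log(p);
    break;
  case 2:  // (no, yes q2)
    e2 = q2 - mu2;
    ll = lnphi(e2, c.Vq);
    p = rect2(t1, c.m2c * e2, c.v2c, t2, c.m1c * e2, c.v1c, c.rho1,
              -1, +1);
    ll += std::log(p);
    break;
  case 3: {  // (yes q1, yes q2)
    e1 = q1 - mu1;
    e2 = q2 - mu2;
    double quad =
        (c.Vq * e1 * e1 - 2.0 * c.cQQ * e1 * e2 + c.Vq * e2 * e2) / c.detQ;
    ll = -std::log(2.0 * M_PI) - 0.5 * std::log(c.detQ) - 0.5 * quad;
    mc1 = c.al * e1 + c.be * e2;
    mc2 = c.be * e1 + c.al * e2;
    p = rect2(t1, mc1, c.v11g, t2, mc2, c.v11g, c.rhog, +1, +1);
    ll += std::log(p);
    break;
  }
  case 4:  // (yes no-q, no)
    p = rect2(t1, 0, 1, t2, 0, 1, c.rLL, +1, -1);
    ll = std::log(p);
    break;
  case 5:  // (no, yes no-q)
    p = rect2(t1, 0, 1, t2, 0, 1, c.rLL, -1, +1);
    ll = std::log(p);
    break;
  case 6:  // (yes no-q, yes no-q)
    p = rect2(t1, 0, 1, t2, 0, 1, c.rLL, +1, +1);
    ll = std::log(p);
    break;
  case 7:  // (yes q1, yes no-q)
    e1 = q1 - mu1;
    ll = lnphi(e1, c.Vq);
    p = rect2(t1, c.m1c * e1, c.v1c, t2, c.m2c * e1, c.v2c, c.rho1,
              +1, +1);
    ll += std::log(p);
    break;
  case 8:  // (yes no-q, yes q2)
    e2 = q2 - mu2;
    ll = lnphi(e2, c.Vq);
    p = rect2(t1, c.m2c * e2, c.v2c, t2, c.m1c * e2, c.v1c, c.rho1,
              +1, +1);
    ll += std::log(p);
    break;
  case 9:  // singleton, no
    ll = R::pnorm(t1, 0.0, 1.0, 1, 1);
    break;
  case 10:  // singleton, yes with quantity
    e1 = q1 - mu1;
    ll = lnphi(e1, c.Vq);
    ll += R::pnorm((t1 - c.m1c * e1) / std::sqrt(c.v1c), 0.0, 1.0, 0, 1);
    break;
  case 11:  // singleton, yes, quantity missing
    ll = R::pnorm(t1, 0.0, 1.0, 0, 1);
    break;
  default:
    stop("unknown observation pattern code: %d", pat);
  }
  return ll;
}

// [[Rcpp::export]]
NumericVector ccc_pair_loglik_cpp(IntegerVector pattern, NumericVector t1,
                                  NumericVector t2, NumericVector q1,
                                  NumericVector q2, NumericVector mu1,
                                  NumericVector mu2, double rLL, double b,
                                  double Aq, double Cq, double Eq,
                                  double rA, NumericVector weight) {
  R_xlen_t n = pattern.size();
  NumericVector out(n);
  CCCConfig c = make_config(rLL, b, Aq, Cq, Eq, rA);
  if (!c.ok) {
    std::fill(out.begin(), out.end(), R_NegInf);
    return out;
  }
  for (R_xlen_t i = 0; i < n; i++) {
    double ll = row_loglik(pattern[i], t1[i], t2[i], q1[i], q2[i],
                           mu1[i], mu2[i], c);
    out[i] = weight.size() ? weight[i] * ll : ll;
  }
  return out;
}

// Summed weighted log-likelihood over rows whose parameters are selected
// per row by cfg (0-based index into the columns of cfgmat); cfgmat rows:
// rLL, b, Aq, Cq, Eq, rA.  Returns -Inf on any invalid configuration or
// impossible observation.
// [[Rcpp::export]]
double ccc_loglik_sum_cpp(IntegerVector pattern, NumericVector t1,
                          NumericVector t2, NumericVector q1,
                          NumericVector q2, NumericVector mu1,
                          NumericVector mu2, NumericVector weight,
                          IntegerVector cfg, NumericMatrix cfgmat) {
  int K = cfgmat.ncol();
  std::vector<CCCConfig> cs(K);
  for (int k = 0; k < K; k++) {
    cs[k] = make_config(cfgmat(0, k), cfgmat(1, k), cfgmat(2, k),
                        cfgmat(3, k), cfgmat(4, k), cfgmat(5, k));
    if (!cs[k].ok) return R_NegInf;
  }
  R_xlen_t n = pattern.size();
  double tot = 0;
  for (R_xlen_t i = 0; i < n; i++) {
    double ll = row_loglik(pattern[i], t1[i], t2[i], q1[i], q2[i],
                           mu1[i], mu2[i], cs[cfg[i]]);
    if (ll == R_NegInf) return R_NegInf;
    tot += weight[i] * ll;
  }
  return tot;
}
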