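// HKY85 transition probabilities and Felsenstein pruning with discrete-gamma
// rate heterogeneity. Branch lengths are in expected substitutions per site
// (time is rescaled internally by the mean rate of the unnormalized chain).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State coding: A=0, C=1, G=2, T=3; >=4 means missing/ambiguous (gap, N).
// Purine class R = {A,G}, pyrimidine class Y = {C,T}.

static inline void hky_fill_pmat(double b, double kappa, const double *pi,
                                 double *P /* 16, row-major P[i*4+j] */) {
  if (b <= 0.0) {
    for (int i = 0; i < 16; ++i) P[i] = 0.0;
    P[0] = P[5] = P[10] = P[15] = 1.0;
    return;
  }
  const double piR = pi[0] + pi[2], piY = pi[1] + pi[3];
  // mean rate of the unnormalized chain (transversion rate 1, transition kappa)
  const double m = 2.0 * kappa * (pi[0] * pi[2] + pi[1] * pi[3]) + 2.0 * piR * piY;
  const double t = b / m;
  const double e1 = std::exp(-t);
  const double eR = std::exp(-(piR * kappa + piY) * t);
  const double eY = std::exp(-(piY * kappa + piR) * t);
  for (int i = 0; i < 4; ++i) {
    const bool iR = (i == 0 || i == 2);
    for (int j = 0; j < 4; ++j) {
      const bool jR = (j == 0 || j == 2);
      const double Pj = jR ? piR : piY;
      const double e2 = jR ? eR : eY;
      double p;
      if (iR != jR) {                       // transversion
        p = pi[j] * (1.0 - e1);
      } else if (i == j) {                  // no change
        p = pi[j] + pi[j] * (1.0 / Pj - 1.0) * e1 + ((Pj - pi[j]) / Pj) * e2;
      } else {                              // transition
        p = pi[j] + pi[j] * (1.0 / Pj - 1.0) * e1 - (pi[j] / Pj) * e2;
      }
      P[i * 4 + j] = p;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix hky_pmat_cpp(double b, double kappa, NumericVector pi) {
  double P[16];
  double pp[4] = { pi[0], pi[1], pi[2], pi[3] };
  hky_fill_pmat(b, kappa, pp, P);
  NumericMatrix out(4, 4);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = P[i * 4 + j];
  return out;
}

// Pruning log likelihood over site patterns.
//  edge: (nedge x 2) matrix of 1-based node ids (parent, child), postorder
//        (children appear as child before they appear as parent).
//  nnode_total = n_tip + n_internal; root has no incoming edge.
//  tipstate: (n_tip x npat) integer codes.
//  weights: pattern multiplicities.
//  rates: per-category relative rates (equal prior weight per category).
double prune_loglik_core(const IntegerMatrix &edge, int n_tip, int nnode_total,
                         const NumericVector &blen, const IntegerMatrix &tipstate,
                         const NumericVector &weights, double kappa,
                         const NumericVector &pi, const NumericVector &rates,
                         NumericVector *site_out) {
  const int nedge = edge.nrow(), npat = tipstate.ncol(), ncat = rates.size();
  const int root = [&]() {  // node never appearing as a child
    std::vector<bool> ischild(nnode_total + 1, false);
    for (int e = 0; e < nedge; ++e) ischild[edge(e, 1)] = true;
    for (int v = n_tip + 1; v <= nnode_total; ++v)
      if (!ischild[v]) return v;
    return n_tip + 1;
  }();
  double pp[4] = { pi[0], pi[1], pi[2], pi[3] };

  // per-category per-pattern log likelihood at the root
  std::vector<double> sitelog(npat, 0.0), catlog((size_t)npat * ncat);
  std::vector<double> part;   // partials for internal nodes, this category
  std::vector<double> scale;  // per-pattern log scaling, this category
  std::vector<double> Pm((size_t)nedge * 16);

  for (int k = 0; k < ncat; ++k) {
    for (int e = 0; e < nedge; ++e)
      hky_fill_pmat(blen[e] * rates[k], kappa, pp, &Pm[(size_t)e * 16]);
    part.assign((size_t)(nnode_total - n_tip) * npat * 4, 1.0);
    scale.assign(npat, 0.0);
    for (int e = 0; e < nedge; ++e) {
      const int p = edge(e, 0), c = edge(e, 1);
      const double *P = &Pm[(size_t)e * 16];
      double *pparent = &part[(size_t)(p - n_tip - 1) * npat * 4];
      if (c <= n_tip) {
        for (int s = 0; s < npat; ++s) {
          const int st = tipstate(c - 1, s);
          if (st >= 4) continue;  // missing: row sums to 1, multiply by 1
          double *pv = pparent + (size_t)s * 4;
          pv[0] *= P[st];  pv[1] *= P[4 + st];
          pv[2] *= P[8 + st]; pv[3] *= P[12 + st];
        }
      } else {
        double *pchild = &part[(size_t)(c - n_tip - 1) * npat * 4];
        for (int s = 0; s < npat; ++s) {
          double *cv = pchild + (size_t)s * 4;
          double mx = cv[0];
          if (cv[1] > mx) mx = cv[1];
          if (cv[2] > mx) mx = cv[2];
          if (cv[3] > mx) mx = cv[3];
          if (mx > 0 && mx < 1e-120) {  // rescale to avoid underflow
            const double inv = 1.0 / mx;
            cv[0] *= inv; cv[1] *= inv; cv[2] *= inv; cv[3] *= inv;
            scale[s] += std::log(mx);
          }
          double *pv = pparent + (size_t)s * 4;
          for (int a = 0; a < 4; ++a) {
            const double *Pr = P + a * 4;
            pv[a] *= Pr[0] * cv[0] + Pr[1] * cv[1] + Pr[2] * cv[2] + Pr[3] * cv[3];
          }
        }
      }
    }
    const double *proot = &part[(size_t)(root - n_tip - 1) * npat * 4];
    for (int s = 0; s < npat; ++s) {
      const double *rv = proot + (size_t)s * 4;
      const double L = pp[0] * rv[0] + pp[1] * rv[1] + pp[2] * rv[2] + pp[3] * rv[3];
      catlog[(size_t)s * ncat + k] =
          (L > 0) ? std::log(L) + scale[s] : -std::numeric_limits<double>::infinity();
    }
  }
  double total = 0.0;
  const double logK = std::log((double)ncat);
  for (int s = 0; s < npat; ++s) {
    const double *cl = &catlog[(size_t)s * ncat];
    double mx = cl[0];
    for (int k = 1; k < ncat; ++k)
      if (cl[k] > mx) mx = cl[k];
    double acc = 0.0;
    for (int k = 0; k < ncat; ++k) acc += std::exp(cl[k] - mx);
    const double sl = mx + std::log(acc) - logK;
    if (site_out) (*site_out)[s] = sl;
    total += weights[s] * sl;
  }
  return total;
}

// [[Rcpp::export]]
double prune_loglik_cpp(IntegerMatrix edge, int n_tip, int nnode_total,
                        NumericVector blen, IntegerMatrix tipstate,
                        NumericVector weights, double kappa, NumericVector pi,
                        NumericVector rates) {
  return prune_loglik_core(edge, n_tip, nnode_total, blen, tipstate, weights,
                           kappa, pi, rates, nullptr);
}

// [[Rcpp::export]]
NumericVector prune_sitelik_cpp(IntegerMatrix edge, int n_tip, int nnode_total,
                                NumericVector blen, IntegerMatrix tipstate,
                                NumericVector weights, double kappa,
                                NumericVector pi, NumericVector rates) {
  NumericVector out(tipstate.ncol());
  prune_loglik_core(edge, n_tip, nnode_total, blen, tipstate, weights, kappa,
                    pi, rates, &out);
  return out;
}
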