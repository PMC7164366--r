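// Metropolis-Hastings sampler for fossil-calibrated divergence dating.
//
// State: internal-node ages, per-partition branch rates (IR/AR), per-partition
// mean rates mu and diffusion/variance parameters sigma^2. Likelihood modes per
// partition: none (prior-only), exact HKY85+Gamma pruning (with partial-vector
// caching keyed to the edges a proposal touches), or the quadratic Taylor
// approximation around MLE branch lengths. The likelihood is raised to a power
// beta so the same sampler serves ordinary posteriors (beta = 1) and the power
// posteriors used by stepping-stone marginal-likelihood estimation.
//
// The cached exact likelihood deliberately skips partial rescaling: trees here
// are small (tens of tips) and patterns observed in data do not underflow; a
// zero site likelihood yields -Inf and the proposal is rejected.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline void hky_pmat16(double b, double kappa, const double *pi, double *P) {
  if (b <= 0.0) {
    for (int i = 0; i < 16; ++i) P[i] = 0.0;
    P[0] = P[5] = P[10] = P[15] = 1.0;
    return;
  }
  const double piR = pi[0] + pi[2], piY = pi[1] + pi[3];
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
      if (iR != jR) p = pi[j] * (1.0 - e1);
      else if (i == j) p = pi[j] + pi[j] * (1.0 / Pj - 1.0) * e1 + ((Pj - pi[j]) / Pj) * e2;
      else p = pi[j] + pi[j] * (1.0 / Pj - 1.0) * e1 - (pi[j] / Pj) * e2;
      P[i * 4 + j] = p;
    }
  }
}

static inline double dgamma_log(double x, double a, double b) {
  if (x <= 0) return NEG_INF;
  return a * std::log(b) - std::lgamma(a) + (a - 1.0) * std::log(x) - b * x;
}

static inline double lnorm_log(double x, double meanlog, double varlog) {
  if (x <= 0) return NEG_INF;
  if (varlog < 1e-12) varlog = 1e-12;
  const double z = std::log(x) - meanlog;
  return -std::log(x) - 0.5 * std::log(2.0 * M_PI * varlog) - z * z / (2.0 * varlog);
}

// Birth-death node-age kernel conditional on the root age t1.
static double bd_log_kernel(double t, double t1, double lam, double mud, double rho) {
  if (!(t > 0.0) || !(t < t1)) return NEG_INF;
  if (std::fabs(lam - mud) < 1e-12) {
    const double c = rho * lam;
    return std::log1p(c * t1) - std::log(t1) - 2.0 * std::log1p(c * t);
  }
  const double d = lam - mud;
  const auto P0 = [&](double s) {
    return rho * d / (rho * lam + (lam * (1.0 - rho) - mud) * std::exp(-d * s));
  };
  const double vt1 = 1.0 - P0(t1) * std::exp(-d * t1) / rho;
  const double p = P0(t);
  return std::log(lam) + 2.0 * std::log(p) - d * t - std::log(rho) - std::log(vt1);
}

// Calibration density: uniform mass 1-pL-pU on [tL,tU]; exponential upper
// tail and power lower tail matched to the interior density for continuity;
// zero tail probability means a hard bound (true zero density outside).
static double calib_logpdf(double t, double tL, double tU, double pL, double pU) {
  if (t <= 0) return NEG_INF;
  const double h = (1.0 - pL - pU) / (tU - tL);
  if (t >= tL && t <= tU) return std::log(h);
  if (t > tU) {
    if (pU <= 0) return NEG_INF;
    return std::log(h) - (t - tU) * (h / pU);
  }
  if (pL <= 0) return NEG_INF;
  const double theta = h * tL / pL - 1.0;
  return std::log(h) + theta * (std::log(t) - std::log(tL));
}

struct DetRNG {
  std::mt19937_64 eng;
  explicit DetRNG(uint64_t seed) : eng(seed ^ 0x9e3779b97f4a7c15ULL) {
    for (int i = 0; i < 8; ++i) eng();
  }
  double unif() { return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
};

struct Part {
  int mode = 0;  // 0 none, 1 exact, 2 approx
  double ll = 0.0, ll_pending = 0.0;
  // exact
  int npat = 0, ncat = 0;
  double kappa = 2.0;
  double pi[4] = {0.25, 0.25, 0.25, 0.25};
  std::vector<double> crates;
  std::vector<int> tip;       // [pat*ntip + tipindex] state codes
  std::vector<double> w;      // pattern weights
  std::vector<double> part;   // partials [cat][intnode][buf][pat*4]
  std::vector<int> nbuf;      // internal node -> current buffer
  std::vector<double> Pm;     // [cat][edge][buf][16]
  std::vector<int> pbuf;      // edge -> current buffer
  std::vector<int> pendN, pendE;  // pending dirty nodes / edges
  // approx
  std::vector<int> emap;      // rooted edge -> unrooted branch (0-based)
  std::vector<double> bhat, grad, H;
  int m = 0;
  double llhat = 0.0;
};

struct Sampler {
  int ntip, nint, nnode, nedge, root, clock, npart;
  std::vector<int> epar, echild, edge_of_node, parent, po_rank;
  std::vector<std::vector<int>> kid_edges;  // internal node -> child edge idx
  std::vector<int> po_int_nodes;            // internal nodes, postorder
  std::vector<double> age, mu, s2;
  std::vector<std::vector<double>> rate;    // [p][e]
  std::vector<Part> parts;
  NumericMatrix calib;   // rows: internal nodes (v - ntip - 1); cols kind,tL,tU,pL,pU
  double lam, mud, rho;
  double cur_prior = 0.0;
  // scratch
  std::vector<int> stamp_node;
  int stamp = 0;
  std::vector<int> dirtyN, dirtyE;
  std::vector<double> accbuf;

  double dur(int e) const { return age[epar[e]] - age[echild[e]]; }

  double log_prior() {
    double lp = 0.0;
    const double t1 = age[root];
    for (int e = 0; e < nedge; ++e)
      if (!(dur(e) > 0.0)) return NEG_INF;
    for (int v = ntip + 1; v <= nnode; ++v) {
      const int r = v - ntip - 1;
      const double t = age[v];
      if ((int)calib(r, 0) == 1)
        lp += calib_logpdf(t, calib(r, 1), calib(r, 2), calib(r, 3), calib(r, 4));
      else
        lp += bd_log_kernel(t, t1, lam, mud, rho);
      if (lp == NEG_INF) return NEG_INF;
    }
    double s = 0.0;
    for (int p = 0; p < npart; ++p) s += mu[p];
    s /= npart;
    lp += dgamma_log(s, 2.0, 20.0);
    if (npart > 1)  // gamma-Dirichlet (concentration 1) on partition mean rates
      lp += std::lgamma((double)npart) - npart * std::log((double)npart) -
            (npart - 1.0) * std::log(s);
    if (clock != 0) {
      for (int p = 0; p < npart; ++p) lp += dgamma_log(s2[p], 2.0, 2.0);
      if (clock == 1) {  // independent lognormal, expectation mu
        for (int p = 0; p < npart; ++p) {
          const double ml = std::log(mu[p]) - s2[p] / 2.0;
          for (int e = 0; e < nedge; ++e) lp += lnorm_log(rate[p][e], ml, s2[p]);
        }
      } else {           // autocorrelated: geometric Brownian motion on branches
        for (int p = 0; p < npart; ++p) {
          for (int e = 0; e < nedge; ++e) {
            const int pn = epar[e];
            double dt, ml;
            if (pn == root) {
              dt = dur(e) / 2.0;
              ml = std::log(mu[p]) - s2[p] * dt / 2.0;
            } else {
              const int pe = edge_of_node[pn];
              dt = (dur(pe) + dur(e)) / 2.0;
              ml = std::log(rate[p][pe]) - s2[p] * dt / 2.0;
            }
            lp += lnorm_log(rate[p][e], ml, s2[p] * dt);
          }
        }
      }
    }
    return lp;
  }

  // single AR prior term of edge e in partition p
  double ar_term(int p, int e) {
    const int pn = epar[e];
    double dt, ml;
    if (pn == root) {
      dt = dur(e) / 2.0;
      ml = std::log(mu[p]) - s2[p] * dt / 2.0;
    } else {
      const int pe = edge_of_node[pn];
      dt = (dur(pe) + dur(e)) / 2.0;
      ml = std::log(rate[p][pe]) - s2[p] * dt / 2.0;
    }
    return lnorm_log(rate[p][e], ml, s2[p] * dt);
  }

  // prior terms involving rate[p][e]: its own density, plus (AR) the terms
  // of the child branches for which it is the conditioning parent rate
  double rate_terms(int p, int e) {
    if (clock == 1)
      return lnorm_log(rate[p][e], std::log(mu[p]) - s2[p] / 2.0, s2[p]);
    double lp = ar_term(p, e);
    for (int ce : kid_edges[echild[e]]) lp += ar_term(p, ce);
    return lp;
  }

  double blen(int p, int e) const {
    const double r = (clock == 0) ? mu[p] : rate[p][e];
    return r * dur(e);
  }

  double approx_ll(Part &P) {
    accbuf.assign(P.m, 0.0);
    for (int e = 0; e < nedge; ++e) accbuf[P.emap[e]] += blen_p_e_cache(e);
    double ll = P.llhat;
    // d = b - bhat; ll += g'd + 0.5 d'Hd
    for (int i = 0; i < P.m; ++i) accbuf[i] -= P.bhat[i];
    for (int i = 0; i < P.m; ++i) {
      ll += P.grad[i] * accbuf[i];
      double hd = 0.0;
      const double *Hrow = &P.H[(size_t)i * P.m];
      for (int j = 0; j < P.m; ++j) hd += Hrow[j] * accbuf[j];
      ll += 0.5 * accbuf[i] * hd;
    }
    return ll;
  }
  int cur_p_ = 0;
  double blen_p_e_cache(int e) const { return blen(cur_p_, e); }

  // Recompute exact-partition likelihood after the edges in `edges` changed.
  double exact_ll(int pidx, Part &P, const std::vector<int> &edges) {
    ++stamp;
    dirtyN.clear();
    for (int e : edges) {
      int v = epar[e];
      while (v != 0 && stamp_node[v] != stamp) {
        stamp_node[v] = stamp;
        dirtyN.push_back(v);
        v = parent[v];
      }
    }
    std::sort(dirtyN.begin(), dirtyN.end(),
              [&](int a, int b) { return po_rank[a] < po_rank[b]; });
    ++stamp;  // mark dirty edges with a fresh stamp on a parallel array trick
    P.pendE.assign(edges.begin(), edges.end());
    P.pendN = dirtyN;
    std::vector<char> edirty(nedge, 0);
    for (int e : edges) edirty[e] = 1;
    std::vector<char> ndirty(nnode + 1, 0);
    for (int v : dirtyN) ndirty[v] = 1;
    const int npat = P.npat, ncat = P.ncat;
    for (int k = 0; k < ncat; ++k)
      for (int e : edges)
        hky_pmat16(blen(pidx, e) * P.crates[k], P.kappa, P.pi,
                   &P.Pm[(((size_t)k * nedge + e) * 2 + (1 - P.pbuf[e])) * 16]);
    accbuf.assign(npat, 0.0);
    for (int k = 0; k < ncat; ++k) {
      for (int v : dirtyN) {
        const int vi = v - ntip - 1;
        double *pv =
            &P.part[(((size_t)k * nint + vi) * 2 + (1 - P.nbuf[vi])) * npat * 4];
        for (int s = 0; s < npat * 4; ++s) pv[s] = 1.0;
        for (int ce : kid_edges[v]) {
          const int c = echild[ce];
          const int pb = edirty[ce] ? (1 - P.pbuf[ce]) : P.pbuf[ce];
          const double *Pmat = &P.Pm[(((size_t)k * nedge + ce) * 2 + pb) * 16];
          if (c <= ntip) {
            const int *ts = &P.tip[0];
            for (int s = 0; s < npat; ++s) {
              const int st = ts[(size_t)s * ntip + (c - 1)];
              if (st >= 4) continue;
              double *out = pv + (size_t)s * 4;
              out[0] *= Pmat[st];
              out[1] *= Pmat[4 + st];
              out[2] *= Pmat[8 + st];
              out[3] *= Pmat[12 + st];
            }
          } else {
            const int ci = c - ntip - 1;
            const int cb = ndirty[c] ? (1 - P.nbuf[ci]) : P.nbuf[ci];
            const double *cvv = &P.part[(((size_t)k * nint + ci) * 2 + cb) * npat * 4];
            for (int s = 0; s < npat; ++s) {
              const double *cv = cvv + (size_t)s * 4;
              double *out = pv + (size_t)s * 4;
              for (int a = 0; a < 4; ++a) {
                const double *Pr = Pmat + a * 4;
                out[a] *= Pr[0] * cv[0] + Pr[1] * cv[1] + Pr[2] * cv[2] + Pr[3] * cv[3];
              }
            }
          }
        }
      }
      const int ri = root - ntip - 1;
      const int rb = ndirty[root] ? (1 - P.nbuf[ri]) : P.nbuf[ri];
      const double *rv = &P.part[(((size_t)k * nint + ri) * 2 + rb) * npat * 4];
      for (int s = 0; s < npat; ++s) {
        const double *v4 = rv + (size_t)s * 4;
        accbuf[s] += P.pi[0] * v4[0] + P.pi[1] * v4[1] + P.pi[2] * v4[2] + P.pi[3] * v4[3];
      }
    }
    double ll = 0.0;
    const double invK = 1.0 / ncat;
    for (int s = 0; s < npat; ++s) {
      const double L = accbuf[s] * invK;
      if (!(L > 0.0)) return NEG_INF;
      ll += P.w[s] * std::log(L);
    }
    return ll;
  }

  void commit_part(Part &P) {
    for (int v : P.pendN) P.nbuf[v - ntip - 1] = 1 - P.nbuf[v - ntip - 1];
    for (int e : P.pendE) P.pbuf[e] = 1 - P.pbuf[e];
    P.pendN.clear();
    P.pendE.clear();
    P.ll = P.ll_pending;
  }

  // Evaluate pending likelihoods of affected partitions for the current
  // (already-modified) state. `whichp` = -1 means all partitions.
  double pending_ll_total(const std::vector<int> &edges, int whichp, bool need_lik) {
    double tot = 0.0;
    for (int p = 0; p < npart; ++p) {
      Part &P = parts[p];
      if (P.mode == 0) { P.ll_pending = 0.0; continue; }
      if (!need_lik || (whichp >= 0 && whichp != p) || edges.empty()) {
        P.ll_pending = P.ll;
        P.pendN.clear();
        P.pendE.clear();
      } else if (P.mode == 2) {
        cur_p_ = p;
        P.ll_pending = approx_ll(P);
      } else {
        P.ll_pending = exact_ll(p, P, edges);
      }
      tot += P.ll_pending;
    }
    return tot;
  }

  double committed_ll_total() {
    double t = 0.0;
    for (auto &P : parts) t += P.ll;
    return t;
  }
};

// [[Rcpp::export]]
List run_mcmc_cpp(IntegerMatrix edge, int n_tip, NumericVector ages_init,
                  NumericMatrix calib, NumericVector bd, int clock, List parts_in,
                  NumericVector mu_init, NumericVector s2_init,
                  NumericMatrix rate_init, List settings) {
  Sampler S;
  S.ntip = n_tip;
  S.nedge = edge.nrow();
  S.nnode = S.nedge + 1;  // rooted tree: every node but the root has an edge
  S.nint = S.nnode - n_tip;
  S.clock = clock;
  S.npart = parts_in.size();
  S.calib = calib;
  S.lam = bd[0]; S.mud = bd[1]; S.rho = bd[2];
  S.epar.resize(S.nedge); S.echild.resize(S.nedge);
  S.edge_of_node.assign(S.nnode + 1, -1);
  S.parent.assign(S.nnode + 1, 0);
  S.kid_edges.assign(S.nnode + 1, {});
  for (int e = 0; e < S.nedge; ++e) {
    S.epar[e] = edge(e, 0);
    S.echild[e] = edge(e, 1);
    S.edge_of_node[edge(e, 1)] = e;
    S.parent[edge(e, 1)] = edge(e, 0);
    S.kid_edges[edge(e, 0)].push_back(e);
  }
  S.root = -1;
  for (int v = n_tip + 1; v <= S.nnode; ++v)
    if (S.edge_of_node[v] < 0) S.root = v;
  if (S.root < 0) stop("no root found");
  // postorder ranks for internal nodes (edge matrix is postorder)
  S.po_rank.assign(S.nnode + 1, 0);
  {
    int r = 0;
    std::vector<char> seen(S.nnode + 1, 0);
    for (int e = 0; e < S.nedge; ++e) {
      const int c = S.echild[e];
      if (c > n_tip && !seen[c]) { seen[c] = 1; S.po_rank[c] = r++; S.po_int_nodes.push_back(c); }
    }
    S.po_rank[S.root] = r;
    S.po_int_nodes.push_back(S.root);
  }
  S.age.assign(S.nnode + 1, 0.0);
  for (int v = 1; v <= S.nnode; ++v) S.age[v] = ages_init[v - 1];
  S.mu.assign(mu_init.begin(), mu_init.end());
  S.s2.assign(s2_init.begin(), s2_init.end());
  S.rate.assign(S.npart, std::vector<double>(S.nedge, 0.0));
  for (int p = 0; p < S.npart; ++p)
    for (int e = 0; e < S.nedge; ++e) S.rate[p][e] = rate_init(e, p);
  S.stamp_node.assign(S.nnode + 1, 0);

  // partitions
  S.parts.resize(S.npart);
  for (int p = 0; p < S.npart; ++p) {
    List pi_ = parts_in[p];
    Part &P = S.parts[p];
    P.mode = as<int>(pi_["mode"]);
    if (P.mode == 1) {
      IntegerMatrix ts = pi_["tipstate"];  // ntip x npat
      P.npat = ts.ncol();
      NumericVector w = pi_["weights"];
      P.w.assign(w.begin(), w.end());
      P.kappa = as<double>(pi_["kappa"]);
      NumericVector pv = pi_["pi"];
      for (int i = 0; i < 4; ++i) P.pi[i] = pv[i];
      NumericVector cr = pi_["rates"];
      P.crates.assign(cr.begin(), cr.end());
      P.ncat = P.crates.size();
      P.tip.assign((size_t)P.npat * n_tip, 4);
      for (int s = 0; s < P.npat; ++s)
        for (int t = 0; t < n_tip; ++t) P.tip[(size_t)s * n_tip + t] = ts(t, s);
      P.part.assign((size_t)P.ncat * S.nint * 2 * P.npat * 4, 1.0);
      P.nbuf.assign(S.nint, 0);
      P.Pm.assign((size_t)P.ncat * S.nedge * 2 * 16, 0.0);
      P.pbuf.assign(S.nedge, 0);
    } else if (P.mode == 2) {
      IntegerVector em = pi_["emap"];
      P.emap.resize(S.nedge);
      for (int e = 0; e < S.nedge; ++e) P.emap[e] = em[e] - 1;
      NumericVector bh = pi_["bhat"], gr = pi_["g"];
      P.bhat.assign(bh.begin(), bh.end());
      P.grad.assign(gr.begin(), gr.end());
      NumericMatrix H = pi_["H"];
      P.m = H.nrow();
      P.H.assign((size_t)P.m * P.m, 0.0);
      for (int i = 0; i < P.m; ++i)
        for (int j = 0; j < P.m; ++j) P.H[(size_t)i * P.m + j] = H(i, j);
      P.llhat = as<double>(pi_["logl_hat"]);
    }
  }

  const int n_iter = as<int>(settings["n_iter"]);
  const int sample_every = as<int>(settings["sample_every"]);
  const int burnin = as<int>(settings["burnin_sweeps"]);
  const double beta = as<double>(settings["beta"]);
  const bool tune = as<bool>(settings["tune"]);
  const uint64_t seed = (uint64_t)as<double>(settings["seed"]);
  NumericVector st = settings["steps"];  // age,root,rate,mu,s2,scale
  double w_age = st[0], w_root = st[1], w_rate = st[2], w_mu = st[3],
         w_s2 = st[4], w_scale = st[5];
  DetRNG rng(seed);
  const bool need_lik = beta > 0.0;

  // initial full evaluation
  std::vector<int> all_edges(S.nedge);
  for (int e = 0; e < S.nedge; ++e) all_edges[e] = e;
  S.cur_prior = S.log_prior();
  if (S.cur_prior == NEG_INF) stop("initial state has zero prior probability");
  for (int p = 0; p < S.npart; ++p) {
    Part &P = S.parts[p];
    if (P.mode == 1) { P.ll_pending = S.exact_ll(p, P, all_edges); S.commit_part(P); }
    else if (P.mode == 2) { S.cur_p_ = p; P.ll = S.approx_ll(P); }
    if (P.mode != 0 && !std::isfinite(P.ll)) stop("initial likelihood not finite");
  }

  const int nsample = n_iter / sample_every;
  const int ncol = S.nint + 3 * S.npart + 3;
  NumericMatrix samples(nsample, ncol);
  NumericVector ll_out(nsample);
  double att[6] = {0, 0, 0, 0, 0, 0}, acc[6] = {0, 0, 0, 0, 0, 0};
  double att_w[6] = {0, 0, 0, 0, 0, 0}, acc_w[6] = {0, 0, 0, 0, 0, 0};

  std::vector<int> mv_edges;
  auto decide = [&](double dprior, double dll, double jac) {
    const double la = beta * dll + dprior + jac;
    return la >= 0.0 || std::log(rng.unif()) < la;
  };

  auto try_move = [&](int cls, const std::vector<int> &edges, int whichp,
                      double jac,
                      double pr_pre = std::numeric_limits<double>::quiet_NaN()) {
    att[cls] += 1; att_w[cls] += 1;
    const double pr_new = std::isnan(pr_pre) ? S.log_prior() : pr_pre;
    bool ok = false;
    if (pr_new != NEG_INF) {
      const double ll_old = S.committed_ll_total();
      const double ll_new = S.pending_ll_total(edges, whichp, need_lik);
      if (std::isfinite(ll_new) || !need_lik)
        ok = decide(pr_new - S.cur_prior, ll_new - ll_old, jac);
    }
    if (ok) {
      S.cur_prior = pr_new;
      for (auto &P : S.parts)
        if (P.mode == 1 && !P.pendN.empty()) S.commit_part(P);
        else if (P.mode == 2) P.ll = P.ll_pending;
      acc[cls] += 1; acc_w[cls] += 1;
    } else {
      for (auto &P : S.parts) { P.pendN.clear(); P.pendE.clear(); }
    }
    return ok;
  };

  for (int iter = 0; iter < n_iter; ++iter) {
    // --- node-age moves ---
    for (int v : S.po_int_nodes) {
      if (v == S.root) continue;
      double lo = 0.0;
      for (int ce : S.kid_edges[v]) lo = std::max(lo, S.age[S.echild[ce]]);
      const double hi = S.age[S.parent[v]];
      if (!(hi > lo)) continue;
      const double told = S.age[v];
      const double w = w_age * (hi - lo);
      double tnew = told + (2.0 * rng.unif() - 1.0) * w;
      for (int k = 0; k < 4 && (tnew < lo || tnew > hi); ++k) {
        if (tnew < lo) tnew = 2.0 * lo - tnew;
        if (tnew > hi) tnew = 2.0 * hi - tnew;
      }
      if (tnew <= lo || tnew >= hi) continue;
      S.age[v] = tnew;
      mv_edges.clear();
      mv_edges.push_back(S.edge_of_node[v]);
      for (int ce : S.kid_edges[v]) mv_edges.push_back(ce);
      if (!try_move(0, mv_edges, -1, 0.0)) S.age[v] = told;
    }
    // --- root-age move (multiplier on the slack above the older child) ---
    {
      double lo = 0.0;
      for (int ce : S.kid_edges[S.root]) lo = std::max(lo, S.age[S.echild[ce]]);
      const double told = S.age[S.root];
      const double eps = w_root * (2.0 * rng.unif() - 1.0);
      const double tnew = lo + (told - lo) * std::exp(eps);
      S.age[S.root] = tnew;
      mv_edges = S.kid_edges[S.root];
      if (!try_move(1, mv_edges, -1, eps)) S.age[S.root] = told;
    }
    // --- branch-rate moves ---
    if (clock != 0) {
      for (int p = 0; p < S.npart; ++p) {
        for (int e = 0; e < S.nedge; ++e) {
          const double rold = S.rate[p][e];
          const double eps = w_rate * (2.0 * rng.unif() - 1.0);
          const double terms_old = S.rate_terms(p, e);
          S.rate[p][e] = rold * std::exp(eps);
          // only this rate's own (and AR-child) prior terms change
          const double pr_pre = S.cur_prior + (S.rate_terms(p, e) - terms_old);
          mv_edges.assign(1, e);
          if (!try_move(2, mv_edges, p, eps, pr_pre)) S.rate[p][e] = rold;
        }
      }
    }
    // --- hyperparameter moves ---
    for (int p = 0; p < S.npart; ++p) {
      const double mold = S.mu[p];
      const double eps = w_mu * (2.0 * rng.unif() - 1.0);
      S.mu[p] = mold * std::exp(eps);
      if (clock == 0) {
        mv_edges = all_edges;  // strict clock: mu is the rate on every branch
        if (!try_move(3, mv_edges, p, eps)) S.mu[p] = mold;
      } else {
        mv_edges.clear();
        if (!try_move(3, mv_edges, p, eps)) S.mu[p] = mold;
      }
    }
    if (clock != 0) {
      for (int p = 0; p < S.npart; ++p) {
        const double sold = S.s2[p];
        const double eps = w_s2 * (2.0 * rng.unif() - 1.0);
        S.s2[p] = sold * std::exp(eps);
        mv_edges.clear();
        if (!try_move(4, mv_edges, p, eps)) S.s2[p] = sold;
      }
    }
    // --- whole-tree scaling: ages * c, rates (and mu) / c; b = r t invariant ---
    {
      const double eps = w_scale * (2.0 * rng.unif() - 1.0);
      const double c = std::exp(eps);
      std::vector<double> age_old(S.age), mu_old(S.mu);
      std::vector<std::vector<double>> rate_old(S.rate);
      for (int v = n_tip + 1; v <= S.nnode; ++v) S.age[v] *= c;
      for (int p = 0; p < S.npart; ++p) S.mu[p] /= c;
      int nscaled_down = S.npart;
      if (clock != 0) {
        for (int p = 0; p < S.npart; ++p)
          for (int e = 0; e < S.nedge; ++e) S.rate[p][e] /= c;
        nscaled_down += S.npart * S.nedge;
      }
      const double jac = (S.nint - nscaled_down) * eps;
      mv_edges.clear();  // likelihood exactly invariant; caches stay valid
      if (!try_move(5, mv_edges, -1, jac)) {
        S.age = age_old; S.mu = mu_old; S.rate = rate_old;
      }
    }
    // --- burn-in step-size tuning toward 20-40% acceptance ---
    if (tune && iter < burnin && (iter + 1) % 25 == 0) {
      auto adj = [&](double &w, int cls, double lo2, double hi2) {
        if (att_w[cls] >= 5) {
          const double a = acc_w[cls] / att_w[cls];
          w *= std::exp(1.2 * (a - 0.3));
          if (w < lo2) w = lo2;
          if (w > hi2) w = hi2;
        }
        att_w[cls] = acc_w[cls] = 0;
      };
      adj(w_age, 0, 1e-4, 1.0);
      adj(w_root, 1, 1e-4, 5.0);
      adj(w_rate, 2, 1e-4, 10.0);
      adj(w_mu, 3, 1e-4, 10.0);
      adj(w_s2, 4, 1e-4, 10.0);
      adj(w_scale, 5, 1e-4, 5.0);
    }
    // --- record ---
    if ((iter + 1) % sample_every == 0) {
      S.cur_prior = S.log_prior();  // resync incremental prior updates
      const int row = (iter + 1) / sample_every - 1;
      int col = 0;
      for (int v = n_tip + 1; v <= S.nnode; ++v) samples(row, col++) = S.age[v];
      double lltot;
      if (need_lik) lltot = S.committed_ll_total();
      else {  // beta = 0: likelihood not tracked during moves; compute now
        lltot = 0.0;
        for (int p = 0; p < S.npart; ++p) {
          Part &P = S.parts[p];
          if (P.mode == 1) {
            P.ll_pending = S.exact_ll(p, P, all_edges);
            S.commit_part(P);
            lltot += P.ll;
          } else if (P.mode == 2) {
            S.cur_p_ = p; P.ll = S.approx_ll(P); lltot += P.ll;
          }
        }
      }
      for (int p = 0; p < S.npart; ++p) {
        samples(row, col++) = S.mu[p];
        samples(row, col++) = (clock == 0) ? 0.0 : S.s2[p];
        double mr = S.mu[p];
        if (clock != 0) {
          mr = 0.0;
          for (int e = 0; e < S.nedge; ++e) mr += S.rate[p][e];
          mr /= S.nedge;
        }
        samples(row, col++) = mr;
      }
      samples(row, col++) = lltot;
      samples(row, col++) = S.cur_prior;
      samples(row, col++) = beta * lltot + S.cur_prior;
      ll_out[row] = lltot;
    }
  }

  NumericVector accr(6), attv(6);
  for (int i = 0; i < 6; ++i) {
    attv[i] = att[i];
    accr[i] = att[i] > 0 ? acc[i] / att[i] : NA_REAL;
  }
  NumericVector steps_out =
      NumericVector::create(w_age, w_root, w_rate, w_mu, w_s2, w_scale);
  return List::create(_["samples"] = samples, _["loglik"] = ll_out,
                      _["acceptance"] = accr, _["attempts"] = attv,
                      _["steps"] = steps_out);
}
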