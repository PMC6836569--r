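#include <Rcpp.h>
using namespace Rcpp;

// HKY transition probability matrix, written into P (row-major 4x4,
// state order A, C, G, T). Branch length t is in expected substitutions
// per site; the rate matrix is normalized to unit mean rate.
static void hky_pmat(double t, double kappa, const double *pi, double *P) {
  const double piA = pi[0], piC = pi[1], piG = pi[2], piT = pi[3];
  const double piR = piA + piG, piY = piC + piT;
  // mean rate with beta = 1, alpha = kappa * beta
  const double scale =
      2.0 * (piA * piG * kappa + piC * piT * kappa + piR * piY);
  const double bt = t / scale;
  const double e2 = exp(-bt);
  const double e3 = exp(-(piR * kappa + piY) * bt);
  const double e4 = exp(-(piY * kappa + piR) * bt);
  // purines
  P[0 * 4 + 0] = piA + piA * piY / piR * e2 + piG / piR * e3;
  P[0 * 4 + 2] = piG + piG * piY / piR * e2 - piG / piR * e3;
  P[2 * 4 + 0] = piA + piA * piY / piR * e2 - piA / piR * e3;
  P[2 * 4 + 2] = piG + piG * piY / piR * e2 + piA / piR * e3;
  P[0 * 4 + 1] = P[2 * 4 + 1] = piC * (1.0 - e2);
  P[0 * 4 + 3] = P[2 * 4 + 3] = piT * (1.0 - e2);
  // pyrimidines
  P[1 * 4 + 1] = piC + piC * piR / piY * e2 + piT / piY * e4;
  P[1 * 4 + 3] = piT + piT * piR / piY * e2 - piT / piY * e4;
  P[3 * 4 + 1] = piC + piC * piR / piY * e2 - piC / piY * e4;
  P[3 * 4 + 3] = piT + piT * piR / piY * e2 + piC / piY * e4;
  P[1 * 4 + 0] = P[3 * 4 + 0] = piA * (1.0 - e2);
  P[1 * 4 + 2] = P[3 * 4 + 2] = piG * (1.0 - e2);
}

// [[Rcpp::export(name = ".hky_pmat_cpp")]]
NumericMatrix hky_pmat_cpp(double t, double kappa, NumericVector freqs) {
  NumericMatrix out(4, 4);
  double P[16];
  hky_pmat(t, kappa, freqs.begin(), P);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = P[i * 4 + j];
  return out;
}

// Felsenstein pruning log-likelihood under HKY for a fixed rooted binary
// topology. Nodes are numbered 1..n in topological order (root = 1).
// postorder: internal node indices, children-before-parents.
// children: 2-column matrix, row i = children of postorder[i].
// edge_len: substitution length of the branch above each node (unused for
// the root). patterns: ntip x npat integer matrix of states 1..4 (values
// outside 1..4 mean missing). tip_row: for each node, its row in patterns
// (0 for internal nodes). weights: pattern multiplicities.
// [[Rcpp::export(name = ".loglik_hky_cpp")]]
double loglik_hky_cpp(IntegerVector postorder, IntegerMatrix children,
                      NumericVector edge_len, IntegerMatrix patterns,
                      IntegerVector tip_row, NumericVector weights,
                      double kappa, NumericVector freqs) {
  const int nnode = tip_row.size();
  const int npat = patterns.ncol();
  const int ntip = patterns.nrow();
  const int nint = postorder.size();
  std::vector<double> pmat(16 * (nnode + 1));
  for (int v = 2; v <= nnode; ++v)
    hky_pmat(edge_len[v - 1], kappa, freqs.begin(), &pmat[16 * v]);
  std::vector<double> partial(4 * (nnode + 1));
  std::vector<double> site(npat);
  // pattern-major loop keeps the partial buffer tiny
  (void)ntip;
  for (int p = 0; p < npat; ++p) {
    for (int v = 1; v <= nnode; ++v) {
      const int r = tip_row[v - 1];
      if (r > 0) {
        double *pl = &partial[4 * v];
        const int s = patterns(r - 1, p);
        if (s >= 1 && s <= 4) {
          pl[0] = pl[1] = pl[2] = pl[3] = 0.0;
          pl[s - 1] = 1.0;
        } else {
          pl[0] = pl[1] = pl[2] = pl[3] = 1.0;
        }
      }
    }
    for (int k = 0; k < nint; ++k) {
      const int v = postorder[k];
      double *pl = &partial[4 * v];
      pl[0] = pl[1] = pl[2] = pl[3] = 1.0;
      for (int c = 0; c < 2; ++c) {
        const int w = children(k, c);
        const double *pw = &partial[4 * w];
        const double *P = &pmat[16 * w];
        for (int i = 0; i < 4; ++i) {
          double s = P[i * 4 + 0] * pw[0] + P[i * 4 + 1] * pw[1] +
                     P[i * 4 + 2] * pw[2] + P[i * 4 + 3] * pw[3];
          pl[i] *= s;
        }
      }
    }
    const double *pr = &partial[4 * 1];
    site[p] = freqs[0] * pr[0] + freqs[1] * pr[1] + freqs[2] * pr[2] +
              freqs[3] * pr[3];
  }
  double ll = 0.0;
  for (int p = 0; p < npat; ++p) {
    if (site[p] <= 0) return R_NegInf;
    ll += weights[p] * log(site[p]);
  }
  return ll;
}

// Waiting time from the origin of a clade (one stem lineage) to its first
// fossil, under a constant-rate birth-death process with Poisson fossil
// sampling. Returns NA when the clade dies or reaches t_max unfossilized.
// Per-simulation rates allow integrating over uncertainty intervals.
// [[Rcpp::export(name = ".first_fossil_times_cpp")]]
NumericVector first_fossil_times_cpp(int n_sims, NumericVector lambda,
                                     NumericVector mu, NumericVector psi,
                                     double t_max, int max_lineages) {
  NumericVector out(n_sims);
  RNGScope scope;
  for (int i = 0; i < n_sims; ++i) {
    const double la = lambda[i % lambda.size()];
    const double m = mu[i % mu.size()];
    const double ps = psi[i % psi.size()];
    double t = 0.0;
    int N = 1;
    double res = NA_REAL;
    if (ps <= 0.0) {
      out[i] = NA_REAL;
      continue;
    }
    while (true) {
      const double total = N * (la + m + ps);
      t += R::rexp(1.0 / total);
      if (t > t_max) break;
      const double u = R::runif(0.0, la + m + ps);
      if (u < ps) {
        res = t;
        break;
      } else if (u < ps + la) {
        if (++N > max_lineages) break;
      } else {
        if (--N == 0) break;
      }
    }
    out[i] = res;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Persistent pruning likelihood with per-node partial caching.
//
// Partials are stored state-major ([state][pattern]) per node so the inner
// loops vectorize over patterns. A proposal recomputes only the internal
// nodes above changed edges into a scratch buffer; accept copies them into
// the main buffer, reject discards them.
// ---------------------------------------------------------------------------
class PhyloLik {
 public:
  int n, npat, ntip;
  std::vector<int> parent, ch1, ch2, postorder, tip_row;
  std::vector<double> weights;
  std::vector<int> pat;  // ntip x npat, column-major as passed
  double kappa;
  double pi[4];
  std::vector<double> cur, prop;  // (n+1) * 4 * npat
  std::vector<int> pending;       // nodes living in prop buffer
  std::vector<char> in_prop;

  PhyloLik(IntegerVector parent_, IntegerVector postorder_,
           IntegerVector ch1_, IntegerVector ch2_, IntegerMatrix patterns,
           IntegerVector tip_row_, NumericVector weights_, double kappa_,
           NumericVector freqs) {
    n = parent_.size();
    npat = patterns.ncol();
    ntip = patterns.nrow();
    parent.assign(parent_.begin(), parent_.end());
    postorder.assign(postorder_.begin(), postorder_.end());
    ch1.assign(ch1_.begin(), ch1_.end());
    ch2.assign(ch2_.begin(), ch2_.end());
    tip_row.assign(tip_row_.begin(), tip_row_.end());
    weights.assign(weights_.begin(), weights_.end());
    pat.assign(patterns.begin(), patterns.end());
    kappa = kappa_;
    for (int i = 0; i < 4; ++i) pi[i] = freqs[i];
    cur.assign((size_t)(n + 1) * 4 * npat, 0.0);
    prop.assign((size_t)(n + 1) * 4 * npat, 0.0);
    in_prop.assign(n + 1, 0);
    // tip partials never change
    for (int v = 1; v <= n; ++v) {
      int r = tip_row[v - 1];
      if (r > 0) {
        double *pl = &cur[(size_t)v * 4 * npat];
        for (int p = 0; p < npat; ++p) {
          int s = pat[(size_t)(p)*ntip + (r - 1)];
          if (s >= 1 && s <= 4) {
            pl[(s - 1) * npat + p] = 1.0;
          } else {
            for (int i = 0; i < 4; ++i) pl[i * npat + p] = 1.0;
          }
        }
      }
    }
  }

  const double *read_buf(int v) const {
    return in_prop[v] ? &prop[(size_t)v * 4 * npat] : &cur[(size_t)v * 4 * npat];
  }

  void compute_node(int v, const std::vector<double> &el, bool to_prop) {
    double *out =
        to_prop ? &prop[(size_t)v * 4 * npat] : &cur[(size_t)v * 4 * npat];
    int kids[2] = {ch1[v - 1], ch2[v - 1]};
    for (int c = 0; c < 2; ++c) {
      int w = kids[c];
      double P[16];
      hky_pmat(el[w - 1], kappa, pi, P);
      const double *pw = read_buf(w);
      for (int i = 0; i < 4; ++i) {
        const double pi0 = P[i * 4 + 0], pi1 = P[i * 4 + 1],
                     pi2 = P[i * 4 + 2], pi3 = P[i * 4 + 3];
        double *o = out + (size_t)i * npat;
        const double *w0 = pw, *w1 = pw + npat, *w2 = pw + 2 * npat,
                     *w3 = pw + 3 * npat;
        if (c == 0) {
          for (int p = 0; p < npat; ++p)
            o[p] = pi0 * w0[p] + pi1 * w1[p] + pi2 * w2[p] + pi3 * w3[p];
        } else {
          for (int p = 0; p < npat; ++p)
            o[p] *= pi0 * w0[p] + pi1 * w1[p] + pi2 * w2[p] + pi3 * w3[p];
        }
      }
    }
  }

  double root_loglik() {
    const double *pr = read_buf(1);
    double ll = 0.0;
    for (int p = 0; p < npat; ++p) {
      double s = pi[0] * pr[p] + pi[1] * pr[npat + p] +
                 pi[2] * pr[2 * npat + p] + pi[3] * pr[3 * npat + p];
      if (s <= 0) return R_NegInf;
      ll += weights[p] * log(s);
    }
    return ll;
  }

  double set_full(const std::vector<double> &el) {
    pending.clear();
    std::fill(in_prop.begin(), in_prop.end(), 0);
    for (size_t k = 0; k < postorder.size(); ++k)
      compute_node(postorder[k], el, false);
    return root_loglik();
  }

  double propose(const std::vector<int> &nodes, const std::vector<double> &el) {
    // nodes: internal nodes needing recomputation, in postorder order
    pending = nodes;
    for (size_t k = 0; k < nodes.size(); ++k) {
      compute_node(nodes[k], el, true);
      in_prop[nodes[k]] = 1;
    }
    double ll = root_loglik();
    return ll;
  }

  void accept() {
    for (size_t k = 0; k < pending.size(); ++k) {
      int v = pending[k];
      memcpy(&cur[(size_t)v * 4 * npat], &prop[(size_t)v * 4 * npat],
             sizeof(double) * 4 * npat);
      in_prop[v] = 0;
    }
    pending.clear();
  }

  void reject() {
    for (size_t k = 0; k < pending.size(); ++k) in_prop[pending[k]] = 0;
    pending.clear();
  }
};

// [[Rcpp::export(name = ".lik_init_cpp")]]
SEXP lik_init_cpp(IntegerVector parent, IntegerVector postorder,
                  IntegerVector ch1, IntegerVector ch2,
                  IntegerMatrix patterns, IntegerVector tip_row,
                  NumericVector weights, double kappa, NumericVector freqs) {
  XPtr<PhyloLik> p(new PhyloLik(parent, postorder, ch1, ch2, patterns,
                                tip_row, weights, kappa, freqs));
  return p;
}

// [[Rcpp::export(name = ".lik_set_cpp")]]
double lik_set_cpp(SEXP xp, NumericVector edge_len) {
  XPtr<PhyloLik> p(xp);
  std::vector<double> el(edge_len.begin(), edge_len.end());
  return p->set_full(el);
}

// [[Rcpp::export(name = ".lik_propose_cpp")]]
double lik_propose_cpp(SEXP xp, IntegerVector nodes, NumericVector edge_len) {
  XPtr<PhyloLik> p(xp);
  std::vector<int> nd(nodes.begin(), nodes.end());
  std::vector<double> el(edge_len.begin(), edge_len.end());
  return p->propose(nd, el);
}

// [[Rcpp::export(name = ".lik_accept_cpp")]]
void lik_accept_cpp(SEXP xp) { XPtr<PhyloLik>(xp)->accept(); }

// [[Rcpp::export(name = ".lik_reject_cpp")]]
void lik_reject_cpp(SEXP xp) { XPtr<PhyloLik>(xp)->reject(); }

// ---------------------------------------------------------------------------
// Tree-prior fast paths used inside the MCMC loop. These mirror the exported
// R implementations (a test asserts agreement).
// ---------------------------------------------------------------------------
static inline double fbd_log_q(double t, double c1, double c2) {
  double e = exp(-c1 * t);
  return log(4.0) - c1 * t - 2.0 * log(e * (1.0 - c2) + (1.0 + c2));
}

static inline double fbd_p0(double t, double la, double mu, double ps,
                            double c1, double c2) {
  double e = exp(-c1 * t);
  double w = (e * (1.0 - c2) - (1.0 + c2)) / (e * (1.0 - c2) + (1.0 + c2));
  return (la + mu + ps + c1 * w) / (2.0 * la);
}

// FBD tree prior over ages + fossil attachments, conditioned on root age
// and two-sided sampling, including the lineage-count factor that
// marginalizes the attachment lineage within the assigned clade.
// [[Rcpp::export(name = ".fbd_prior_cpp")]]
double fbd_prior_cpp(NumericVector age, IntegerVector parent,
                     IntegerVector nonroot_int, int n_extant,
                     NumericVector att, NumericVector y, IntegerVector f_par,
                     IntegerVector desc_all, IntegerVector desc_fidx,
                     double d, double r, double s, double rho) {
  if (d <= 0 || r < 0 || r >= 1 || s < 0 || s >= 1) return R_NegInf;
  const double la = d / (1 - r);
  const double mu = d * r / (1 - r);
  const double ps = s * mu / (1 - s);
  const int m = att.size();
  const double x1 = age[0];
  for (int k = 0; k < nonroot_int.size(); ++k) {
    int v = nonroot_int[k];
    if (age[v - 1] <= 0 || age[v - 1] >= age[parent[v - 1] - 1])
      return R_NegInf;
  }
  for (int j = 0; j < m; ++j) {
    if (att[j] <= y[j] || att[j] >= age[f_par[j] - 1]) return R_NegInf;
  }
  if (m > 0 && ps <= 0) return R_NegInf;
  const double c1 = sqrt((la - mu - ps) * (la - mu - ps) + 4 * la * ps);
  if (c1 <= 0) return R_NegInf;
  const double c2 = -(la - mu - 2 * la * rho - ps) / c1;
  double ll = 2.0 * fbd_log_q(x1, c1, c2) -
              2.0 * log1p(-fbd_p0(x1, la, mu, ps, c1, c2)) +
              n_extant * log(rho);
  const double lla = log(la);
  for (int k = 0; k < nonroot_int.size(); ++k)
    ll += lla + fbd_log_q(age[nonroot_int[k] - 1], c1, c2);
  if (m > 0) {
    const double lps = log(ps);
    for (int j = 0; j < m; ++j) {
      ll += lla + fbd_log_q(att[j], c1, c2);
      ll += lps + log(fbd_p0(y[j], la, mu, ps, c1, c2)) -
            fbd_log_q(y[j], c1, c2);
    }
    // lineage multiplicity per fossil
    std::vector<int> mult(m, 1);
    for (int k = 0; k < desc_all.size(); ++k) {
      if (age[desc_all[k] - 1] > att[desc_fidx[k] - 1]) mult[desc_fidx[k] - 1]++;
    }
    for (int j = 0; j < m; ++j) ll += log((double)mult[j]);
  }
  return ll;
}

// Birth-death tree prior with rho-sampling plus CladeAge calibration
// densities (linear interpolation on a uniform grid) on stem ages.
// [[Rcpp::export(name = ".bd_cladeage_prior_cpp")]]
double bd_cladeage_prior_cpp(NumericVector age, IntegerVector parent,
                             IntegerVector nonroot_int, double d, double r,
                             double rho, IntegerVector ca_par,
                             NumericVector ca_y, NumericVector cal_dens,
                             double grid_max) {
  if (d <= 0 || r < 0 || r >= 1) return R_NegInf;
  const double la = d / (1 - r);
  const double mu = d * r / (1 - r);
  const double x1 = age[0];
  for (int k = 0; k < nonroot_int.size(); ++k) {
    int v = nonroot_int[k];
    if (age[v - 1] <= 0 || age[v - 1] >= age[parent[v - 1] - 1])
      return R_NegInf;
  }
  const double dd = la - mu;
  const double a = rho * la, b = la * (1 - rho) - mu;
  // p1/p0 of the rho-sampled reconstructed process
  double ebx = exp(-dd * x1);
  double denom1 = a + b * ebx;
  double lp1_root = log(rho) + 2 * log(dd) - dd * x1 - 2 * log(denom1);
  double p0_root = 1 - rho * dd / denom1;
  double ll = 2 * lp1_root - 2 * log1p(-p0_root);
  const double lla = log(la);
  for (int k = 0; k < nonroot_int.size(); ++k) {
    double t = age[nonroot_int[k] - 1];
    double e = exp(-dd * t);
    ll += lla + log(rho) + 2 * log(dd) - dd * t - 2 * log(a + b * e);
  }
  const int ng = cal_dens.size();
  const double step = grid_max / (ng - 1);
  for (int k = 0; k < ca_par.size(); ++k) {
    double delta = age[ca_par[k] - 1] - ca_y[k];
    if (delta < 0 || delta > grid_max) return R_NegInf;
    int i = (int)(delta / step);
    if (i >= ng - 1) i = ng - 2;
    double fr = delta / step - i;
    double dv = cal_dens[i] * (1 - fr) + cal_dens[i + 1] * fr;
    if (dv <= 0) return R_NegInf;
    ll += log(dv);
  }
  return ll;
}
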