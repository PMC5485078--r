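#include <Rcpp.h>
using namespace Rcpp;

// Variable-rate Brownian motion on a fixed binary time tree. The trait
// likelihood is the REML/contrast form: each independent contrast is normal
// with variance equal to the summed (adjusted) branch lengths of its cherry,
// where branch lengths have been multiplied by their per-branch rates. The
// root state is eliminated by REML, so no root parameter is sampled.
//
// Conventions shared with the R wrapper:
//  * edges are in postorder with the two child edges of each internal node
//    adjacent (rows 2i, 2i+1 share the parent);
//  * node indices are 0-based; tips are 0..ntip-1;
//  * parent_edge[e] is the postorder index of the edge above anc[e], or -1.

static double reml_loglik(const IntegerVector &anc, const IntegerVector &des,
                          const std::vector<double> &slen,
                          const NumericVector &xtip, int ntip, int nnode) {
  const int nn = ntip + nnode;
  std::vector<double> xv(nn), vv(nn, 0.0);
  for (int i = 0; i < ntip; ++i) xv[i] = xtip[i];
  double ll = 0.0;
  const int ne = anc.size();
  for (int i = 0; i < ne; i += 2) {
    const int p = anc[i], c1 = des[i], c2 = des[i + 1];
    const double v1 = slen[i] + vv[c1];
    const double v2 = slen[i + 1] + vv[c2];
    const double V = v1 + v2;
    const double c = xv[c1] - xv[c2];
    ll += -0.5 * (std::log(2.0 * M_PI * V) + c * c / V);
    xv[p] = (xv[c1] * v2 + xv[c2] * v1) / V;
    vv[p] = v1 * v2 / V;
  }
  return ll;
}

// Per-edge rates from the shift configuration: rate multipliers inherit
// down the tree, so rate[e] = sigma2_0 * prod(mult on root path to e).
// Edges are visited in preorder (reverse postorder).
static void edge_rates(const IntegerVector &parent_edge,
                       const std::vector<double> &mult, double sigma2,
                       std::vector<double> &rate) {
  const int ne = parent_edge.size();
  for (int i = ne - 1; i >= 0; --i) {
    const double up = (parent_edge[i] >= 0) ? rate[parent_edge[i]] : sigma2;
    rate[i] = up * mult[i];
  }
}

// [[Rcpp::export]]
double bm_pruning_loglik_cpp(IntegerVector anc, IntegerVector des,
                             NumericVector slen, NumericVector xtip,
                             int ntip, int nnode) {
  std::vector<double> sl(slen.begin(), slen.end());
  return reml_loglik(anc, des, sl, xtip, ntip, nnode);
}

static double lognormal_logpdf(double x, double sdlog) {
  const double lx = std::log(x);
  return -std::log(x) - 0.5 * std::log(2.0 * M_PI) - std::log(sdlog) -
         0.5 * lx * lx / (sdlog * sdlog);
}

// [[Rcpp::export]]
List rjmcmc_cpp(IntegerVector anc, IntegerVector des, NumericVector len,
                IntegerVector parent_edge, NumericVector xtip, int ntip,
                int nnode, int n_gen, int thin, double lambda_k,
                double mult_sdlog, double s2_lo, double s2_hi,
                double sigma2_init, NumericVector move_weights,
                double win_mult, double win_s2) {
  const int ne = anc.size();
  std::vector<double> mult(ne, 1.0), rate(ne), rate_prop(ne);
  std::vector<bool> shifted(ne, false);
  int k = 0;
  double sigma2 = sigma2_init;

  auto loglik_for = [&](const std::vector<double> &m, double s2,
                        std::vector<double> &r) {
    edge_rates(parent_edge, m, s2, r);
    std::vector<double> sl(ne);
    for (int i = 0; i < ne; ++i) sl[i] = len[i] * r[i];
    return reml_loglik(anc, des, sl, xtip, ntip, nnode);
  };

  double ll = loglik_for(mult, sigma2, rate);

  // cumulative move probabilities: 0 rate-scale, 1 sigma2-scale, 2 add,
  // 3 delete, 4 move, 5 swap
  std::vector<double> cum(6);
  double tot = 0.0;
  for (int i = 0; i < 6; ++i) tot += move_weights[i];
  double acc = 0.0;
  for (int i = 0; i < 6; ++i) {
    acc += move_weights[i] / tot;
    cum[i] = acc;
  }

  const int n_samples = n_gen / thin;
  NumericMatrix rates_out(n_samples, ne);
  IntegerVector k_out(n_samples), gen_out(n_samples);
  NumericVector s2_out(n_samples), ll_out(n_samples);
  IntegerVector prop_count(6), acc_count(6);

  std::vector<int> shift_ids, free_ids;
  shift_ids.reserve(ne);
  free_ids.reserve(ne);

  auto rebuild_ids = [&]() {
    shift_ids.clear();
    free_ids.clear();
    for (int i = 0; i < ne; ++i) {
      if (shifted[i]) shift_ids.push_back(i);
      else free_ids.push_back(i);
    }
  };
  rebuild_ids();

  int s = 0;
  for (int gen = 1; gen <= n_gen; ++gen) {
    const double u = R::runif(0.0, 1.0);
    int move = 0;
    while (move < 5 && u > cum[move]) ++move;

    bool feasible = true;
    double log_hastings = 0.0, log_prior_ratio = 0.0;
    std::vector<double> mult_prop = mult;
    double sigma2_prop = sigma2;
    int k_prop = k;
    int changed_edge = -1, changed_edge2 = -1;

    switch (move) {
    case 0: { // rescale one shift's multiplier (log sliding window)
      if (k == 0) { feasible = false; break; }
      const int e = shift_ids[(int)(R::unif_rand() * k) % k];
      const double m_new = mult[e] * std::exp(R::runif(-win_mult, win_mult));
      mult_prop[e] = m_new;
      log_hastings = std::log(m_new / mult[e]);
      log_prior_ratio =
          lognormal_logpdf(m_new, mult_sdlog) - lognormal_logpdf(mult[e], mult_sdlog);
      changed_edge = e;
      break;
    }
    case 1: { // rescale base rate sigma2_0 (log-uniform prior)
      const double s_new = sigma2 * std::exp(R::runif(-win_s2, win_s2));
      if (s_new < s2_lo || s_new > s2_hi) { feasible = false; break; }
      sigma2_prop = s_new;
      log_hastings = std::log(s_new / sigma2);
      log_prior_ratio = std::log(sigma2 / s_new); // density 1/s within bounds
      break;
    }
    case 2: { // add a shift on a uniformly chosen free edge
      const int nfree = (int)free_ids.size();
      if (nfree == 0) { feasible = false; break; }
      const int e = free_ids[(int)(R::unif_rand() * nfree) % nfree];
      const double m_new = std::exp(R::rnorm(0.0, mult_sdlog));
      mult_prop[e] = m_new;
      k_prop = k + 1;
      // Poisson(k) prior times the uniform placement prior 1/C(ne, k); the
      // multiplier prior cancels against its proposal (drawn from the
      // prior) and the placement prior against the uniform edge choice,
      // leaving lambda / (k + 1).
      log_prior_ratio = std::log(lambda_k) - std::log((double)k_prop);
      log_hastings = 0.0;
      changed_edge = e;
      break;
    }
    case 3: { // delete a uniformly chosen shift
      if (k == 0) { feasible = false; break; }
      const int e = shift_ids[(int)(R::unif_rand() * k) % k];
      mult_prop[e] = 1.0;
      k_prop = k - 1;
      // reverse of the add move: k / lambda
      log_prior_ratio = std::log((double)k) - std::log(lambda_k);
      log_hastings = 0.0;
      changed_edge = e;
      break;
    }
    case 4: { // relocate a shift to a uniformly chosen free edge (symmetric)
      const int nfree = (int)free_ids.size();
      if (k == 0 || nfree == 0) { feasible = false; break; }
      const int from = shift_ids[(int)(R::unif_rand() * k) % k];
      const int to = free_ids[(int)(R::unif_rand() * nfree) % nfree];
      mult_prop[to] = mult[from];
      mult_prop[from] = 1.0;
      changed_edge = from;
      changed_edge2 = to;
      break;
    }
    case 5: { // swap the multipliers of two shifts (symmetric)
      if (k < 2) { feasible = false; break; }
      const int i1 = (int)(R::unif_rand() * k) % k;
      int i2 = (int)(R::unif_rand() * (k - 1)) % (k - 1);
      if (i2 >= i1) ++i2;
      const int e1 = shift_ids[i1], e2 = shift_ids[i2];
      mult_prop[e1] = mult[e2];
      mult_prop[e2] = mult[e1];
      changed_edge = e1;
      changed_edge2 = e2;
      break;
    }
    }

    ++prop_count[move];
    if (feasible) {
      const double ll_prop = loglik_for(mult_prop, sigma2_prop, rate_prop);
      const double log_alpha = (ll_prop - ll) + log_prior_ratio + log_hastings;
      if (std::log(R::unif_rand()) < log_alpha) {
        ++acc_count[move];
        ll = ll_prop;
        sigma2 = sigma2_prop;
        mult.swap(mult_prop);
        rate.swap(rate_prop);
        k = k_prop;
        if (move == 2) shifted[changed_edge] = true;
        if (move == 3) shifted[changed_edge] = false;
        if (move == 4) {
          shifted[changed_edge] = false;
          shifted[changed_edge2] = true;
        }
        if (move == 2 || move == 3 || move == 4) rebuild_ids();
      }
    }

    if (gen % thin == 0) {
      for (int i = 0; i < ne; ++i) rates_out(s, i) = rate[i];
      k_out[s] = k;
      s2_out[s] = sigma2;
      ll_out[s] = ll;
      gen_out[s] = gen;
      ++s;
    }
  }

  return List::create(
      _["generation"] = gen_out, _["k"] = k_out, _["sigma2_0"] = s2_out,
      _["loglik"] = ll_out, _["rates"] = rates_out,
      _["proposed"] = prop_count, _["accepted"] = acc_count);
}
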