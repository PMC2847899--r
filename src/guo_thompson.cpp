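#include <Rcpp.h>
using namespace Rcpp;

// Guo & Thompson Markov chain for the exact conditional test of
// Hardy-Weinberg proportions.  State: genotype count table (k x k,
// counts kept on i <= j).  Proposal: pick two individuals at random,
// pick one gene copy from each, swap them.  The Hastings ratio is
// computed exactly from the forward and reverse proposal probabilities
// restricted to the (at most 4) cells a move touches.

static inline int cell(int i, int j, int k) {
  // row-major index with i <= j
  if (i > j) std::swap(i, j);
  return i * k + j;
}

// log conditional probability of the table up to an additive constant:
// h * log 2 - sum log(n_ij!)
static double log_table_prob(const std::vector<int>& tab, int k) {
  double lp = 0.0;
  for (int i = 0; i < k; ++i)
    for (int j = i; j < k; ++j) {
      int n = tab[cell(i, j, k)];
      lp -= lgamma((double)n + 1.0);
      if (i != j) lp += n * M_LN2;
    }
  return lp;
}

// probability that one proposal step transforms `from` into `to`;
// sources = cells losing count in the move (candidates for the two
// sampled individuals)
static double proposal_prob(const std::vector<int>& from,
                            const std::vector<int>& to,
                            int k, int n_ind) {
  // collect cells that lose counts
  std::vector<std::pair<int,int>> src;
  for (int i = 0; i < k; ++i)
    for (int j = i; j < k; ++j)
      if (to[cell(i, j, k)] < from[cell(i, j, k)])
        src.push_back(std::make_pair(i, j));
  if (src.empty()) return 0.0;
  double q = 0.0;
  std::vector<int> work(from.size());
  for (size_t a = 0; a < src.size(); ++a)
    for (size_t b = 0; b < src.size(); ++b) {
      int i1 = src[a].first, j1 = src[a].second;
      int i2 = src[b].first, j2 = src[b].second;
      int c1 = cell(i1, j1, k), c2 = cell(i2, j2, k);
      double n1 = from[c1];
      double n2 = from[c2] - (c1 == c2 ? 1.0 : 0.0);
      if (n1 <= 0 || n2 <= 0) continue;
      double p_pick = n1 * n2 / ((double)n_ind * (n_ind - 1));
      int al1[2] = { i1, j1 }, al2[2] = { i2, j2 };
      for (int x = 0; x < 2; ++x)
        for (int y = 0; y < 2; ++y) {
          // swap allele al1[x] with al2[y]
          work = from;
          work[c1] -= 1; work[c2] -= 1;
          int g1a = al1[1 - x], g1b = al2[y];   // ind 1 keeps other allele
          int g2a = al2[1 - y], g2b = al1[x];
          work[cell(g1a, g1b, k)] += 1;
          work[cell(g2a, g2b, k)] += 1;
          if (work == to) q += p_pick * 0.25;
        }
    }
  return q;
}

// [[Rcpp::export]]
List gt_chain(IntegerMatrix genotype_counts, int steps, int burn_in) {
  int k = genotype_counts.nrow();
  if (genotype_counts.ncol() != k) stop("square table required");
  std::vector<int> tab(k * k, 0);
  int n_ind = 0;
  for (int i = 0; i < k; ++i)
    for (int j = i; j < k; ++j) {
      int n = genotype_counts(i, j) + (i == j ? 0 : genotype_counts(j, i));
      tab[cell(i, j, k)] = n;
      n_ind += n;
    }
  if (n_ind < 2) stop("need at least 2 individuals");

  const double tol = 1e-7;   // tie tolerance; also absorbs incremental drift
  double lp_obs = log_table_prob(tab, k);
  double lp_cur = lp_obs;

  // individual lookup by cumulative counts
  std::vector<int> cells;
  for (int i = 0; i < k; ++i)
    for (int j = i; j < k; ++j) cells.push_back(cell(i, j, k));

  RNGScope scope;
  long kept = 0, extreme = 0;
  int n_batch = 50;
  std::vector<double> batch_sum(n_batch, 0.0), batch_n(n_batch, 0.0);
  int recorded = steps - burn_in;

  std::vector<int> prop(tab.size());
  for (int s = 0; s < steps; ++s) {
    // sample two distinct individuals
    int u1 = (int)(unif_rand() * n_ind);
    int u2 = (int)(unif_rand() * (n_ind - 1));
    if (u2 >= u1) u2 += 1;
    // locate their cells
    int c1 = -1, c2 = -1, acc = 0;
    for (size_t ci = 0; ci < cells.size(); ++ci) {
      int nxt = acc + tab[cells[ci]];
      if (c1 < 0 && u1 < nxt) c1 = cells[ci];
      if (c2 < 0 && u2 < nxt) c2 = cells[ci];
      acc = nxt;
      if (c1 >= 0 && c2 >= 0) break;
    }
    int i1 = c1 / k, j1 = c1 % k, i2 = c2 / k, j2 = c2 % k;
    int al1[2] = { i1, j1 }, al2[2] = { i2, j2 };
    int x = unif_rand() < 0.5 ? 0 : 1;
    int y = unif_rand() < 0.5 ? 0 : 1;
    int t1 = cell(al1[1 - x], al2[y], k);
    int t2 = cell(al2[1 - y], al1[x], k);
    prop = tab;
    prop[c1] -= 1; prop[c2] -= 1;
    prop[t1] += 1;
    prop[t2] += 1;
    if (prop != tab) {
      // incremental log-probability over the (<= 4) touched cells
      int touched[4] = { c1, c2, t1, t2 };
      double delta = 0.0;
      for (int t = 0; t < 4; ++t) {
        bool seen = false;
        for (int u = 0; u < t; ++u) if (touched[u] == touched[t]) seen = true;
        if (seen) continue;
        int cidx = touched[t];
        bool diag = (cidx / k) == (cidx % k);
        int n_old = tab[cidx], n_new = prop[cidx];
        delta += lgamma((double)n_old + 1.0) - lgamma((double)n_new + 1.0);
        if (!diag) delta += (n_new - n_old) * M_LN2;
      }
      double lp_new = lp_cur + delta;
      double q_fwd = proposal_prob(tab, prop, k, n_ind);
      double q_rev = proposal_prob(prop, tab, k, n_ind);
      double log_alpha = lp_new - lp_cur + std::log(q_rev) - std::log(q_fwd);
      if (log_alpha >= 0 || std::log(unif_rand()) < log_alpha) {
        tab = prop;
        lp_cur = lp_new;
      }
    }
    if (s >= burn_in) {
      int b = (int)(( (long)(s - burn_in) * n_batch) / recorded);
      if (b >= n_batch) b = n_batch - 1;
      double ind = (lp_cur <= lp_obs + tol) ? 1.0 : 0.0;
      batch_sum[b] += ind; batch_n[b] += 1.0;
      extreme += (ind > 0.5); kept += 1;
    }
  }
  double p = (double)extreme / (double)kept;
  // batch-means standard error (guards against chain autocorrelation)
  double mean_b = 0.0; int used = 0;
  std::vector<double> bm;
  for (int b = 0; b < n_batch; ++b)
    if (batch_n[b] > 0) { bm.push_back(batch_sum[b] / batch_n[b]); ++used; }
  for (size_t i = 0; i < bm.size(); ++i) mean_b += bm[i];
  mean_b /= used;
  double v = 0.0;
  for (size_t i = 0; i < bm.size(); ++i)
    v += (bm[i] - mean_b) * (bm[i] - mean_b);
  double se = used > 1 ? std::sqrt(v / (used - 1) / used) : NA_REAL;
  return List::create(_["p_value"] = p, _["se"] = se,
                      _["steps"] = kept);
}
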