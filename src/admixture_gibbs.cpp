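#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the admixture model with (optionally) correlated
// cluster allele frequencies (F-model).  Data: diploid multiallelic
// genotypes, missing copies carry no likelihood term.
//
//   Q_i       ~ Dirichlet(alpha, ..., alpha)          (membership)
//   z_{ilc}   ~ Categorical(Q_i)                      (copy origin)
//   a_{ilc}   ~ Categorical(P_{z,l,.})                (allele)
//   P_{k,l,.} ~ Dirichlet(p_anc_{l,.} (1-F_k)/F_k)    (correlated prior)
// or P_{k,l,.} ~ Dirichlet(lambda, ..., lambda)       (independent prior)
//
// alpha gets a uniform(0,10) prior with a Metropolis random-walk update;
// each F_k gets a uniform(0,1) prior with a logit-scale random walk.

static void rdirichlet_inplace(std::vector<double>& out,
                               const double* shape, int n) {
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    double g = R::rgamma(shape[i] > 1e-8 ? shape[i] : 1e-8, 1.0);
    if (g < 1e-300) g = 1e-300;
    out[i] = g; tot += g;
  }
  for (int i = 0; i < n; ++i) out[i] /= tot;
}

// log Dirichlet(shape) density of x (both length n)
static double ldirichlet(const std::vector<double>& x,
                         const std::vector<double>& shape) {
  double lp = 0.0, s = 0.0;
  for (size_t i = 0; i < x.size(); ++i) {
    lp += (shape[i] - 1.0) * std::log(std::max(x[i], 1e-300));
    lp -= lgamma(std::max(shape[i], 1e-8));
    s += shape[i];
  }
  return lp + lgamma(s);
}

// [[Rcpp::export]]
List admixture_gibbs(IntegerMatrix geno, IntegerVector n_alleles,
                     NumericVector p_anc_flat, IntegerVector offsets,
                     int K, int burn_in, int run_length,
                     bool correlated, double lambda,
                     double alpha_init, bool sample_alpha) {
  int n = geno.nrow();
  int L = n_alleles.size();
  if (geno.ncol() != 2 * L) stop("genotype matrix must have 2 columns per locus");
  int A = 0;                        // total allele slots
  for (int l = 0; l < L; ++l) A += n_alleles[l];

  RNGScope scope;

  // state
  std::vector<int> Z(n * 2 * L, 0);
  std::vector<double> Q(n * K, 1.0 / K);
  std::vector<double> P(K * A, 0.0);
  std::vector<double> Fk(K, 0.1);
  double alpha = alpha_init;

  // init P from ancestral frequencies (or uniform)
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) {
      int off = offsets[l], na = n_alleles[l];
      std::vector<double> shape(na);
      for (int a = 0; a < na; ++a)
        shape[a] = correlated ? std::max(p_anc_flat[off + a], 1e-3) * 50.0
                              : 1.0;
      std::vector<double> draw(na);
      rdirichlet_inplace(draw, shape.data(), na);
      for (int a = 0; a < na; ++a) P[k * A + off + a] = draw[a];
    }
  // init Z randomly
  for (size_t t = 0; t < Z.size(); ++t)
    Z[t] = (int)(unif_rand() * K);

  // accumulators
  std::vector<double> Qsum(n * K, 0.0), Psum(K * A, 0.0);
  NumericVector trace(run_length);
  NumericVector alpha_trace(run_length), f_trace(run_length * K);

  std::vector<double> prob(K);
  std::vector<int> nz(n * K);            // copies per individual per cluster
  std::vector<double> ncl(K * A);        // allele counts per cluster

  int total = burn_in + run_length;
  for (int sweep = 0; sweep < total; ++sweep) {
    // --- update Z, accumulate counts
    std::fill(nz.begin(), nz.end(), 0);
    std::fill(ncl.begin(), ncl.end(), 0.0);
    for (int i = 0; i < n; ++i)
      for (int l = 0; l < L; ++l)
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a < 0) continue;
          int off = offsets[l];
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            prob[k] = Q[i * K + k] * P[k * A + off + a];
            tot += prob[k];
          }
          double u = unif_rand() * tot, cum = 0.0;
          int k = K - 1;
          for (int kk = 0; kk < K; ++kk) {
            cum += prob[kk];
            if (u <= cum) { k = kk; break; }
          }
          Z[(i * L + l) * 2 + c] = k;
          nz[i * K + k] += 1;
          ncl[k * A + off + a] += 1.0;
        }

    // --- update Q
    {
      std::vector<double> shape(K), draw(K);
      for (int i = 0; i < n; ++i) {
        for (int k = 0; k < K; ++k)
          shape[k] = alpha + nz[i * K + k];
        rdirichlet_inplace(draw, shape.data(), K);
        for (int k = 0; k < K; ++k) Q[i * K + k] = draw[k];
      }
    }

    // --- update P
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        int off = offsets[l], na = n_alleles[l];
        std::vector<double> shape(na), draw(na);
        for (int a = 0; a < na; ++a) {
          double prior = correlated
            ? std::max(p_anc_flat[off + a], 1e-6) * (1.0 - Fk[k]) / Fk[k]
            : lambda;
          shape[a] = prior + ncl[k * A + off + a];
        }
        rdirichlet_inplace(draw, shape.data(), na);
        for (int a = 0; a < na; ++a) P[k * A + off + a] = draw[a];
      }

    // --- update F_k (correlated model): logit random walk, U(0,1) prior
    if (correlated) {
      for (int k = 0; k < K; ++k) {
        double f = Fk[k];
        double logit = std::log(f / (1.0 - f)) + norm_rand() * 0.3;
        double fprop = 1.0 / (1.0 + std::exp(-logit));
        if (fprop <= 1e-4 || fprop >= 1.0 - 1e-4) continue;
        double lr = 0.0;
        for (int l = 0; l < L; ++l) {
          int off = offsets[l], na = n_alleles[l];
          std::vector<double> x(na), s_old(na), s_new(na);
          for (int a = 0; a < na; ++a) {
            x[a] = P[k * A + off + a];
            double anc = std::max(p_anc_flat[off + a], 1e-6);
            s_old[a] = anc * (1.0 - f) / f;
            s_new[a] = anc * (1.0 - fprop) / fprop;
          }
          lr += ldirichlet(x, s_new) - ldirichlet(x, s_old);
        }
        // Jacobian of the logit walk
        lr += std::log(fprop * (1.0 - fprop)) - std::log(f * (1.0 - f));
        if (lr >= 0 || std::log(unif_rand()) < lr) Fk[k] = fprop;
      }
    }

    // --- update alpha: random walk, U(0,10) prior
    if (sample_alpha && K > 1) {
      double aprop = alpha + norm_rand() * 0.05;
      if (aprop > 1e-3 && aprop < 10.0) {
        double lr = 0.0;
        lr += n * (lgamma(K * aprop) - K * lgamma(aprop)
                   - lgamma(K * alpha) + K * lgamma(alpha));
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k)
            lr += (aprop - alpha) * std::log(std::max(Q[i * K + k], 1e-300));
        if (lr >= 0 || std::log(unif_rand()) < lr) alpha = aprop;
      }
    }

    // --- record
    if (sweep >= burn_in) {
      int s = sweep - burn_in;
      double ll = 0.0;
      for (int i = 0; i < n; ++i)
        for (int l = 0; l < L; ++l)
          for (int c = 0; c < 2; ++c) {
            int a = geno(i, 2 * l + c);
            if (a < 0) continue;
            int off = offsets[l];
            double mix = 0.0;
            for (int k = 0; k < K; ++k)
              mix += Q[i * K + k] * P[k * A + off + a];
            ll += std::log(std::max(mix, 1e-300));
          }
      trace[s] = ll;
      alpha_trace[s] = alpha;
      for (int k = 0; k < K; ++k) f_trace[s * K + k] = Fk[k];
      for (size_t t = 0; t < Qsum.size(); ++t) Qsum[t] += Q[t];
      for (size_t t = 0; t < Psum.size(); ++t) Psum[t] += P[t];
    }
  }

  NumericMatrix Qmean(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k)
      Qmean(i, k) = Qsum[i * K + k] / run_length;
  NumericMatrix Pmean(K, A);
  for (int k = 0; k < K; ++k)
    for (int a = 0; a < A; ++a)
      Pmean(k, a) = Psum[k * A + a] / run_length;

  return List::create(_["Q"] = Qmean, _["P"] = Pmean,
                      _["loglik_trace"] = trace,
                      _["alpha_trace"] = alpha_trace,
                      _["f_trace"] = f_trace);
}
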