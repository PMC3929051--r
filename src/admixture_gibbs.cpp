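#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the admixture model. Each of the two allele copies of a
// diploid genotype is assigned a latent ancestral cluster z; allele
// frequencies P get a Uniform(0,1) (Beta(1,1)) prior, membership rows Q a
// symmetric Dirichlet(alpha) prior. Missing dosages (NA) are skipped both in
// the assignment step and in the likelihood. Uses R's RNG, so results are
// reproducible via set.seed() on the R side.
//
// X: n x L integer dosage matrix (copies of allele B), NA allowed.
// Returns posterior-mean Q and P over the sampling sweeps plus the per-sweep
// data log-likelihood trace evaluated at the current (post-update) state.
// [[Rcpp::export]]
List gibbs_admixture_cpp(IntegerMatrix X, int K, int n_burnin, int n_sweeps,
                         double alpha) {
  const int n = X.nrow();
  const int L = X.ncol();
  const int total = n_burnin + n_sweeps;

  NumericMatrix P(K, L);        // allele-B frequency per cluster x marker
  NumericMatrix Q(n, K);        // membership per sample
  NumericMatrix Qsum(n, K), Psum(K, L);
  NumericVector ll_trace(n_sweeps);

  // init: P ~ U(0,1), Q ~ Dirichlet(alpha)
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) P(k, l) = R::unif_rand();
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { Q(i, k) = R::rgamma(alpha, 1.0); s += Q(i, k); }
    for (int k = 0; k < K; ++k) Q(i, k) /= s;
  }

  std::vector<double> a(K * L), b(K * L);   // cluster allele counts (B / A)
  std::vector<double> c(n * K);             // per-sample cluster copy counts
  std::vector<double> w(K);

  const double lchoose2 = std::log(2.0);

  for (int sweep = 0; sweep < total; ++sweep) {
    std::fill(a.begin(), a.end(), 0.0);
    std::fill(b.begin(), b.end(), 0.0);
    std::fill(c.begin(), c.end(), 0.0);

    // (i) latent assignments for every allele copy
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        int g = X(i, l);
        if (g == NA_INTEGER) continue;
        // g copies of allele B
        for (int copy = 0; copy < 2; ++copy) {
          bool isB = copy < g;
          double ws = 0.0;
          for (int k = 0; k < K; ++k) {
            double pk = P(k, l);
            w[k] = Q(i, k) * (isB ? pk : 1.0 - pk);
            ws += w[k];
          }
          double u = R::unif_rand() * ws;
          int k = 0;
          double acc = w[0];
          while (u > acc && k < K - 1) acc += w[++k];
          if (isB) a[k * L + l] += 1.0; else b[k * L + l] += 1.0;
          c[i * K + k] += 1.0;
        }
      }
    }

    // (ii) allele frequencies from Beta posteriors
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l)
        P(k, l) = R::rbeta(1.0 + a[k * L + l], 1.0 + b[k * L + l]);

    // (iii) memberships from Dirichlet posteriors
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        Q(i, k) = R::rgamma(alpha + c[i * K + k], 1.0);
        s += Q(i, k);
      }
      for (int k = 0; k < K; ++k) Q(i, k) /= s;
    }

    if (sweep >= n_burnin) {
      // data log-likelihood at the current state: copies independent given
      // (Q, P), so genotype ~ Binomial(2, u_il) with u_il = sum_k q_ik p_kl
      double ll = 0.0;
      for (int i = 0; i < n; ++i) {
        for (int l = 0; l < L; ++l) {
          int g = X(i, l);
          if (g == NA_INTEGER) continue;
          double u = 0.0;
          for (int k = 0; k < K; ++k) u += Q(i, k) * P(k, l);
          if (u < 1e-300) u = 1e-300;
          if (u > 1.0 - 1e-12) u = 1.0 - 1e-12;
          if (g == 0) ll += 2.0 * std::log(1.0 - u);
          else if (g == 2) ll += 2.0 * std::log(u);
          else ll += lchoose2 + std::log(u) + std::log(1.0 - u);
        }
      }
      int s_idx = sweep - n_burnin;
      ll_trace[s_idx] = ll;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l) Psum(k, l) += P(k, l);
    }
  }

  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= n_sweeps;
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) Psum(k, l) /= n_sweeps;

  return List::create(_["Q"] = Qsum, _["P"] = Psum, _["ll_trace"] = ll_trace);
}
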