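#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA over a tokenized corpus.
// words, docs: 0-based token streams; uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector words, IntegerVector docs,
                   int D, int V, int K, double alpha, double beta,
                   int n_iter, int burn_in) {
  const int N = words.size();
  std::vector<int> z(N);
  std::vector<int> nkv((size_t)K * V, 0);  // topic-word counts
  std::vector<int> ndk((size_t)D * K, 0);  // doc-topic counts
  std::vector<int> nk(K, 0);               // topic totals
  std::vector<int> nd(D, 0);               // doc lengths

  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[i] = k;
    nkv[(size_t)k * V + words[i]]++;
    ndk[(size_t)docs[i] * K + k]++;
    nk[k]++;
    nd[docs[i]]++;
  }

  const double Vbeta = V * beta;
  std::vector<double> p(K);
  NumericMatrix phi_sum(K, V), theta_sum(D, K);
  std::vector<double> loglik_kept;
  NumericVector loglik_trace(n_iter);
  int n_kept = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int i = 0; i < N; ++i) {
      const int w = words[i], d = docs[i];
      int k = z[i];
      nkv[(size_t)k * V + w]--;
      ndk[(size_t)d * K + k]--;
      nk[k]--;
      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        tot += (nkv[(size_t)j * V + w] + beta) / (nk[j] + Vbeta) *
               (ndk[(size_t)d * K + j] + alpha);
        p[j] = tot;
      }
      double u = unif_rand() * tot;
      int knew = 0;
      while (knew < K - 1 && p[knew] < u) ++knew;
      z[i] = knew;
      nkv[(size_t)knew * V + w]++;
      ndk[(size_t)d * K + knew]++;
      nk[knew]++;
    }
    // log p(w | z): Dirichlet-multinomial integrated over phi
    double ll = K * (R::lgammafn(Vbeta) - V * R::lgammafn(beta));
    for (int k = 0; k < K; ++k) {
      for (int v = 0; v < V; ++v)
        ll += R::lgammafn(nkv[(size_t)k * V + v] + beta);
      ll -= R::lgammafn(nk[k] + Vbeta);
    }
    loglik_trace[iter] = ll;
    if (iter >= burn_in) {
      loglik_kept.push_back(ll);
      for (int k = 0; k < K; ++k)
        for (int v = 0; v < V; ++v)
          phi_sum(k, v) += (nkv[(size_t)k * V + v] + beta) / (nk[k] + Vbeta);
      for (int d = 0; d < D; ++d)
        for (int k = 0; k < K; ++k)
          theta_sum(d, k) += (ndk[(size_t)d * K + k] + alpha) /
                             (nd[d] + K * alpha);
      ++n_kept;
    }
  }

  NumericMatrix phi(K, V), theta(D, K);
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v) phi(k, v) = phi_sum(k, v) / n_kept;
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) theta(d, k) = theta_sum(d, k) / n_kept;
  // renormalize posterior means so rows sum to exactly 1
  for (int k = 0; k < K; ++k) {
    double s = 0; for (int v = 0; v < V; ++v) s += phi(k, v);
    for (int v = 0; v < V; ++v) phi(k, v) /= s;
  }
  for (int d = 0; d < D; ++d) {
    double s = 0; for (int k = 0; k < K; ++k) s += theta(d, k);
    for (int k = 0; k < K; ++k) theta(d, k) /= s;
  }

  IntegerVector zr(z.begin(), z.end());
  return List::create(_["phi"] = phi, _["theta"] = theta,
                      _["assignments"] = zr + 1,
                      _["loglik"] = NumericVector(loglik_kept.begin(), loglik_kept.end()),
                      _["loglik_trace"] = loglik_trace);
}
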