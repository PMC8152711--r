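// Collapsed Gibbs sampler for latent Dirichlet allocation.
// Token stream comes in as parallel 0-based doc/word index vectors.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::mat lda_gibbs_cpp(const arma::ivec& doc_id, const arma::ivec& word_id,
                        int n_docs, int n_words, int n_topics,
                        double alpha, double beta, int n_iter,
                        int seed) {
  const int n_tok = doc_id.n_elem;
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  arma::imat ndk(n_docs, n_topics, arma::fill::zeros);   // doc-topic
  arma::imat nkw(n_topics, n_words, arma::fill::zeros);  // topic-word
  arma::ivec nk(n_topics, arma::fill::zeros);            // topic totals
  arma::ivec nd(n_docs, arma::fill::zeros);              // doc lengths
  arma::ivec z(n_tok);

  for (int t = 0; t < n_tok; ++t) {
    int k = static_cast<int>(unif(rng) * n_topics);
    if (k >= n_topics) k = n_topics - 1;
    z[t] = k;
    ndk(doc_id[t], k) += 1;
    nkw(k, word_id[t]) += 1;
    nk[k] += 1;
    nd[doc_id[t]] += 1;
  }

  std::vector<double> p(n_topics);
  const double vbeta = n_words * beta;

  auto sweep = [&]() {
    for (int t = 0; t < n_tok; ++t) {
      const int d = doc_id[t], w = word_id[t], old = z[t];
      ndk(d, old) -= 1; nkw(old, w) -= 1; nk[old] -= 1;
      double tot = 0.0;
      for (int k = 0; k < n_topics; ++k) {
        tot += (ndk(d, k) + alpha) * (nkw(k, w) + beta) / (nk[k] + vbeta);
        p[k] = tot;
      }
      const double u = unif(rng) * tot;
      int k = 0;
      while (k < n_topics - 1 && p[k] < u) ++k;
      z[t] = k;
      ndk(d, k) += 1; nkw(k, w) += 1; nk[k] += 1;
    }
  };
  // per-token predictive log-likelihood under the current counts; used
  // only for the convergence test
  auto loglik = [&]() {
    double ll = 0.0;
    for (int t = 0; t < n_tok; ++t) {
      const int d = doc_id[t], w = word_id[t];
      double s = 0.0;
      for (int k = 0; k < n_topics; ++k)
        s += (ndk(d, k) + alpha) * (nkw(k, w) + beta) / (nk[k] + vbeta);
      ll += std::log(s / (nd[d] + n_topics * alpha));
    }
    return ll / n_tok;
  };

  // burn-in: up to n_iter sweeps, stopping early once the per-token
  // log-likelihood changes by < 1e-4 between successive checks
  const int check_every = 20, min_burn = std::min(100, n_iter);
  const int max_burn = std::max(1, n_iter - n_iter / 4);
  double last_ll = -arma::datum::inf;
  for (int it = 0; it < max_burn; ++it) {
    sweep();
    if (it + 1 >= min_burn && (it + 1) % check_every == 0) {
      double ll = loglik();
      if (std::fabs(ll - last_ll) < 1e-4) break;
      last_ll = ll;
    }
  }
  // averaging phase: accumulate doc-topic counts over n_iter/4 sweeps
  arma::mat acc(n_docs, n_topics, arma::fill::zeros);
  const int n_avg_target = std::max(1, n_iter / 4);
  int n_avg = 0;
  for (int it = 0; it < n_avg_target; ++it) {
    sweep();
    for (int d = 0; d < n_docs; ++d)
      for (int k = 0; k < n_topics; ++k)
        acc(d, k) += ndk(d, k);
    ++n_avg;
  }

  arma::mat theta(n_docs, n_topics);
  for (int d = 0; d < n_docs; ++d) {
    const double denom = nd[d] + n_topics * alpha;
    for (int k = 0; k < n_topics; ++k)
      theta(d, k) = (acc(d, k) / std::max(1, n_avg) + alpha) / denom;
  }
  // exact simplex normalisation (guards the averaging arithmetic)
  for (int d = 0; d < n_docs; ++d) theta.row(d) /= arma::accu(theta.row(d));
  return theta;
}
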