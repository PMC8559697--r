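// EM training loop for the mixture of multinomial mixture models.
// The catalog is passed as sparse triplets (0-based sample index, 0-based
// category index, count); panel catalogs have a handful of non-zero
// categories per sample, so all O(nnz * L) work stays proportional to the
// number of observed (sample, category) pairs.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double PROB_FLOOR = 1e-300;

// [[Rcpp::export(name = "mix_em_cpp")]]
List mix_em_cpp(IntegerVector ti, IntegerVector tj, NumericVector tx,
                int N, int M,
                NumericVector w0, NumericMatrix pi0, NumericMatrix e0,
                bool refit, int max_iterations,
                double tol_abs, double tol_rel) {
  const int L = w0.size();
  const int K = e0.nrow();
  const int nnz = ti.size();

  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> pi(L * K);   // pi[l*K + i]
  std::vector<double> e(K * M);    // e[i*M + j]
  for (int l = 0; l < L; ++l)
    for (int i = 0; i < K; ++i) pi[l * K + i] = pi0(l, i);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < M; ++j) e[i * M + j] = e0(i, j);

  std::vector<double> lq(L * M), q(L * M);
  std::vector<double> ll(N * L), f(N * L);
  std::vector<double> G(L * M), E(K * M), A(L * K), W(L);
  std::vector<double> trace;
  trace.reserve(64);

  int n_guard = 0, iterations = 0;
  bool converged = false;
  double prev = 0.0;

  for (int it = 0; ; ++it) {
    // per-cluster category mixture probabilities
    for (int l = 0; l < L; ++l) {
      for (int j = 0; j < M; ++j) {
        double s = 0.0;
        for (int i = 0; i < K; ++i) s += pi[l * K + i] * e[i * M + j];
        double qs = s > PROB_FLOOR ? s : PROB_FLOOR;
        q[l * M + j] = qs;
        lq[l * M + j] = std::log(qs);
      }
    }
    // per-sample per-cluster log-likelihoods (log w + sum of count * log q)
    std::vector<double> lw(L);
    for (int l = 0; l < L; ++l)
      lw[l] = w[l] > 0 ? std::log(w[l]) : -INFINITY;
    for (int n = 0; n < N; ++n)
      for (int l = 0; l < L; ++l) ll[n * L + l] = lw[l];
    for (int t = 0; t < nnz; ++t) {
      const int n = ti[t], j = tj[t];
      const double x = tx[t];
      for (int l = 0; l < L; ++l) ll[n * L + l] += x * lq[l * M + j];
    }
    // responsibilities via log-sum-exp; total log-likelihood
    double loglik = 0.0;
    for (int n = 0; n < N; ++n) {
      double m = -INFINITY;
      for (int l = 0; l < L; ++l)
        if (ll[n * L + l] > m) m = ll[n * L + l];
      double s = 0.0;
      for (int l = 0; l < L; ++l) {
        // terms below exp(-50) ~ 2e-22 cannot move the sum at double
        // precision; skipping them also avoids subnormal slow paths
        const double d = ll[n * L + l] - m;
        const double u = d < -50.0 ? 0.0 : std::exp(d);
        f[n * L + l] = u;
        s += u;
      }
      for (int l = 0; l < L; ++l) f[n * L + l] /= s;
      loglik += m + std::log(s);
    }
    trace.push_back(loglik);

    if (it > 0) {
      const double gain = loglik - prev;
      if (gain < tol_abs || gain < tol_rel * std::fabs(prev)) {
        converged = true;
        break;
      }
    }
    if (it >= max_iterations) break;
    prev = loglik;

    // pooled sufficient statistics
    std::fill(G.begin(), G.end(), 0.0);
    std::fill(W.begin(), W.end(), 0.0);
    for (int n = 0; n < N; ++n)
      for (int l = 0; l < L; ++l) W[l] += f[n * L + l];
    for (int t = 0; t < nnz; ++t) {
      const int n = ti[t], j = tj[t];
      const double x = tx[t];
      for (int l = 0; l < L; ++l) G[l * M + j] += f[n * L + l] * x;
    }
    for (int l = 0; l < L; ++l)
      for (int j = 0; j < M; ++j) G[l * M + j] /= q[l * M + j];
    // E[i,j] = e[i,j] * sum_l pi[l,i] G[l,j];  A[l,i] = pi[l,i] * sum_j e[i,j] G[l,j]
    for (int i = 0; i < K; ++i) {
      for (int j = 0; j < M; ++j) {
        double s = 0.0;
        for (int l = 0; l < L; ++l) s += pi[l * K + i] * G[l * M + j];
        E[i * M + j] = e[i * M + j] * s;
      }
    }
    for (int l = 0; l < L; ++l) {
      for (int i = 0; i < K; ++i) {
        double s = 0.0;
        for (int j = 0; j < M; ++j) s += e[i * M + j] * G[l * M + j];
        A[l * K + i] = pi[l * K + i] * s;
      }
    }

    // M-step with zero-expectation guard (keep previous row)
    double wsum = 0.0;
    for (int l = 0; l < L; ++l) wsum += W[l];
    for (int l = 0; l < L; ++l) w[l] = W[l] / wsum;
    for (int l = 0; l < L; ++l) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += A[l * K + i];
      if (s > 0) {
        for (int i = 0; i < K; ++i) pi[l * K + i] = A[l * K + i] / s;
      } else {
        ++n_guard;
      }
    }
    if (!refit) {
      for (int i = 0; i < K; ++i) {
        double s = 0.0;
        for (int j = 0; j < M; ++j) s += E[i * M + j];
        if (s > 0) {
          for (int j = 0; j < M; ++j) e[i * M + j] = E[i * M + j] / s;
        } else {
          ++n_guard;
        }
      }
    }
    ++iterations;
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pi_out(L, K), e_out(K, M);
  for (int l = 0; l < L; ++l)
    for (int i = 0; i < K; ++i) pi_out(l, i) = pi[l * K + i];
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < M; ++j) e_out(i, j) = e[i * M + j];

  return List::create(
    _["w"] = NumericVector(w.begin(), w.end()),
    _["pi"] = pi_out,
    _["e"] = e_out,
    _["loglik"] = trace.back(),
    _["trace"] = NumericVector(trace.begin(), trace.end()),
    _["iterations"] = iterations,
    _["converged"] = converged,
    _["n_guard"] = n_guard);
}
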