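#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler (and ICM variant) for LDA.
//
// docs: list of integer vectors, 0-based word indices into a vocabulary of
// size V. Returns final assignments, count tables, and (optionally) the
// per-token topic assignment frequencies accumulated over all sweeps after
// `burnin` sweeps, which the toy-corpus enumeration oracle checks against.
//
// Randomness comes from R's RNG (RNGScope), so results are reproducible via
// set.seed() on the R side.
// [[Rcpp::export(name = ".gibbs_lda")]]
List gibbs_lda(List docs, int V, int K, double alpha, double beta,
               int iterations, bool icm = false, bool track = false,
               int burnin = 0) {
  RNGScope scope;
  const int D = docs.size();
  std::vector<std::vector<int>> w(D);
  int N = 0;
  for (int d = 0; d < D; ++d) {
    IntegerVector wd = docs[d];
    w[d].assign(wd.begin(), wd.end());
    N += wd.size();
  }
  if (N == 0) stop("empty corpus");
  if (K < 1) stop("K must be >= 1");
  if (K > N) stop("K exceeds the total number of tokens");

  IntegerMatrix n_dt(D, K);
  IntegerMatrix n_wt(V, K);
  IntegerVector n_t(K);
  std::vector<std::vector<int>> z(D);

  // random initialization
  for (int d = 0; d < D; ++d) {
    z[d].resize(w[d].size());
    for (size_t i = 0; i < w[d].size(); ++i) {
      int t = (int)std::floor(unif_rand() * K);
      if (t == K) t = K - 1;
      z[d][i] = t;
      n_dt(d, t)++;
      n_wt(w[d][i], t)++;
      n_t[t]++;
    }
  }

  // Tracking (for oracle comparisons on toy corpora): per-token topic
  // frequencies, and pairwise co-assignment frequencies P(z_i == z_j),
  // which are invariant under topic relabelling.
  NumericMatrix freq;
  NumericMatrix pairco;
  std::vector<long long> freq_acc;
  std::vector<long long> pair_acc;
  if (track) {
    freq_acc.assign((size_t)N * K, 0LL);
    pair_acc.assign((size_t)N * N, 0LL);
  }

  std::vector<double> p(K);
  const double Vbeta = V * beta;
  int kept_sweeps = 0;

  for (int it = 0; it < iterations; ++it) {
    for (int d = 0; d < D; ++d) {
      const std::vector<int>& wd = w[d];
      for (size_t i = 0; i < wd.size(); ++i) {
        const int wi = wd[i];
        const int old = z[d][i];
        n_dt(d, old)--; n_wt(wi, old)--; n_t[old]--;
        int tnew;
        if (icm) {
          double best = -1.0; tnew = 0;
          for (int t = 0; t < K; ++t) {
            double val = (n_dt(d, t) + alpha) * (n_wt(wi, t) + beta) /
                         (n_t[t] + Vbeta);
            if (val > best) { best = val; tnew = t; }
          }
        } else {
          double tot = 0.0;
          for (int t = 0; t < K; ++t) {
            p[t] = (n_dt(d, t) + alpha) * (n_wt(wi, t) + beta) /
                   (n_t[t] + Vbeta);
            tot += p[t];
          }
          double u = unif_rand() * tot;
          double cum = 0.0; tnew = K - 1;
          for (int t = 0; t < K; ++t) {
            cum += p[t];
            if (u <= cum) { tnew = t; break; }
          }
        }
        z[d][i] = tnew;
        n_dt(d, tnew)++; n_wt(wi, tnew)++; n_t[tnew]++;
      }
    }
    if (track && it >= burnin) {
      ++kept_sweeps;
      std::vector<int> zflat;
      zflat.reserve(N);
      for (int d = 0; d < D; ++d)
        for (size_t i = 0; i < w[d].size(); ++i)
          zflat.push_back(z[d][i]);
      for (int a = 0; a < N; ++a) {
        freq_acc[(size_t)a * K + zflat[a]]++;
        for (int b = a + 1; b < N; ++b)
          if (zflat[a] == zflat[b]) pair_acc[(size_t)a * N + b]++;
      }
    }
    if ((it & 63) == 0) Rcpp::checkUserInterrupt();
  }

  List zout(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector zd(z[d].begin(), z[d].end());
    zout[d] = zd + 1; // 1-based topics for R
  }

  if (track) {
    const double denom = std::max(1, kept_sweeps);
    freq = NumericMatrix(N, K);
    pairco = NumericMatrix(N, N);
    for (int a = 0; a < N; ++a) {
      for (int t = 0; t < K; ++t)
        freq(a, t) = (double)freq_acc[(size_t)a * K + t] / denom;
      pairco(a, a) = 1.0;
      for (int b = a + 1; b < N; ++b) {
        double v = (double)pair_acc[(size_t)a * N + b] / denom;
        pairco(a, b) = v;
        pairco(b, a) = v;
      }
    }
  }

  return List::create(_["z"] = zout, _["n_dt"] = n_dt, _["n_wt"] = n_wt,
                      _["n_t"] = n_t,
                      _["assign_freq"] = track ? (SEXP)freq : R_NilValue,
                      _["pair_freq"] = track ? (SEXP)pairco : R_NilValue);
}
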