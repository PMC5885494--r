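#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo null for the gene-set overlap statistic.
//
// Each permutation draws n indices uniformly without replacement from
// {0, ..., N-1} and counts how many fall below K. By symmetry of uniform
// sampling this is the overlap between a random n-set and a fixed K-set,
// so only (N, K, n) matter, not gene identities. Uses a partial
// Fisher-Yates shuffle whose swaps are undone after each draw, keeping the
// per-permutation cost O(n) instead of O(N).
//
// Driven by R's RNG (unif_rand), so set.seed() in R fully determines the
// output stream.
// [[Rcpp::export]]
IntegerVector perm_overlap_counts(int N, int K, int n, int n_perm) {
  if (N < 1 || K < 0 || K > N || n < 0 || n > N || n_perm < 1)
    stop("invalid permutation parameters");
  std::vector<int> pool(N);
  for (int i = 0; i < N; ++i) pool[i] = i;
  std::vector<int> swapped_from(n), swapped_to(n);
  IntegerVector counts(n_perm);
  RNGScope scope;
  for (int p = 0; p < n_perm; ++p) {
    int hits = 0;
    for (int i = 0; i < n; ++i) {
      int m = N - i;
      int j = (int)(unif_rand() * m);
      if (j >= m) j = m - 1;  // guard against unif_rand() == 1.0
      j += i;
      std::swap(pool[i], pool[j]);
      swapped_from[i] = i;
      swapped_to[i] = j;
      if (pool[i] < K) ++hits;
    }
    // undo swaps in reverse so the pool is pristine for the next draw
    for (int i = n - 1; i >= 0; --i)
      std::swap(pool[swapped_from[i]], pool[swapped_to[i]]);
    counts[p] = hits;
  }
  return counts;
}
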