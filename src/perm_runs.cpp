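#include <Rcpp.h>
using namespace Rcpp;

// Longest run of 1s in a 0/1 vector.
static int max_run(const IntegerVector& x) {
  int best = 0, cur = 0;
  for (int i = 0; i < x.size(); ++i) {
    if (x[i] == 1) {
      if (++cur > best) best = cur;
    } else {
      cur = 0;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".max_run_int")]]
int max_run_int(IntegerVector x) { return max_run(x); }

// Null distribution of the maximal 1-run under label permutation.
// Only the number of sites (n) and the number of 1s (k) matter: positions
// are exchangeable, so we shuffle a fixed vector of k ones among n slots.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".perm_max_run_null")]]
IntegerVector perm_max_run_null(int n, int k, int n_perm) {
  IntegerVector x(n);
  for (int i = 0; i < k; ++i) x[i] = 1;
  IntegerVector out(n_perm);
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates shuffle via unif_rand (respects set.seed in R)
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      int tmp = x[i]; x[i] = x[j]; x[j] = tmp;
    }
    out[b] = max_run(x);
  }
  return out;
}
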