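#include <Rcpp.h>
using namespace Rcpp;

// Literal urn birth process: k clones start at size 1 and the population is
// grown one cell at a time to n_final, each new cell copying the clone of a
// uniformly chosen existing cell (selection probability proportional to
// current clone size). Returns the final clone sizes.
// [[Rcpp::export]]
IntegerVector urn_grow_cpp(int k, double n_final) {
  if (k < 1) stop("k must be >= 1");
  int n = (int) n_final;
  if (k > n) stop("k must not exceed n_final");
  std::vector<int> color(n);
  for (int i = 0; i < k; ++i) color[i] = i;
  GetRNGstate();
  for (int t = k; t < n; ++t) {
    int j = (int) (unif_rand() * t);
    if (j >= t) j = t - 1;
    color[t] = color[j];
  }
  PutRNGstate();
  IntegerVector sizes(k);
  for (int t = 0; t < n; ++t) sizes[color[t]]++;
  return sizes;
}
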