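#include <Rcpp.h>
using namespace Rcpp;

// Multivariate hypergeometric draw: sample k copies without replacement from a
// pool partitioned into clones with the given copy counts. Sequential
// conditional hypergeometric; uses R's RNG so draws are reproducible under
// set.seed(). counts must be non-negative and sum(counts) >= k.
// [[Rcpp::export(name = ".rmvhyper_cpp")]]
IntegerVector rmvhyper_cpp(IntegerVector counts, double k) {
  int S = counts.size();
  IntegerVector out(S);
  long double total = 0;
  for (int i = 0; i < S; ++i) {
    if (counts[i] < 0) stop("negative clone count");
    total += counts[i];
  }
  if (k < 0 || k > (double)total) stop("draw size outside [0, total copies]");
  double rest = (double)total;
  double m = k;
  for (int i = 0; i < S && m > 0; ++i) {
    rest -= counts[i];
    double d = ::Rf_rhyper((double)counts[i], rest, m);
    out[i] = (int)d;
    m -= d;
  }
  return out;
}
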