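#include <Rcpp.h>
using namespace Rcpp;

// Peak-to-trough amplitudes of "random" SSVEPs: for each repeat, permute the
// sample order independently within every segment (fresh Fisher-Yates draws
// from R's RNG), average across segments, and take max - min of the average.
// [[Rcpp::export]]
NumericVector shuffle_null_amps_cpp(NumericMatrix segs, int n_repeats) {
  const int n = segs.nrow(), L = segs.ncol();
  NumericVector amps(n_repeats);
  std::vector<double> buf(L), acc(L);
  for (int r = 0; r < n_repeats; ++r) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < L; ++j) buf[j] = segs(i, j);
      for (int j = L - 1; j > 0; --j) {
        int k = (int)(unif_rand() * (j + 1));
        if (k > j) k = j;
        std::swap(buf[j], buf[k]);
      }
      for (int j = 0; j < L; ++j) acc[j] += buf[j];
    }
    double mx = acc[0], mn = acc[0];
    for (int j = 1; j < L; ++j) {
      if (acc[j] > mx) mx = acc[j];
      if (acc[j] < mn) mn = acc[j];
    }
    amps[r] = (mx - mn) / n;
  }
  return amps;
}
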