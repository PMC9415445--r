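#include <Rcpp.h>
using namespace Rcpp;

// All-pairs REO stability scan. For every row pair i < j counts samples with
// x[i,s] > x[j,s] and x[i,s] < x[j,s] (ties count as neither but stay in the
// denominator) and emits the pair when the majority direction's support
// max(gt, lt) / S meets the threshold (>= when inclusive, > when strict).
// The pair space is streamed in row blocks so no more than one block of the
// G x G space is ever held; output is bit-identical to the naive triple loop.
// [[Rcpp::export(name = ".count_stable_pairs")]]
List count_stable_pairs(NumericMatrix x, double threshold, bool inclusive,
                        int block_size) {
  const int G = x.nrow(), S = x.ncol();
  if (block_size < 1) block_size = 1;
  std::vector<int> out_i, out_j, out_gt, out_lt;

  for (int ib = 0; ib < G; ib += block_size) {
    const int iend = std::min(G, ib + block_size);
    for (int i = ib; i < iend; ++i) {
      for (int j = i + 1; j < G; ++j) {
        int gt = 0, lt = 0;
        for (int s = 0; s < S; ++s) {
          const double a = x(i, s), b = x(j, s);
          if (a > b) ++gt;
          else if (a < b) ++lt;
        }
        const int mx = gt > lt ? gt : lt;
        const double support = (double)mx / S;
        const bool keep = inclusive ? (support >= threshold)
                                    : (support > threshold);
        if (keep && gt != lt) {
          out_i.push_back(i + 1);
          out_j.push_back(j + 1);
          out_gt.push_back(gt);
          out_lt.push_back(lt);
        }
      }
      if ((i & 127) == 0) Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["i"] = out_i, _["j"] = out_j,
                      _["n_gt"] = out_gt, _["n_lt"] = out_lt);
}
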