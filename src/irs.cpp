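#include <Rcpp.h>
using namespace Rcpp;

// Longest pair (u, v) with u in the upstream window and v in the downstream
// window such that u matches the reverse complement of v with at most
// max_mismatch mismatches. The caller passes the downstream window already
// reverse-complemented, so this reduces to the longest common prefix-run
// (allowing <= max_mismatch mismatches) over all offset pairs.
// Bases are 0..3; negative codes (ambiguity) never match.
// Ties: longer first, then smallest upstream offset, then smallest
// downstream offset.

// [[Rcpp::export]]
List longest_ir_match_cpp(IntegerVector up, IntegerVector down_rc,
                          int min_len, int max_mismatch) {
  int nu = up.size(), nd = down_rc.size();
  int best_len = 0, best_i = -1, best_j = -1, best_mm = 0;
  for (int i = 0; i < nu; ++i) {
    for (int j = 0; j < nd; ++j) {
      int mm = 0;
      int lim = std::min(nu - i, nd - j);
      for (int t = 0; t < lim; ++t) {
        int a = up[i + t], b = down_rc[j + t];
        if (a < 0 || b < 0 || a != b) {
          if (++mm > max_mismatch) break;
          continue; // runs must end on a match
        }
        int len = t + 1;
        if (len > best_len) {
          best_len = len;
          best_i = i;
          best_j = j;
          best_mm = mm;
        }
      }
    }
  }
  if (best_len < min_len)
    return List::create(_["found"] = false);
  return List::create(_["found"] = true, _["len"] = best_len,
                      _["up_off"] = best_i + 1, _["down_rc_off"] = best_j + 1,
                      _["mismatches"] = best_mm);
}
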