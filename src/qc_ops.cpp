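// Per-read trimming and quality statistics for the QC cascade.
//
// Adapter removal follows the 3'-anchored convention: the longest overlap
// between a read suffix and the adapter prefix, at least `min_overlap` long
// and with at most floor(max_mm_frac * overlap) mismatches, is cut.  Quality
// tail-cutting then removes the maximal 3' suffix whose Phred values are all
// <= q_cutoff.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List qc_trim_stats(CharacterVector seqs, CharacterVector quals,
                   std::string adapter, int min_overlap,
                   double max_mm_frac, int q_cutoff, int phred_offset) {
  const int n = seqs.size();
  if (quals.size() != n) stop("seqs and quals lengths differ");
  IntegerVector trim_len(n);
  NumericVector mean_q(n);
  const int alen = (int)adapter.size();
  for (int r = 0; r < n; ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    const char* q = CHAR(STRING_ELT(quals, r));
    int len = (int)LENGTH(STRING_ELT(seqs, r));
    if ((int)LENGTH(STRING_ELT(quals, r)) != len)
      stop("sequence/quality length mismatch at read %d", r + 1);
    int keep = len;
    // adapter: longest valid 3'-anchored overlap
    if (alen >= 1 && min_overlap >= 1) {
      int lmax = std::min(len, alen);
      for (int l = lmax; l >= min_overlap; --l) {
        int allowed = (int)std::floor(max_mm_frac * l);
        int mm = 0;
        const char* suf = s + (len - l);
        for (int i = 0; i < l; ++i) {
          if (suf[i] != adapter[i] && ++mm > allowed) break;
        }
        if (mm <= allowed) { keep = len - l; break; }
      }
    }
    // quality tail: strip maximal all-<=cutoff suffix
    while (keep > 0 && (q[keep - 1] - phred_offset) <= q_cutoff) --keep;
    trim_len[r] = keep;
    double sum = 0.0;
    for (int i = 0; i < keep; ++i) sum += (double)(q[i] - phred_offset);
    mean_q[r] = keep > 0 ? sum / keep : 0.0;
  }
  return List::create(_["trim_len"] = trim_len, _["mean_q"] = mean_q);
}
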