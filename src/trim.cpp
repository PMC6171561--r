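#include <Rcpp.h>
using namespace Rcpp;

// 3' adapter trimming: leftmost position where either the full adapter
// matches with <= 1 mismatch, or an adapter prefix of length >= minOverlap
// matches exactly through to the read end. Reads shorter than minLength
// after trimming become NA.

// [[Rcpp::export(name = ".trim_adapter_cpp")]]
CharacterVector trim_adapter_cpp(CharacterVector seqs, std::string adapter,
                                 int minOverlap, int minLength) {
  const int aLen = adapter.size();
  CharacterVector out(seqs.size());
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    if (seqs[r] == NA_STRING) { out[r] = NA_STRING; continue; }
    std::string sq = as<std::string>(seqs[r]);
    const int n = sq.size();
    int cut = n;
    for (int s = 0; s < n; ++s) {
      int rem = n - s;
      if (rem >= aLen) {
        int mm = 0;
        for (int i = 0; i < aLen && mm <= 1; ++i)
          if (sq[s + i] != adapter[i]) ++mm;
        if (mm <= 1) { cut = s; break; }
      } else if (rem >= minOverlap) {
        if (sq.compare(s, rem, adapter, 0, rem) == 0) { cut = s; break; }
      } else break;
    }
    if (cut < minLength) out[r] = NA_STRING;
    else out[r] = sq.substr(0, cut);
  }
  return out;
}
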