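#include <Rcpp.h>
using namespace Rcpp;

// Best exact-to-k-mismatch occurrence of a query in one reference strand.
// Byte-level scan over every offset; ties go to the smallest offset. Returns
// integer(0) when no offset qualifies, else c(offset0, mismatches).
// [[Rcpp::export(name = ".cpp_best_offset")]]
IntegerVector cpp_best_offset(RawVector query, RawVector ref, int k) {
  const int L = query.size();
  const int n_off = ref.size() - L + 1;
  int best_off = -1;
  int best_mm = k + 1;
  for (int o = 0; o < n_off; ++o) {
    int mm = 0;
    for (int i = 0; i < L; ++i) {
      if (ref[o + i] != query[i] && ++mm >= best_mm) break;
    }
    if (mm < best_mm) {
      best_mm = mm;
      best_off = o;
      if (best_mm == 0) break;
    }
  }
  if (best_off < 0) return IntegerVector(0);
  return IntegerVector::create(best_off, best_mm);
}

// 3' adapter trim point under cutadapt-style semantics: leftmost position p
// (1-based; 0 = no occurrence) where the adapter, or the prefix of it that
// fits before the read ends, matches read[p..] with at most
// floor(error_rate * overlap) mismatches and overlap >= min_overlap.
// [[Rcpp::export(name = ".cpp_trim_point")]]
int cpp_trim_point(RawVector read, RawVector adapter, double error_rate,
                   int min_overlap) {
  const int L = read.size();
  const int alen = adapter.size();
  for (int p = 0; p < L; ++p) {
    const int ov = std::min(alen, L - p);
    if (ov < min_overlap) break;
    const int allowed = (int)std::floor(error_rate * ov);
    int mm = 0;
    bool ok = true;
    for (int i = 0; i < ov; ++i) {
      if (read[p + i] != adapter[i] && ++mm > allowed) { ok = false; break; }
    }
    if (ok) return p + 1;
  }
  return 0;
}
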