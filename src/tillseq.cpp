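#include <Rcpp.h>
using namespace Rcpp;

// Per-base substitution errors drawn with R's RNG so results are governed by
// set.seed(). Each base is flipped with probability `rate` to one of the
// other three bases, uniformly.
// [[Rcpp::export]]
CharacterVector cpp_inject_errors(CharacterVector seqs, double rate) {
  if (rate <= 0.0) return clone(seqs);
  const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  RNGScope scope;
  std::string buf;
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    buf.assign(s);
    for (size_t j = 0; j < buf.size(); ++j) {
      if (unif_rand() < rate) {
        char cur = buf[j];
        // pick one of the 3 other bases
        int k = (int)(unif_rand() * 3.0);
        if (k > 2) k = 2;
        int idx = 0;
        for (int b = 0; b < 4; ++b) {
          if (bases[b] == cur) continue;
          if (idx == k) { buf[j] = bases[b]; break; }
          ++idx;
        }
        // non-ACGT input base: leave untouched
      }
    }
    out[i] = buf;
  }
  return out;
}

// Hamming distance of each read against a reference window starting at
// `offsets` (0-based). Reads are assumed to lie fully within the reference;
// positions running past the end are counted as mismatches.
// [[Rcpp::export]]
IntegerVector cpp_mismatch(CharacterVector seqs, IntegerVector offsets,
                           std::string ref) {
  int n = seqs.size();
  int L = ref.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int off = offsets[i];
    if (off == NA_INTEGER || off < 0) { out[i] = NA_INTEGER; continue; }
    const char *s = CHAR(STRING_ELT(seqs, i));
    int len = LENGTH(STRING_ELT(seqs, i));
    int mm = 0;
    for (int j = 0; j < len; ++j) {
      int p = off + j;
      if (p >= L || s[j] != ref[p]) ++mm;
    }
    out[i] = mm;
  }
  return out;
}

// Accumulate per-position base counts (rows A,C,G,T) for reads placed at
// 0-based `offsets` on a reference of length L. Non-ACGT read bases are
// skipped (they contribute to neither counts nor depth).
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(CharacterVector seqs, IntegerVector offsets, int L) {
  IntegerMatrix out(4, L);
  int n = seqs.size();
  for (int i = 0; i < n; ++i) {
    int off = offsets[i];
    if (off == NA_INTEGER || off < 0) continue;
    const char *s = CHAR(STRING_ELT(seqs, i));
    int len = LENGTH(STRING_ELT(seqs, i));
    for (int j = 0; j < len; ++j) {
      int p = off + j;
      if (p < 0 || p >= L) continue;
      switch (s[j]) {
      case 'A': out(0, p)++; break;
      case 'C': out(1, p)++; break;
      case 'G': out(2, p)++; break;
      case 'T': out(3, p)++; break;
      default: break;
      }
    }
  }
  return out;
}
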