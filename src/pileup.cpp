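#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Strand-resolved per-cell allele counting over mitochondrial reads.
// A read contributes iff mapq >= min_mapq and nm <= max_mismatches; every
// base additionally requires base quality >= min_base_quality. Reads
// overhanging the mito end are clipped (no origin wrap-around).
// [[Rcpp::export(name = ".pileup_counts")]]
List pileup_counts(IntegerVector cell, IntegerVector pos,
                   LogicalVector is_plus, IntegerVector mapq,
                   IntegerVector nm, CharacterVector seq,
                   CharacterVector qual, int mito_length,
                   int min_base_quality, int min_mapq, int max_mismatches) {
  const int n = cell.size();
  std::unordered_map<uint64_t, int> acc;
  acc.reserve(n * 4);
  int n_clipped = 0;
  for (int i = 0; i < n; ++i) {
    if (mapq[i] < min_mapq || nm[i] > max_mismatches) continue;
    const char *s = CHAR(STRING_ELT(seq, i));
    const char *q = CHAR(STRING_ELT(qual, i));
    int len = LENGTH(STRING_ELT(seq, i));
    int p0 = pos[i];  // 1-based leftmost
    int usable = len;
    if (p0 + len - 1 > mito_length) {
      usable = mito_length - p0 + 1;
      ++n_clipped;
      if (usable <= 0) continue;
    }
    uint64_t strand = is_plus[i] ? 0 : 1;
    for (int j = 0; j < usable; ++j) {
      if ((int)q[j] - 33 < min_base_quality) continue;
      int allele;
      switch (s[j]) {
        case 'A': allele = 0; break;
        case 'C': allele = 1; break;
        case 'G': allele = 2; break;
        case 'T': allele = 3; break;
        default: continue;  // N or other
      }
      uint64_t key = ((((uint64_t)cell[i] * (uint64_t)(mito_length + 1) +
                        (uint64_t)(p0 + j)) * 4ULL + (uint64_t)allele) * 2ULL) +
                     strand;
      ++acc[key];
    }
  }
  const size_t m = acc.size();
  IntegerVector out_cell(m), out_pos(m), out_allele(m), out_strand(m),
      out_count(m);
  size_t k = 0;
  for (const auto &kv : acc) {
    uint64_t key = kv.first;
    out_strand[k] = (int)(key % 2ULL);
    key /= 2ULL;
    out_allele[k] = (int)(key % 4ULL);
    key /= 4ULL;
    out_pos[k] = (int)(key % (uint64_t)(mito_length + 1));
    out_cell[k] = (int)(key / (uint64_t)(mito_length + 1));
    out_count[k] = kv.second;
    ++k;
  }
  return List::create(_["cell"] = out_cell, _["pos"] = out_pos,
                      _["allele"] = out_allele, _["strand"] = out_strand,
                      _["count"] = out_count, _["n_clipped"] = n_clipped);
}
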