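#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Bundle position-permuted level vectors into one hypervector per sample.
//
// level_idx: N x M matrix of 1-based level indices (one per sample/feature).
// levels_t:  D x m matrix, column l holding level vector l (transposed for
//            contiguous column access).
// Feature j (1-based) contributes its level vector rotated by j-1 positions
// toward higher indices. Entries are bounded by M, so int accumulation is safe.
// [[Rcpp::export]]
IntegerMatrix encode_profiles_cpp(const IntegerMatrix& level_idx,
                                  const IntegerMatrix& levels_t) {
  const int n = level_idx.nrow();
  const int m_feat = level_idx.ncol();
  const int d = levels_t.nrow();
  const int n_lev = levels_t.ncol();

  IntegerMatrix out(n, d);
  std::vector<int> buf(d);

  for (int i = 0; i < n; ++i) {
    std::fill(buf.begin(), buf.end(), 0);
    for (int j = 0; j < m_feat; ++j) {
      const int li = level_idx(i, j) - 1;
      if (li < 0 || li >= n_lev) stop("level index out of range");
      const int rot = j % d;
      const int* lv = &levels_t(0, li);
      // buf[(p + rot) mod d] += lv[p], split to avoid the modulo in the loop
      int q = rot;
      for (int p = 0; p < d - rot; ++p, ++q) buf[q] += lv[p];
      q = 0;
      for (int p = d - rot; p < d; ++p, ++q) buf[q] += lv[p];
    }
    for (int p = 0; p < d; ++p) out(i, p) = buf[p];
  }
  return out;
}
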