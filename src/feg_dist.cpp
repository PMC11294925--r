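#include <Rcpp.h>
using namespace Rcpp;

// Unit-cost edit distance of a query (length m) aligned globally into a
// reference (length n) whose ends are free: leading and trailing reference
// bases cost nothing, every query base is matched, mismatched (cost 1) or
// gapped (cost 1). Column dynamic program over reference positions
// (Sellers): C[0] = 0 at every column, C[i] = i initially, answer =
// min over columns of C[m]. 'N' matches anything.
//
// Distances above `cap` are reported as cap + 1, which licenses a diagonal
// band: a free leading offset of s reference bases forces at least
// s + m - n trailing query gaps, so any path with cost <= cap satisfies
// j - i >= -cap (query-gap budget) and j - i <= (n - m) + 2*cap (offset
// plus reference-gap budget). Cells outside the band are treated as
// cap + 1.
static int feg_dist_banded(const char *q, int m, const char *r, int n,
                           int cap) {
  const long full = (long)m + n;
  if (cap > full) cap = full;          // exact regime
  const int capped = cap + 1;
  std::vector<int> C(m + 1);
  for (int i = 0; i <= m; ++i) C[i] = (i <= cap) ? i : capped;
  int best = C[m];                     // column j = 0: query vs nothing
  for (int j = 1; j <= n; ++j) {
    const char rc = r[j - 1];
    long lo_l = (long)j - (n - m) - 2L * cap;
    long hi_l = (long)j + cap;
    const int lo = lo_l < 1 ? 1 : (int)lo_l;
    const int hi = hi_l > m ? m : (int)hi_l;
    if (lo > hi) continue;
    const int hi_prev = hi_l - 1 > m ? m : (int)(hi_l - 1);
    int prev_diag = (lo == 1) ? 0 : C[lo - 1];  // row lo-1, previous column
    int left = (lo == 1) ? 0 : capped;          // row lo-1, current column
    for (int i = lo; i <= hi; ++i) {
      const char qc = q[i - 1];
      const int sub = (qc == rc || qc == 'N' || rc == 'N') ? 0 : 1;
      const int old = (i > hi_prev) ? capped : C[i];
      int v = prev_diag + sub;
      if (left + 1 < v) v = left + 1;
      if (old + 1 < v) v = old + 1;
      if (v > capped) v = capped;
      prev_diag = old;
      left = v;
      C[i] = v;
    }
    if (hi == m && C[m] < best) best = C[m];
  }
  return best;
}

// [[Rcpp::export(name = ".feg_editdist_matrix")]]
IntegerMatrix feg_editdist_matrix(CharacterVector queries,
                                  CharacterVector refs,
                                  int cap = NA_INTEGER) {
  const int nq = queries.size(), nr = refs.size();
  IntegerMatrix out(nq, nr);
  std::vector<std::string> rs(nr);
  for (int r = 0; r < nr; ++r) rs[r] = as<std::string>(refs[r]);
  for (int i = 0; i < nq; ++i) {
    const std::string qs = as<std::string>(queries[i]);
    for (int r = 0; r < nr; ++r) {
      const int k = (cap == NA_INTEGER) ? (int)qs.size() + (int)rs[r].size()
                                        : cap;
      if (qs == rs[r]) {
        out(i, r) = 0;  // identity fast path
      } else {
        out(i, r) = feg_dist_banded(qs.c_str(), qs.size(),
                                    rs[r].c_str(), rs[r].size(), k);
      }
    }
  }
  return out;
}
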