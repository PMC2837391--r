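#include <Rcpp.h>
using namespace Rcpp;

// Hamming kernels for fixed-length tag sequences. These sit in C++ because
// family inference and synthetic planting are all-pairs / rejection-sampling
// workloads (10^8-10^9 byte comparisons at desk scale).

static inline int hamming_cstr(const char *a, const char *b, int n) {
  int d = 0;
  for (int i = 0; i < n; ++i) d += (a[i] != b[i]);
  return d;
}

// [[Rcpp::export(name = ".hamming_mat_cpp")]]
IntegerMatrix hamming_mat_cpp(CharacterVector a, CharacterVector b) {
  int na = a.size(), nb = b.size();
  if (na == 0 || nb == 0) return IntegerMatrix(na, nb);
  int len = LENGTH(STRING_ELT(a, 0));
  for (int i = 0; i < na; ++i)
    if (LENGTH(STRING_ELT(a, i)) != len) stop("sequences must share one length");
  for (int j = 0; j < nb; ++j)
    if (LENGTH(STRING_ELT(b, j)) != len) stop("sequences must share one length");
  IntegerMatrix out(na, nb);
  for (int j = 0; j < nb; ++j) {
    const char *pb = CHAR(STRING_ELT(b, j));
    for (int i = 0; i < na; ++i)
      out(i, j) = hamming_cstr(CHAR(STRING_ELT(a, i)), pb, len);
  }
  return out;
}

// For each candidate, TRUE iff its distance to every pool member is >= min_dist.
// Early exit on first violation keeps greedy rejection sampling cheap.
// [[Rcpp::export(name = ".min_dist_ok_cpp")]]
LogicalVector min_dist_ok_cpp(CharacterVector cand, CharacterVector pool,
                              int min_dist) {
  int nc = cand.size(), np = pool.size();
  LogicalVector out(nc, true);
  if (np == 0 || nc == 0) return out;
  int len = LENGTH(STRING_ELT(cand, 0));
  for (int i = 0; i < nc; ++i) {
    const char *pc = CHAR(STRING_ELT(cand, i));
    if (LENGTH(STRING_ELT(cand, i)) != len) stop("sequences must share one length");
    for (int j = 0; j < np; ++j) {
      if (LENGTH(STRING_ELT(pool, j)) != len) stop("sequences must share one length");
      if (hamming_cstr(pc, CHAR(STRING_ELT(pool, j)), len) < min_dist) {
        out[i] = false;
        break;
      }
    }
  }
  return out;
}
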