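#include "kfm.h"

using namespace Rcpp;

// Merge planning (joint prefix recursion over both indexes).
//
// For every vertex i of A its position in the preliminary n_A+n_B merged
// list is i + alpha_B(v_i^A); duplicates (alpha_B < beta_B) put the A record
// immediately before its B twin. Vertex groups present in both indexes have
// positions alpha_A+alpha_B .. beta_A+beta_B-2 marked for group-end flag
// removal. Rather than materializing vertex strings, the recursion extends
// prefixes one letter at a time (gamma(ax) = rho(a, gamma(x)) on both
// indexes) and tracks the sentinel-padded vertex x$^l of each prefix x
// through the in-edge chain of its parent's sentinel vertex.

struct MergeCtx {
  KfmView A, B;
  int k, sigma;
  std::vector<char> src, dup, clr;
  double rho_calls;
};

static void premerge(MergeCtx& C, int p, long aA, long bA, long aB, long bB,
                     bool sA, bool sB) {
  if (p == C.k - 1) {
    if (bA > aA) {
      C.src[aA + aB] = 1;
      C.dup[aA] = (bB > aB) ? 1 : 0;
    }
    return;
  }
  if (sA) { // A holds the sentinel vertex x$^(k-1-p) at position aA
    C.src[aA + aB] = 1;
    C.dup[aA] = sB ? 1 : 0;
  }
  if (p == C.k - 2 && bA > aA && bB > aB) {
    for (long t = aA + aB; t <= bA + bB - 2; ++t) C.clr[t] = 1;
  }
  for (int b = 0; b < C.sigma; ++b) {
    long caA = C.A.rho(b, aA), cbA = C.A.rho(b, bA);
    C.rho_calls += 2;
    if (caA == cbA) continue; // no A vertices below this prefix
    long caB = C.B.rho(b, aB), cbB = C.B.rho(b, bB);
    C.rho_calls += 2;
    premerge(C, p + 1, caA, cbA, caB, cbB,
             sA && C.A.eta(b, aA), sB && C.B.eta(b, aB));
  }
}

// [[Rcpp::export]]
List kfm_merge_plan_cpp(List A, List B) {
  MergeCtx C;
  C.A = as_view(A);
  C.B = as_view(B);
  if (C.A.k != C.B.k) stop("indexes have different k");
  if (C.A.sigma != C.B.sigma) stop("indexes have different alphabets");
  C.k = C.A.k;
  C.sigma = C.A.sigma;
  C.src.assign(C.A.n + C.B.n, 0);
  C.dup.assign(C.A.n, 0);
  C.clr.assign(C.A.n + C.B.n, 0);
  C.rho_calls = 0;
  premerge(C, 0, 0, C.A.n, 0, C.B.n, true, true);
  long placed = 0;
  for (char f : C.src) placed += f;
  if (placed != C.A.n) stop("internal error: merge plan placed %d of %d A vertices",
                            (int)placed, (int)C.A.n);
  return List::create(_["source_flags"] = LogicalVector(C.src.begin(), C.src.end()),
                      _["duplicate_flags"] = LogicalVector(C.dup.begin(), C.dup.end()),
                      _["groupend_clear_flags"] = LogicalVector(C.clr.begin(), C.clr.end()),
                      _["rho_calls"] = C.rho_calls);
}

// Single sequential pass: emit records in merged order, OR-combining each
// duplicate (A, B-twin) pair, clearing marked group-end flags.
// [[Rcpp::export]]
IntegerVector kfm_merge_apply_cpp(IntegerVector recA, IntegerVector recB,
                                  int sigma, LogicalVector src,
                                  LogicalVector dup, LogicalVector clr) {
  long nA = recA.size(), nB = recB.size(), N = nA + nB;
  if ((long)src.size() != N || (long)clr.size() != N || (long)dup.size() != nA)
    stop("merge plan does not match the given indexes");
  int fmask = 1 << sigma;
  std::vector<int> out;
  out.reserve(N);
  long ia = 0, ib = 0;
  for (long pos = 0; pos < N; ++pos) {
    if (src[pos]) {
      if (ia >= nA) stop("merge plan corrupt: too many A positions");
      int r = recA[ia];
      if (clr[pos]) r &= ~fmask;
      if (dup[ia]) {
        if (pos + 1 >= N || src[pos + 1])
          stop("merge plan corrupt: duplicate A vertex without adjacent B twin");
        int r2 = recB[ib];
        if (clr[pos + 1]) r2 &= ~fmask;
        r |= r2;
        ++ib;
        ++pos;
      }
      out.push_back(r);
      ++ia;
    } else {
      if (ib >= nB) stop("merge plan corrupt: too many B positions");
      int r = recB[ib];
      if (clr[pos]) r &= ~fmask;
      out.push_back(r);
      ++ib;
    }
  }
  if (ia != nA || ib != nB) stop("merge plan corrupt: not all vertices consumed");
  return IntegerVector(out.begin(), out.end());
}
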