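#include "kfm.h"

using namespace Rcpp;

// Pruning of superfluous sentinel-padded (final-completing) vertices.
//
// The sentinel-padded vertices form a tree rooted at the final vertex
// $^{k-1} (position 0). A depth-first backtrack through in-edges visits
// every such vertex once (each has exactly one out-edge, to its own
// $-extension). Two rules apply:
//   * a vertex u$ ending in a single $ may drop its in-edge a if another
//     vertex u.b of the same group has an a in-edge (the origin a.u can
//     then still be reached by backtracking from u.b);
//   * a sentinel-padded vertex with no (remaining) in-edges is removed,
//     together with the in-edge of its $-extension that pointed at it.
// Because rho depends on group composition, edges and vertices are only
// marked here; the actual removal is one compaction pass at the end.

struct PruneCtx {
  KfmView V;
  std::vector<int> edgeRm;   // per-vertex mask of removed in-edges
  std::vector<char> vertRm;
};

static bool prune_rec(PruneCtx& C, long i, int l) {
  int e = C.V.edges(i);
  for (int a = 0; a < C.V.sigma; ++a) {
    if (!((e >> a) & 1)) continue;
    if (l > 1) {
      long j = C.V.rho(a, i);
      if (prune_rec(C, j, l - 1)) {
        C.edgeRm[i] |= 1 << a;
        C.vertRm[j] = 1;
      }
    } else {
      // v = u$: redundant if some u.b in the same group has an a in-edge
      long ge = i;
      while (!C.V.fend(ge)) ++ge;
      for (long t = i + 1; t <= ge; ++t) {
        if (C.V.eta(a, t)) {
          C.edgeRm[i] |= 1 << a;
          break;
        }
      }
    }
  }
  return (C.edgeRm[i] & e) == e; // all in-edges removed => vertex unneeded
}

// [[Rcpp::export]]
List kfm_prune_cpp(List idx) {
  PruneCtx C;
  C.V = as_view(idx);
  long n = C.V.n;
  C.edgeRm.assign(n, 0);
  C.vertRm.assign(n, 0);
  if (C.V.k > 2) prune_rec(C, 0, C.V.k - 1); // root itself is never removed
  int fmask = 1 << C.V.sigma;
  std::vector<int> out;
  out.reserve(n);
  long removedV = 0, removedE = 0;
  long lastNew = -1; // output slot of the last survivor in the current group
  for (long i = 0; i < n; ++i) {
    if (!C.vertRm[i]) {
      int mask = C.edgeRm[i];
      for (int a = 0; a < C.V.sigma; ++a) removedE += (mask >> a) & 1;
      out.push_back((C.V.rec[i] & ~mask) & ~fmask);
      lastNew = (long)out.size() - 1;
    } else {
      ++removedV;
      int e = C.V.edges(i);
      for (int a = 0; a < C.V.sigma; ++a) removedE += (e >> a) & 1;
    }
    if (C.V.fend(i)) {
      if (lastNew >= 0) out[lastNew] |= fmask;
      lastNew = -1;
    }
  }
  return List::create(_["records"] = IntegerVector(out.begin(), out.end()),
                      _["removed_vertices"] = (double)removedV,
                      _["removed_edges"] = (double)removedE,
                      _["vertex_removed"] = LogicalVector(C.vertRm.begin(),
                                                          C.vertRm.end()));
}
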