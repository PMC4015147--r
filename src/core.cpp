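#include "kfm.h"

using namespace Rcpp;

KfmView as_view(const List& idx) {
  KfmView v;
  IntegerVector rec = idx["records"];
  List st = idx["store"];
  IntegerVector u = st["u"];
  RawVector dl = st["delta"];
  IntegerVector cp = st["checkpoints"];
  v.rec = INTEGER(rec);
  v.n = rec.size();
  v.sigma = as<int>(idx["sigma"]);
  v.k = as<int>(idx["k"]);
  v.q = as<int>(st["q"]);
  v.w = as<int>(st["w"]);
  v.zeta = as<int>(st["zeta"]);
  v.u = INTEGER(u);
  v.dl = RAW(dl);
  v.cp = INTEGER(cp);
  v.ncp = cp.size();
  if ((long)u.size() != (long)v.sigma * v.zeta + 1)
    stop("corrupt index: previous-position store has wrong length");
  return v;
}

// Build the sparse previous-position store from finalized vertex records.
// Stored positions are i_r = min(r*q, n), r = 0..zeta; kappa(a*zeta + r) =
// rho(a, i_r) = 1 + sum_{b<a} tau(b) + c(a, i_r) is computed in one linear
// pass that counts, per letter, the vertex groups wholly before each i_r.
// [[Rcpp::export]]
List kfm_store_build_cpp(IntegerVector records, int sigma, int q, int w) {
  long n = records.size();
  if (n < 1) stop("index must contain at least the final vertex");
  if (q < 1 || w < 1) stop("q and w must be positive");
  const int* rec = INTEGER(records);
  if (!((rec[n - 1] >> sigma) & 1))
    stop("corrupt records: last vertex must close a group (f[n-1] = TRUE)");
  long zeta = (n + q - 1) / q;
  std::vector<long> C((size_t)(zeta + 1) * sigma);
  std::vector<long> c(sigma, 0);
  unsigned int seen = 0;
  for (long i = 0; i < n; ++i) {
    if (i % q == 0) {
      long r = i / q;
      for (int a = 0; a < sigma; ++a) C[(size_t)r * sigma + a] = c[a];
    }
    seen |= (unsigned int)rec[i];
    if ((rec[i] >> sigma) & 1) {
      for (int a = 0; a < sigma; ++a)
        if ((seen >> a) & 1) ++c[a];
      seen = 0;
    }
  }
  for (int a = 0; a < sigma; ++a) C[(size_t)zeta * sigma + a] = c[a];

  IntegerVector tau(sigma);
  std::vector<long> pre(sigma);
  long s = 1; // the +1 skips the final vertex $^{k-1}
  for (int a = 0; a < sigma; ++a) {
    tau[a] = (int)c[a];
    pre[a] = s;
    s += c[a];
  }

  long m = (long)sigma * zeta;
  IntegerVector u(m + 1);
  RawVector dl(m + 1);
  IntegerVector cp(m / w + 1);
  long prevU = 0;
  for (long j = 0; j <= m; ++j) {
    int a = (int)(j / zeta);
    long r = j % zeta;
    if (a == sigma) { a = sigma - 1; r = zeta; }
    long kap = pre[a] + C[(size_t)r * sigma + a];
    long U = kap / q;
    u[j] = (int)(kap % q);
    if (j == 0) {
      dl[j] = 0;
    } else {
      long d = U - prevU;
      if (d < 0 || d > 1)
        stop("internal error: kappa increment outside [0, q] at entry %d", (int)j);
      dl[j] = (unsigned char)d;
    }
    if (j % w == 0) cp[j / w] = (int)U;
    prevU = U;
  }
  return List::create(_["q"] = q, _["w"] = w, _["zeta"] = (int)zeta,
                      _["u"] = u, _["delta"] = dl, _["checkpoints"] = cp,
                      _["tau"] = tau);
}

// [[Rcpp::export]]
IntegerVector kfm_rho_cpp(List idx, IntegerVector a, IntegerVector i) {
  KfmView v = as_view(idx);
  R_xlen_t len = std::max(a.size(), i.size());
  IntegerVector out(len);
  for (R_xlen_t t = 0; t < len; ++t) {
    int at = a[t % a.size()];
    long it = i[t % i.size()];
    if (at < 0 || at >= v.sigma) stop("letter code out of range");
    if (it < 0 || it > v.n) stop("vertex index out of range [0, n]");
    out[t] = (int)v.rho(at, it);
  }
  return out;
}

// [[Rcpp::export]]
int kfm_gamma_cpp(List idx, IntegerVector xcodes, int i0) {
  KfmView v = as_view(idx);
  if (i0 < 0 || i0 > v.n) stop("start index out of range [0, n]");
  long cur = i0;
  for (R_xlen_t p = xcodes.size() - 1; p >= 0; --p) {
    int a = xcodes[p];
    if (a < 0 || a >= v.sigma) stop("letter code out of range");
    cur = v.rho(a, cur);
  }
  return (int)cur;
}

// Combined alpha/beta fold; once the two states coincide the remaining
// steps are computed once.
// [[Rcpp::export]]
IntegerVector kfm_interval_cpp(List idx, IntegerVector xcodes) {
  KfmView v = as_view(idx);
  long alpha = 0, beta = v.n;
  for (R_xlen_t p = xcodes.size() - 1; p >= 0; --p) {
    int a = xcodes[p];
    if (a < 0 || a >= v.sigma) stop("letter code out of range");
    if (alpha == beta) {
      alpha = beta = v.rho(a, alpha);
    } else {
      alpha = v.rho(a, alpha);
      beta = v.rho(a, beta);
    }
  }
  return IntegerVector::create((int)alpha, (int)beta);
}

// Backtrack the graph along x (|x| >= k): locate the (k-1)-suffix vertex,
// then follow one in-edge per remaining letter, checking eta at each step.
// Returns c(found, vertex-of-(k-1)-prefix or -1).
// [[Rcpp::export]]
IntegerVector kfm_contains_cpp(List idx, IntegerVector xcodes) {
  KfmView v = as_view(idx);
  R_xlen_t len = xcodes.size();
  if (len < v.k) stop("string shorter than k");
  long alpha = 0, beta = v.n;
  for (R_xlen_t p = len - 1; p >= len - (v.k - 1); --p) {
    int a = xcodes[p];
    if (a < 0 || a >= v.sigma) stop("letter code out of range");
    if (alpha == beta) {
      alpha = beta = v.rho(a, alpha);
    } else {
      alpha = v.rho(a, alpha);
      beta = v.rho(a, beta);
    }
  }
  if (alpha == beta) return IntegerVector::create(0, -1);
  long i = alpha;
  for (R_xlen_t p = len - v.k; p >= 0; --p) {
    int a = xcodes[p];
    if (a < 0 || a >= v.sigma) stop("letter code out of range");
    if (!v.eta(a, i)) return IntegerVector::create(0, -1);
    i = v.rho(a, i);
  }
  return IntegerVector::create(1, (int)i);
}

// [[Rcpp::export]]
IntegerMatrix kfm_rho_inv_cpp(List idx, IntegerVector is) {
  KfmView v = as_view(idx);
  IntegerMatrix out(2, is.size());
  for (R_xlen_t t = 0; t < is.size(); ++t) {
    long i = is[t];
    if (i < 0 || i >= v.n) stop("vertex index out of range [0, n)");
    int a;
    long j;
    v.rho_inv(i, &a, &j);
    out(0, t) = a;
    out(1, t) = (int)j;
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix kfm_vertex_codes_cpp(List idx, IntegerVector is) {
  KfmView v = as_view(idx);
  IntegerMatrix out(v.k - 1, is.size());
  std::vector<int> buf(v.k - 1);
  for (R_xlen_t t = 0; t < is.size(); ++t) {
    long i = is[t];
    if (i < 0 || i >= v.n) stop("vertex index out of range [0, n)");
    v.vertex_codes(i, buf.data());
    for (int p = 0; p < v.k - 1; ++p) out(p, t) = buf[p];
  }
  return out;
}

// In/out-degrees in one synchronized sweep: rho(a, .) is constant within a
// vertex group, so a running per-letter origin counter gives the origin
// vertex of every edge without materializing strings.
// [[Rcpp::export]]
List kfm_classify_cpp(List idx) {
  KfmView v = as_view(idx);
  IntegerVector tau = idx["tau"];
  std::vector<long> cur(v.sigma);
  long s = 1;
  for (int a = 0; a < v.sigma; ++a) {
    cur[a] = s; // rho(a, 0)
    s += tau[a];
  }
  IntegerVector indeg(v.n), outdeg(v.n);
  unsigned int seen = 0;
  for (long i = 0; i < v.n; ++i) {
    int e = v.edges(i);
    int d = 0;
    for (int a = 0; a < v.sigma; ++a)
      if ((e >> a) & 1) {
        ++d;
        ++outdeg[cur[a]];
      }
    indeg[i] = d;
    seen |= (unsigned int)e;
    if (v.fend(i)) {
      for (int a = 0; a < v.sigma; ++a)
        if ((seen >> a) & 1) ++cur[a];
      seen = 0;
    }
  }
  return List::create(_["in_degree"] = indeg, _["out_degree"] = outdeg);
}

// Extract all uniquely determined paths: anchor at each non-simple vertex t
// and each in-edge a of t, walk backward through simple vertices collecting
// in-edge letters (= first letters of the traversed vertices), then emit
// reversed letters + string(t). Paths whose vertices are all sentinel-padded
// are dropped; trailing $ are trimmed. Isolated all-simple cycles are
// emitted once each, flagged circular.
// [[Rcpp::export]]
List kfm_paths_cpp(List idx, IntegerVector indeg, IntegerVector outdeg,
                   std::string letters) {
  KfmView v = as_view(idx);
  long n = v.n;
  std::vector<char> nonsimple(n), visited(n);
  for (long i = 0; i < n; ++i)
    nonsimple[i] = (indeg[i] != 1 || outdeg[i] != 1);
  std::vector<std::string> seqs;
  std::vector<int> starts, ends, nverts, circ;
  std::vector<int> vbuf(v.k - 1);
  std::string buf;

  auto emit_tail = [&](long t) {
    // append string(t), return its trailing-$ count
    v.vertex_codes(t, vbuf.data());
    int trail = 0;
    for (int p = 0; p < v.k - 1; ++p) {
      int c = vbuf[p];
      buf.push_back(c < 0 ? '$' : letters[c]);
    }
    for (int p = v.k - 2; p >= 0 && vbuf[p] < 0; --p) ++trail;
    return trail;
  };

  for (long t = 0; t < n; ++t) {
    if (!nonsimple[t]) continue;
    int e = v.edges(t);
    for (int a = 0; a < v.sigma; ++a) {
      if (!((e >> a) & 1)) continue;
      buf.clear();
      buf.push_back(letters[a]);
      long o = v.rho(a, t);
      long guard = 0;
      while (!nonsimple[o]) {
        visited[o] = 1;
        int eo = v.edges(o);
        int b = 0;
        while (!((eo >> b) & 1)) ++b;
        buf.push_back(letters[b]);
        o = v.rho(b, o);
        if (++guard > n) stop("path walk did not terminate (corrupt index?)");
      }
      long m = (long)buf.size(); // number of edges on the path
      std::reverse(buf.begin(), buf.end());
      int trail = emit_tail(t);
      if (trail > m) continue; // all vertices sentinel-padded
      buf.resize(buf.size() - trail);
      seqs.push_back(buf);
      starts.push_back((int)o);
      ends.push_back((int)t);
      nverts.push_back((int)(m + 1));
      circ.push_back(0);
    }
  }
  // isolated all-simple cycles
  for (long i = 0; i < n; ++i) {
    if (nonsimple[i] || visited[i]) continue;
    buf.clear();
    long o = i;
    do {
      visited[o] = 1;
      int eo = v.edges(o);
      int b = 0;
      while (!((eo >> b) & 1)) ++b;
      buf.push_back(letters[b]);
      o = v.rho(b, o);
    } while (o != i);
    long m = (long)buf.size();
    std::reverse(buf.begin(), buf.end());
    emit_tail(i);
    seqs.push_back(buf);
    starts.push_back((int)i);
    ends.push_back((int)i);
    nverts.push_back((int)m);
    circ.push_back(1);
  }
  return List::create(_["sequence"] = wrap(seqs),
                      _["start_vertex"] = wrap(starts),
                      _["end_vertex"] = wrap(ends),
                      _["n_vertices"] = wrap(nverts),
                      _["circular"] = wrap(circ));
}
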