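#ifndef KFMINDEX_KFM_H
#define KFMINDEX_KFM_H

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>

// Light-weight, non-owning view of a kFM-index held as plain R vectors.
//
// Vertex record i is an integer bit mask: bits 0..sigma-1 are the in-edge
// flags eta(a,i) by letter code, bit sigma is the group-end flag f_i.
// The previous-position store holds kappa(j) = rho(a, i_r), j = a*zeta + r,
// decomposed as kappa = u + q*U with U reconstructed from every w-th
// checkpoint plus single-bit increments.
struct KfmView {
  const int* rec;
  long n;
  int sigma;
  int k;
  int q;
  int w;
  long zeta;
  const int* u;            // sigma*zeta + 1 low values, in [0, q)
  const unsigned char* dl; // sigma*zeta + 1 single-bit U increments
  const int* cp;           // U at every w-th entry
  long ncp;

  bool eta(int a, long i) const { return (rec[i] >> a) & 1; }
  bool fend(long i) const { return (rec[i] >> sigma) & 1; }
  int edges(long i) const { return rec[i] & ((1 << sigma) - 1); }

  long kappa(long j) const {
    long base = j - (j % w);
    long U = cp[j / w];
    for (long m = base + 1; m <= j; ++m) U += dl[m];
    return (long)u[j] + (long)q * U;
  }

  long stored_pos(long r) const { return std::min((long)r * q, n); }

  // rho(a, i) for 0 <= i <= n, forward aggregation from the nearest
  // previous stored value; a group straddling the stored position is
  // rewound to its start so group in-edge presence is counted once.
  long rho(int a, long i) const {
    long r = std::min(i / q, zeta);
    long base = kappa((long)a * zeta + r);
    long ir = stored_pos(r);
    if (i == ir) return base;
    long gs = ir;
    while (gs > 0 && !fend(gs - 1)) --gs;
    bool seen = false;
    for (long t = gs; t < ir; ++t) seen = seen || eta(a, t);
    long cnt = 0;
    for (long t = ir; t < i; ++t) {
      seen = seen || eta(a, t);
      if (fend(t)) {
        if (seen) ++cnt;
        seen = false;
      }
    }
    return base + cnt;
  }

  // rho_inv(i) = (a, j) with rho(a, j) = i and rho(a, j + 1) = i + 1,
  // rho_inv(0) = ($, 0) encoded as a = -1. Binary search on the stored
  // kappa values, then a stepwise scan within (at most a few) strides.
  void rho_inv(long i, int* a_out, long* j_out) const {
    if (i == 0) {
      *a_out = -1;
      *j_out = 0;
      return;
    }
    long lo = 0, hi = (long)sigma * zeta; // largest j with kappa(j) <= i
    while (lo < hi) {
      long mid = lo + (hi - lo + 1) / 2;
      if (kappa(mid) <= i) lo = mid;
      else hi = mid - 1;
    }
    int a = (int)(lo / zeta);
    long r = lo % zeta;
    if (a >= sigma) { a = sigma - 1; r = zeta; }
    long cur = kappa(lo);
    long t = stored_pos(r);
    long gs = t;
    while (gs > 0 && !fend(gs - 1)) --gs;
    bool seen = false;
    for (long m = gs; m < t; ++m) seen = seen || eta(a, m);
    while (t < n) {
      seen = seen || eta(a, t);
      long nxt = cur;
      if (fend(t)) nxt += seen ? 1 : 0;
      if (cur == i && nxt == i + 1) {
        *a_out = a;
        *j_out = t;
        return;
      }
      if (fend(t)) seen = false;
      cur = nxt;
      ++t;
    }
    Rcpp::stop("rho_inv: no solution for position %d (corrupt index?)", (int)i);
  }

  // String of vertex i as letter codes, -1 for the sentinel $.
  void vertex_codes(long i, int* out) const {
    long cur = i;
    for (int p = 0; p < k - 1; ++p) {
      int a;
      long j;
      rho_inv(cur, &a, &j);
      out[p] = a;
      cur = j;
    }
  }
};

KfmView as_view(const Rcpp::List& idx);

#endif
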