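#include "kfm.h"

using namespace Rcpp;

// KFMI v1 serialization.
//
// Header: magic "KFMI", version u8, sigma u8, alphabet (sigma bytes),
// k u32, n u64, q u32, w u32 (all little-endian). Then three bit-packed
// sections, each padded to whole little-endian 64-bit words, low bits first:
//   1. vertex records, sigma+1 bits each, floor(64/(sigma+1)) per word;
//   2. the u_j low values, ceil(lg q) bits each (absent when q = 1),
//      followed (new word) by the Delta U_j increments, 1 bit each;
//   3. the U checkpoints, one full 64-bit word each.
// This reproduces the accounted cost of sigma*(lg q + 2)/q store bits and
// 64/floor(64/(sigma+1)) record bits per vertex, up to word rounding.

static void put_u64(std::vector<unsigned char>& b, uint64_t x) {
  for (int i = 0; i < 8; ++i) b.push_back((unsigned char)(x >> (8 * i)));
}
static void put_u32(std::vector<unsigned char>& b, uint32_t x) {
  for (int i = 0; i < 4; ++i) b.push_back((unsigned char)(x >> (8 * i)));
}

struct BitWriter {
  std::vector<unsigned char>& b;
  uint64_t word = 0;
  int fill = 0;
  explicit BitWriter(std::vector<unsigned char>& buf) : b(buf) {}
  void put(uint64_t v, int bits) {
    for (int i = 0; i < bits; ++i) {
      word |= ((v >> i) & 1) << fill;
      if (++fill == 64) {
        put_u64(b, word);
        word = 0;
        fill = 0;
      }
    }
  }
  void flush() {
    if (fill > 0) {
      put_u64(b, word);
      word = 0;
      fill = 0;
    }
  }
};

struct BitReader {
  const unsigned char* p;
  size_t len, at = 0; // bit cursor
  BitReader(const unsigned char* buf, size_t nbytes) : p(buf), len(nbytes * 8) {}
  uint64_t get(int bits) {
    uint64_t v = 0;
    for (int i = 0; i < bits; ++i) {
      if (at >= len) stop("kFM-index file truncated inside a bit-packed section");
      v |= (uint64_t)((p[at >> 3] >> (at & 7)) & 1) << i;
      ++at;
    }
    return v;
  }
  void align64() { at = (at + 63) & ~(size_t)63; }
};

static int ubits(int q) {
  int b = 0;
  while ((1 << b) < q) ++b; // ceil(lg q); 0 when q = 1
  return b;
}

// [[Rcpp::export]]
RawVector kfm_serialize_cpp(List idx, std::string letters) {
  KfmView v = as_view(idx);
  std::vector<unsigned char> b;
  b.push_back('K'); b.push_back('F'); b.push_back('M'); b.push_back('I');
  b.push_back(1);
  b.push_back((unsigned char)v.sigma);
  for (char c : letters) b.push_back((unsigned char)c);
  put_u32(b, (uint32_t)v.k);
  put_u64(b, (uint64_t)v.n);
  put_u32(b, (uint32_t)v.q);
  put_u32(b, (uint32_t)v.w);
  // records: floor(64/(sigma+1)) whole vertices per word, low bits first
  int per = 64 / (v.sigma + 1);
  for (long i = 0; i < v.n; i += per) {
    uint64_t word = 0;
    for (int j = 0; j < per && i + j < v.n; ++j)
      word |= (uint64_t)(unsigned int)v.rec[i + j] << (j * (v.sigma + 1));
    put_u64(b, word);
  }
  BitWriter bw(b);
  long m = (long)v.sigma * v.zeta;
  int nb = ubits(v.q);
  if (nb > 0) {
    for (long j = 0; j <= m; ++j) bw.put((uint64_t)v.u[j], nb);
    bw.flush();
  }
  for (long j = 0; j <= m; ++j) bw.put((uint64_t)v.dl[j], 1);
  bw.flush();
  for (long t = 0; t < v.ncp; ++t) put_u64(b, (uint64_t)(unsigned int)v.cp[t]);
  return RawVector(b.begin(), b.end());
}

// [[Rcpp::export]]
List kfm_deserialize_cpp(RawVector bytes) {
  const unsigned char* p = RAW(bytes);
  size_t len = bytes.size();
  if (len < 6 || p[0] != 'K' || p[1] != 'F' || p[2] != 'M' || p[3] != 'I')
    stop("not a kFM-index file: bad magic at offset 0");
  if (p[4] != 1)
    stop("unsupported kFM-index format version %d at offset 4", (int)p[4]);
  int sigma = p[5];
  if (sigma < 1 || sigma > 30)
    stop("corrupt kFM-index header: sigma = %d at offset 5", sigma);
  size_t at = 6;
  if (len < at + (size_t)sigma + 20) stop("kFM-index file truncated in header");
  std::string letters((const char*)p + at, (size_t)sigma);
  at += sigma;
  uint32_t k = 0, q = 0, w = 0;
  uint64_t n = 0;
  for (int i = 0; i < 4; ++i) k |= (uint32_t)p[at + i] << (8 * i);
  at += 4;
  for (int i = 0; i < 8; ++i) n |= (uint64_t)p[at + i] << (8 * i);
  at += 8;
  for (int i = 0; i < 4; ++i) q |= (uint32_t)p[at + i] << (8 * i);
  at += 4;
  for (int i = 0; i < 4; ++i) w |= (uint32_t)p[at + i] << (8 * i);
  at += 4;
  if (k < 3 || q < 1 || w < 1 || n < 1)
    stop("corrupt kFM-index header: k=%d n=%d q=%d w=%d", (int)k, (int)n,
         (int)q, (int)w);
  long zeta = ((long)n + q - 1) / q;
  long m = (long)sigma * zeta;
  int nb = ubits((int)q);
  size_t words_rec = ((size_t)n + (64 / (sigma + 1)) - 1) / (64 / (sigma + 1));
  size_t words_u = nb > 0 ? ((size_t)(m + 1) * nb + 63) / 64 : 0;
  size_t words_dl = ((size_t)m + 1 + 63) / 64;
  size_t ncp = (size_t)(m / w) + 1;
  size_t need = at + 8 * (words_rec + words_u + words_dl + ncp);
  if (len != need)
    stop("kFM-index file has %d bytes, expected %d (truncated at offset %d?)",
         (int)len, (int)need, (int)std::min(len, need));
  BitReader br(p + at, len - at);
  IntegerVector rec((R_xlen_t)n);
  int per = 64 / (sigma + 1);
  int mask = (1 << (sigma + 1)) - 1;
  for (size_t t = 0; t < words_rec; ++t) {
    uint64_t word = br.get(64);
    for (int j = 0; j < per; ++j) {
      size_t i = t * per + j;
      if (i < n) rec[i] = (int)((word >> (j * (sigma + 1))) & mask);
    }
  }
  IntegerVector u(m + 1);
  if (nb > 0) {
    for (long j = 0; j <= m; ++j) u[j] = (int)br.get(nb);
    br.align64();
  }
  RawVector dl(m + 1);
  for (long j = 0; j <= m; ++j) dl[j] = (unsigned char)br.get(1);
  br.align64();
  IntegerVector cp((R_xlen_t)ncp);
  for (size_t t = 0; t < ncp; ++t) cp[t] = (int)br.get(64);
  List store = List::create(_["q"] = (int)q, _["w"] = (int)w,
                            _["zeta"] = (int)zeta, _["u"] = u,
                            _["delta"] = dl, _["checkpoints"] = cp);
  // tau(a) = rho(a, n) - rho(a, 0), both stored exactly
  KfmView v;
  v.rec = INTEGER(rec);
  v.n = (long)n;
  v.sigma = sigma;
  v.k = (int)k;
  v.q = (int)q;
  v.w = (int)w;
  v.zeta = zeta;
  v.u = INTEGER(u);
  v.dl = RAW(dl);
  v.cp = INTEGER(cp);
  v.ncp = (long)ncp;
  IntegerVector tau(sigma);
  for (int a = 0; a < sigma; ++a)
    tau[a] = (int)(v.kappa((long)a * zeta + zeta) - v.kappa((long)a * zeta));
  return List::create(_["letters"] = letters, _["k"] = (int)k,
                      _["records"] = rec, _["store"] = store, _["tau"] = tau);
}
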