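#include "kfm.h"
#include <cmath>

using namespace Rcpp;

// Edge words are k-symbol sequences over the alphabet extended with the
// sentinel $ (code 0; letters take codes 1..sigma), packed big-endian in
// base sigma+1 into one 64-bit integer keyed as (target (k-1)-mer, letter):
// a single integer sort then yields the (target, letter) order required to
// emit vertex records directly.

static void code_table(const std::string& letters, signed char* tab) {
  for (int c = 0; c < 256; ++c) tab[c] = -1;
  for (size_t a = 0; a < letters.size(); ++a)
    tab[(unsigned char)letters[a]] = (signed char)(a + 1);
}

static uint64_t pow_check(int B, int k) {
  long double lim = std::pow((long double)2.0, 62.0);
  long double p = 1.0;
  for (int t = 0; t < k; ++t) p *= B;
  if (p >= lim)
    stop("k too large for this alphabet: need (sigma+1)^k < 2^62 (DNA: k <= 26)");
  uint64_t r = 1;
  for (int t = 0; t < k; ++t) r *= (uint64_t)B;
  return r;
}

static void collect_words(const CharacterVector& strings, int k,
                          const std::string& letters,
                          std::vector<uint64_t>& words) {
  signed char tab[256];
  code_table(letters, tab);
  int B = (int)letters.size() + 1;
  pow_check(B, k);
  uint64_t powKm2 = 1;
  for (int t = 0; t < k - 2; ++t) powKm2 *= (uint64_t)B;
  for (R_xlen_t s = 0; s < strings.size(); ++s) {
    const char* x = CHAR(STRING_ELT(strings, s));
    long m = (long)LENGTH(STRING_ELT(strings, s));
    if (m < k - 1)
      stop("string %d is shorter than k-1 (filter such strings upstream)",
           (int)(s + 1));
    uint64_t cur = 0;
    for (int p = 0; p < k - 1; ++p) {
      int c = tab[(unsigned char)x[p]];
      if (c < 0) stop("symbol '%c' not in the declared alphabet", x[p]);
      cur = cur * B + (uint64_t)c;
    }
    // vertex marker (in-letter $ = 0) for the string-start (k-1)-mer: it is
    // an edge origin but, unless it recurs internally, never an edge target
    words.push_back(cur * B);
    for (long i = 0; i + k <= m; ++i) {
      int c = tab[(unsigned char)x[i + k - 1]];
      if (c < 0) stop("symbol '%c' not in the declared alphabet", x[i + k - 1]);
      cur = (cur % powKm2) * B + (uint64_t)c; // window s[i+1 .. i+k-1]
      words.push_back(cur * B + (uint64_t)tab[(unsigned char)x[i]]);
    }
    // sentinel-padded words from the (k-1)-suffix v: v[j..]$^j, j = 1..k-1
    uint64_t T = cur;
    for (int j = 1; j <= k - 1; ++j) {
      T = (T % powKm2) * B;
      words.push_back(T * B + (uint64_t)tab[(unsigned char)x[m - k + j]]);
    }
  }
}

static IntegerVector records_from_sorted(std::vector<uint64_t>& words, int sigma) {
  int B = sigma + 1;
  std::sort(words.begin(), words.end());
  words.erase(std::unique(words.begin(), words.end()), words.end());
  std::vector<int> rec;
  std::vector<uint64_t> targ;
  rec.reserve(words.size() + 1);
  targ.reserve(words.size() + 1);
  for (size_t t = 0; t < words.size(); ++t) {
    uint64_t T = words[t] / (uint64_t)B;
    int a = (int)(words[t] % (uint64_t)B);
    if (targ.empty() || targ.back() != T) {
      targ.push_back(T);
      rec.push_back(0);
    }
    if (a > 0) rec.back() |= 1 << (a - 1); // a == 0: vertex marker only
  }
  // the final vertex $^{k-1} (target code 0) is added explicitly if absent
  if (targ.empty() || targ.front() != 0) {
    targ.insert(targ.begin(), 0);
    rec.insert(rec.begin(), 0);
  }
  long n = (long)rec.size();
  IntegerVector out(n);
  int fmask = 1 << sigma;
  for (long i = 0; i < n; ++i) {
    int r = rec[i];
    if (i == n - 1 || targ[i] / (uint64_t)B != targ[i + 1] / (uint64_t)B)
      r |= fmask;
    out[i] = r;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector kfm_records_build_cpp(CharacterVector strings, int k,
                                    std::string letters) {
  if (k < 3) stop("k must be at least 3");
  std::vector<uint64_t> words;
  size_t total = 0;
  for (R_xlen_t s = 0; s < strings.size(); ++s) {
    long m = (long)LENGTH(STRING_ELT(strings, s));
    total += (size_t)std::max(0L, m - k + 1) + (size_t)(k - 1);
  }
  words.reserve(total);
  collect_words(strings, k, letters, words);
  return records_from_sorted(words, (int)letters.size());
}

// Number of edge words a set of strings will contribute (k-substrings plus
// k-1 sentinel completions per string); used for partition planning.
// [[Rcpp::export]]
NumericVector kfm_word_counts_cpp(CharacterVector strings, int k) {
  NumericVector out(strings.size());
  for (R_xlen_t s = 0; s < strings.size(); ++s) {
    long m = (long)LENGTH(STRING_ELT(strings, s));
    out[s] = (double)std::max(0L, m - k + 1) + (double)(k - 1);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector kfm_revcomp_cpp(CharacterVector strings, std::string letters,
                                std::string complements) {
  if (letters.size() != complements.size())
    stop("letters and complements must have equal length");
  unsigned char tab[256];
  for (int c = 0; c < 256; ++c) tab[c] = 0;
  for (size_t a = 0; a < letters.size(); ++a)
    tab[(unsigned char)letters[a]] = (unsigned char)complements[a];
  CharacterVector out(strings.size());
  std::string buf;
  for (R_xlen_t s = 0; s < strings.size(); ++s) {
    const char* x = CHAR(STRING_ELT(strings, s));
    long m = (long)LENGTH(STRING_ELT(strings, s));
    buf.assign((size_t)m, ' ');
    for (long i = 0; i < m; ++i) {
      unsigned char c = tab[(unsigned char)x[m - 1 - i]];
      if (!c) stop("symbol '%c' has no declared complement", x[m - 1 - i]);
      buf[i] = (char)c;
    }
    out[s] = buf;
  }
  return out;
}
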