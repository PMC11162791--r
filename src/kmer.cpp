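#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// 2-bit encoding A=0, C=1, G=2, U=3; k-mer code is big-endian so that
// lexicographic order of sequences equals numeric order of codes.
// Codes cross the R boundary as doubles (exact for k <= 16 < 2^53).

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': return 3;
    default: return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'U'};

// [[Rcpp::export]]
NumericVector window_codes(std::string seq, int k) {
  int n = (int) seq.size();
  if (k < 1 || k > 16) stop("k must be in 1..16");
  if (n < k) return NumericVector(0);
  NumericVector out(n - k + 1);
  int64_t code = 0, mask = ((int64_t)1 << (2 * k)) - 1;
  int valid = 0;  // length of current run of valid bases
  for (int i = 0; i < n; ++i) {
    int b = base_code(seq[i]);
    if (b < 0) { valid = 0; code = 0; }
    else { code = ((code << 2) | b) & mask; valid++; }
    if (i >= k - 1) out[i - k + 1] = (valid >= k) ? (double)code : NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector decode_kmers(NumericVector codes, int k) {
  CharacterVector out(codes.size());
  std::string buf(k, 'A');
  for (int i = 0; i < codes.size(); ++i) {
    if (NumericVector::is_na(codes[i])) { out[i] = NA_STRING; continue; }
    int64_t c = (int64_t) codes[i];
    for (int p = k - 1; p >= 0; --p) { buf[p] = BASES[c & 3]; c >>= 2; }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector encode_kmers(CharacterVector seqs) {
  NumericVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() > 16) stop("k must be <= 16");
    int64_t code = 0;
    bool ok = true;
    for (size_t p = 0; p < s.size(); ++p) {
      int b = base_code(s[p]);
      if (b < 0) { ok = false; break; }
      code = (code << 2) | b;
    }
    out[i] = ok ? (double)code : NA_REAL;
  }
  return out;
}

// enumerate codes at Hamming distance exactly d from `code`, positions
// chosen ascending starting at `minpos`; calls f for each
template <typename F>
static void enum_exact(int64_t code, int k, int d, int minpos, F f) {
  if (d == 0) { f(code); return; }
  for (int pos = minpos; pos <= k - d; ++pos) {
    int shift = 2 * (k - 1 - pos);
    int64_t orig = (code >> shift) & 3;
    for (int64_t sub = 0; sub < 4; ++sub) {
      if (sub == orig) continue;
      int64_t mutated = (code & ~((int64_t)3 << shift)) | (sub << shift);
      enum_exact(mutated, k, d - 1, pos + 1, f);
    }
  }
}

// [[Rcpp::export]]
NumericVector neighbor_codes(double code_, int k, int v) {
  if (v < 0 || v > 3) stop("v must be in 0..3");
  int64_t code = (int64_t) code_;
  std::vector<double> out;
  for (int d = 0; d <= v; ++d)
    enum_exact(code, k, d, 0, [&](int64_t c) { out.push_back((double)c); });
  NumericVector res(out.begin(), out.end());
  return res;
}

static inline void set_bit(Rbyte* bits, int64_t idx) {
  bits[idx >> 3] |= (Rbyte)(1u << (idx & 7));
}

static inline bool get_bit(const Rbyte* bits, int64_t idx) {
  return (bits[idx >> 3] >> (idx & 7)) & 1u;
}

// mark the Hamming-<=v ball of every (non-NA) code into the bitset
// [[Rcpp::export]]
void mark_ball(RawVector bits, NumericVector codes, int k, int v) {
  if (v < 0 || v > 3) stop("v must be in 0..3");
  Rbyte* b = bits.begin();
  int64_t total = (int64_t)1 << (2 * k);
  if ((int64_t)bits.size() * 8 < total) stop("bitset too small for k");
  for (int i = 0; i < codes.size(); ++i) {
    if (NumericVector::is_na(codes[i])) continue;
    int64_t code = (int64_t) codes[i];
    for (int d = 0; d <= v; ++d)
      enum_exact(code, k, d, 0, [&](int64_t c) { set_bit(b, c); });
  }
}

// [[Rcpp::export]]
double bitset_count(RawVector bits, double total_) {
  int64_t total = (int64_t) total_;
  const Rbyte* b = bits.begin();
  int64_t full = total >> 3, cnt = 0;
  for (int64_t i = 0; i < full; ++i) {
    Rbyte x = b[i];
    while (x) { cnt += x & 1; x >>= 1; }
  }
  for (int64_t idx = full << 3; idx < total; ++idx)
    if (get_bit(b, idx)) cnt++;
  return (double) cnt;
}

// extract up to `limit` indices (ascending) whose bit equals `marked`,
// taking every `stride`-th qualifying index so a capped extraction still
// spreads deterministically across the whole space
// [[Rcpp::export]]
NumericVector bitset_extract(RawVector bits, double total_, double limit_,
                             bool marked, double stride_ = 1) {
  int64_t total = (int64_t) total_;
  int64_t limit = (int64_t) limit_;
  int64_t stride = stride_ < 1 ? 1 : (int64_t) stride_;
  const Rbyte* b = bits.begin();
  std::vector<double> out;
  int64_t seen = 0;
  for (int64_t idx = 0; idx < total && (int64_t)out.size() < limit; ++idx) {
    if (get_bit(b, idx) == marked) {
      if (seen % stride == 0) out.push_back((double)idx);
      seen++;
    }
  }
  return NumericVector(out.begin(), out.end());
}

// total multiplicity of `queries` (unique codes) within `sorted` (sorted,
// with duplicates)
// [[Rcpp::export]]
double count_codes_in_sorted(NumericVector sorted, NumericVector queries) {
  double total = 0;
  for (int i = 0; i < queries.size(); ++i) {
    const double* lo = std::lower_bound(sorted.begin(), sorted.end(), queries[i]);
    const double* hi = std::upper_bound(sorted.begin(), sorted.end(), queries[i]);
    total += (double)(hi - lo);
  }
  return total;
}

// minimum Hamming distance between `pattern` and every length-|pattern|
// window of `text`; also returns the 0-based offset of the best window
// [[Rcpp::export]]
List min_hamming_window(std::string pattern, std::string text) {
  int m = (int) pattern.size(), n = (int) text.size();
  if (m > n) stop("pattern longer than text");
  int best = m + 1, best_off = -1;
  for (int off = 0; off + m <= n; ++off) {
    int d = 0;
    for (int i = 0; i < m && d < best; ++i)
      if (pattern[i] != text[off + i]) d++;
    if (d < best) { best = d; best_off = off; }
  }
  return List::create(_["min_mm"] = best, _["offset"] = best_off);
}
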