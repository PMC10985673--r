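// 2-bit packed k-mer codec and bit-level primitives.
//
// A k-mer (k <= 32) is packed into a 64-bit word with base 0 in the two
// lowest-order bits, code A=00 C=01 G=10 T=11.  At the R boundary the word
// travels as two doubles (hi, lo), each holding an exact unsigned 32-bit
// half, because R has no native 64-bit integer vector.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char BASE_CHR[4] = {'A', 'C', 'G', 'T'};

uint64_t hl2u(double hi, double lo) {
  return ((uint64_t)(uint32_t)hi << 32) | (uint64_t)(uint32_t)lo;
}

void u2hl(uint64_t x, double *hi, double *lo) {
  *hi = (double)(uint32_t)(x >> 32);
  *lo = (double)(uint32_t)(x & 0xFFFFFFFFULL);
}

static List make_hl(const std::vector<uint64_t> &xs) {
  int n = xs.size();
  NumericVector hi(n), lo(n);
  for (int i = 0; i < n; ++i) u2hl(xs[i], &hi[i], &lo[i]);
  return List::create(_["hi"] = hi, _["lo"] = lo);
}

// encode one k-mer; returns -1 on ambiguous base, else 0 and fills *out
static int encode_one(const char *s, int k, uint64_t *out) {
  uint64_t x = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return -1;
    x |= (uint64_t)c << (2 * i);
  }
  *out = x;
  return 0;
}

// reverse complement of a packed k-mer: complement is bitwise NOT
// (A<->T is 00<->11, C<->G is 01<->10), then reverse the 2-bit groups
static uint64_t revcomp_u(uint64_t x, int k) {
  x = ~x;
  x = ((x >> 2) & 0x3333333333333333ULL) | ((x & 0x3333333333333333ULL) << 2);
  x = ((x >> 4) & 0x0F0F0F0F0F0F0F0FULL) | ((x & 0x0F0F0F0F0F0F0F0FULL) << 4);
  x = ((x >> 8) & 0x00FF00FF00FF00FFULL) | ((x & 0x00FF00FF00FF00FFULL) << 8);
  x = ((x >> 16) & 0x0000FFFF0000FFFFULL) | ((x & 0x0000FFFF0000FFFFULL) << 16);
  x = (x >> 32) | (x << 32);
  return x >> (64 - 2 * k);
}

// lexicographic comparison of two packed k-mers as strings (base 0 first);
// the 2-bit codes are in alphabetical order so per-base code comparison
// equals character comparison
static bool lex_less(uint64_t a, uint64_t b, int k) {
  for (int i = 0; i < k; ++i) {
    int ca = (a >> (2 * i)) & 3, cb = (b >> (2 * i)) & 3;
    if (ca != cb) return ca < cb;
  }
  return false;
}

static uint64_t canonical_u(uint64_t x, int k) {
  uint64_t rc = revcomp_u(x, k);
  return lex_less(rc, x, k) ? rc : x;
}

static int hamming_u(uint64_t x, uint64_t y) {
  uint64_t d = x ^ y;
  d = (d | (d >> 1)) & 0x5555555555555555ULL;
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(d);
#else
  int n = 0;
  while (d) { d &= d - 1; ++n; }
  return n;
#endif
}

// [[Rcpp::export]]
List cpp_encode(CharacterVector seqs, int k) {
  int n = seqs.size();
  std::vector<uint64_t> out(n);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    if ((int)strlen(s) != k)
      stop("sequence %d has length %d, expected k = %d", i + 1, (int)strlen(s), k);
    if (encode_one(s, k, &out[i]) < 0)
      stop("ambiguous base in sequence %d", i + 1);
  }
  return make_hl(out);
}

// [[Rcpp::export]]
CharacterVector cpp_decode(NumericVector hi, NumericVector lo, int k) {
  int n = hi.size();
  CharacterVector out(n);
  std::string buf(k, 'A');
  for (int i = 0; i < n; ++i) {
    uint64_t x = hl2u(hi[i], lo[i]);
    for (int j = 0; j < k; ++j) buf[j] = BASE_CHR[(x >> (2 * j)) & 3];
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_revcomp(NumericVector hi, NumericVector lo, int k) {
  int n = hi.size();
  std::vector<uint64_t> out(n);
  for (int i = 0; i < n; ++i) out[i] = revcomp_u(hl2u(hi[i], lo[i]), k);
  return make_hl(out);
}

// [[Rcpp::export]]
List cpp_canonical(NumericVector hi, NumericVector lo, int k) {
  int n = hi.size();
  std::vector<uint64_t> out(n);
  for (int i = 0; i < n; ++i) out[i] = canonical_u(hl2u(hi[i], lo[i]), k);
  return make_hl(out);
}

// [[Rcpp::export]]
IntegerVector cpp_hamming(NumericVector hi1, NumericVector lo1,
                          NumericVector hi2, NumericVector lo2) {
  int n = hi1.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = hamming_u(hl2u(hi1[i], lo1[i]), hl2u(hi2[i], lo2[i]));
  return out;
}

// Extract a table's hash row: concatenation of the 2-bit symbols at the
// h sampled base positions (0-based, in list order), symbol j landing at
// bits [2j, 2j+1] of the row index.
// [[Rcpp::export]]
NumericVector cpp_table_hash(NumericVector hi, NumericVector lo,
                             IntegerVector positions) {
  int n = hi.size(), h = positions.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    uint64_t x = hl2u(hi[i], lo[i]), row = 0;
    for (int j = 0; j < h; ++j)
      row |= ((x >> (2 * positions[j])) & 3ULL) << (2 * j);
    out[i] = (double)row;
  }
  return out;
}

// Turn reads into canonical k-mer streams.  Windows containing a non-ACGT
// character are skipped.  With minimizer_window = w > k, each canonical
// w-mer is reduced to its lexicographically smallest k-mer substring and
// consecutive duplicates are collapsed.
// [[Rcpp::export]]
List cpp_reads_to_kmers(CharacterVector reads, int k, int minimizer_window) {
  std::vector<uint64_t> kms;
  std::vector<int> read_idx;
  int w = minimizer_window > 0 ? minimizer_window : k;
  if (w < k) stop("minimizer window must be >= k");
  for (int r = 0; r < reads.size(); ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int n = strlen(s);
    if (n < w) continue;
    // prefix of valid (ACGT) run lengths ending at each position
    std::vector<int> run(n);
    for (int i = 0; i < n; ++i)
      run[i] = base_code(s[i]) >= 0 ? (i > 0 ? run[i - 1] + 1 : 1) : 0;
    uint64_t last = 0;
    bool have_last = false;
    for (int i = 0; i + w <= n; ++i) {
      if (run[i + w - 1] < w) continue;  // window touches an ambiguous base
      if (w == k) {
        uint64_t xw;
        encode_one(s + i, w, &xw);
        kms.push_back(canonical_u(xw, k));
        read_idx.push_back(r + 1);
      } else {
        // windows longer than 32 bases exceed the 64-bit packing, so the
        // canonical w-mer and its smallest k-substring are computed on
        // characters (uppercased)
        std::string win(s + i, s + i + w);
        for (int j = 0; j < w; ++j) win[j] = BASE_CHR[base_code(win[j])];
        std::string rc(w, 'A');
        for (int j = 0; j < w; ++j) {
          switch (win[w - 1 - j]) {
            case 'A': rc[j] = 'T'; break;
            case 'C': rc[j] = 'G'; break;
            case 'G': rc[j] = 'C'; break;
            default:  rc[j] = 'A'; break;
          }
        }
        const std::string &cw = rc < win ? rc : win;
        size_t best_off = 0;
        for (int off = 1; off + k <= w; ++off)
          if (cw.compare(off, k, cw, best_off, k) < 0) best_off = off;
        uint64_t best;
        encode_one(cw.c_str() + best_off, k, &best);
        if (!have_last || best != last) {
          kms.push_back(best);
          read_idx.push_back(r + 1);
          last = best;
          have_last = true;
        }
      }
    }
    have_last = false;
  }
  List out = make_hl(kms);
  out["read"] = IntegerVector(read_idx.begin(), read_idx.end());
  return out;
}
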