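// Bit-sampling LSH index over packed reference k-mers.
//
// l fixed-size hash tables of 2^(2h) rows x b slots hold 1-based pointers
// into the append-only encoding array K.  Bucket overflow is resolved by
// per-row reservoir sampling so retention is unbiased by insertion order.
// Each K entry carries a 2-byte-range soft-LCA taxon label (0 = unassigned)
// and a genome-occurrence count Ni.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

uint64_t hl2u(double hi, double lo);          // codec.cpp
void u2hl(uint64_t x, double *hi, double *lo);

struct LshIndexCpp {
  int k, h, l, b, p, dmax;
  std::vector<std::vector<int> > pos;        // l tables x h 0-based positions
  std::vector<uint64_t> K;
  std::vector<int32_t> labels;               // internal taxon ids, 0 = none
  std::vector<int32_t> counts;               // Ni
  std::vector<std::vector<int32_t> > tables; // nrow*b slots, 0 = empty
  std::vector<std::vector<int32_t> > attempts; // per-row insert attempts
  std::unordered_map<uint64_t, int32_t> kmap;  // kmer -> 1-based K index
  int64_t nrow;

  int64_t hash_row(uint64_t x, int t) const {
    uint64_t row = 0;
    const std::vector<int> &ps = pos[t];
    for (int j = 0; j < h; ++j)
      row |= ((x >> (2 * ps[j])) & 3ULL) << (2 * j);
    return (int64_t)row;
  }
};

static LshIndexCpp *get_index(SEXP xp) {
  Rcpp::XPtr<LshIndexCpp> p(xp);
  return p.get();
}

// [[Rcpp::export]]
SEXP cpp_index_new(int k, int h, int l, int b, int p, int dmax,
                   IntegerMatrix positions) {
  if (positions.nrow() != l || positions.ncol() != h)
    stop("positions must be an l x h matrix");
  LshIndexCpp *idx = new LshIndexCpp();
  idx->k = k; idx->h = h; idx->l = l; idx->b = b; idx->p = p; idx->dmax = dmax;
  idx->nrow = (int64_t)1 << (2 * h);
  idx->pos.resize(l);
  for (int t = 0; t < l; ++t) {
    idx->pos[t].resize(h);
    for (int j = 0; j < h; ++j) idx->pos[t][j] = positions(t, j);
  }
  idx->tables.assign(l, std::vector<int32_t>(idx->nrow * b, 0));
  idx->attempts.assign(l, std::vector<int32_t>(idx->nrow, 0));
  return Rcpp::XPtr<LshIndexCpp>(idx, true);
}

// [[Rcpp::export]]
LogicalVector cpp_index_insert(SEXP xp, NumericVector hi, NumericVector lo) {
  LshIndexCpp *idx = get_index(xp);
  int n = hi.size();
  LogicalVector added(n);
  for (int i = 0; i < n; ++i) {
    uint64_t x = hl2u(hi[i], lo[i]);
    if (idx->kmap.count(x)) { added[i] = false; continue; }
    idx->K.push_back(x);
    idx->labels.push_back(0);
    idx->counts.push_back(0);
    int32_t ptr = (int32_t)idx->K.size();
    idx->kmap[x] = ptr;
    for (int t = 0; t < idx->l; ++t) {
      int64_t row = idx->hash_row(x, t);
      int32_t *slots = &idx->tables[t][row * idx->b];
      int32_t m = ++idx->attempts[t][row];
      if (m <= idx->b) {
        slots[m - 1] = ptr;
      } else if (unif_rand() * m < idx->b) {
        int j = (int)(unif_rand() * idx->b);
        if (j >= idx->b) j = idx->b - 1;
        slots[j] = ptr;
      }
    }
    added[i] = true;
  }
  return added;
}

static int hamming_u64(uint64_t x, uint64_t y) {
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

// Best match per query k-mer: candidates from the l rows are deduplicated
// by K index, the true Hamming distance is computed for each, and the
// minimum-distance candidate (ties: smallest K index) is returned when its
// distance is <= dmax.  NA elements mean no match.
// [[Rcpp::export]]
List cpp_index_lookup(SEXP xp, NumericVector hi, NumericVector lo, int dmax) {
  LshIndexCpp *idx = get_index(xp);
  int n = hi.size();
  IntegerVector ref(n, NA_INTEGER), dist(n, NA_INTEGER), lab(n, NA_INTEGER);
  std::vector<int32_t> cand;
  cand.reserve(idx->b * idx->l);
  for (int i = 0; i < n; ++i) {
    uint64_t x = hl2u(hi[i], lo[i]);
    cand.clear();
    for (int t = 0; t < idx->l; ++t) {
      int64_t row = idx->hash_row(x, t);
      const int32_t *slots = &idx->tables[t][row * idx->b];
      for (int j = 0; j < idx->b; ++j) {
        int32_t ptr = slots[j];
        if (!ptr) continue;
        bool seen = false;
        for (size_t c = 0; c < cand.size(); ++c)
          if (cand[c] == ptr) { seen = true; break; }
        if (!seen) cand.push_back(ptr);
      }
    }
    int best_d = idx->k + 1;
    int32_t best_ptr = 0;
    for (size_t c = 0; c < cand.size(); ++c) {
      int d = hamming_u64(x, idx->K[cand[c] - 1]);
      if (d < best_d || (d == best_d && cand[c] < best_ptr)) {
        best_d = d;
        best_ptr = cand[c];
      }
    }
    if (best_ptr && best_d <= dmax) {
      ref[i] = best_ptr;
      dist[i] = best_d;
      lab[i] = idx->labels[best_ptr - 1];
    }
  }
  return List::create(_["ref_index"] = ref, _["distance"] = dist,
                      _["taxon"] = lab);
}

// Increment Ni for every distinct stored k-mer occurring in one genome.
// [[Rcpp::export]]
int cpp_index_count_genome(SEXP xp, NumericVector hi, NumericVector lo) {
  LshIndexCpp *idx = get_index(xp);
  std::unordered_set<uint64_t> seen;
  int n = hi.size(), counted = 0;
  for (int i = 0; i < n; ++i) {
    uint64_t x = hl2u(hi[i], lo[i]);
    if (!seen.insert(x).second) continue;
    std::unordered_map<uint64_t, int32_t>::iterator it = idx->kmap.find(x);
    if (it != idx->kmap.end()) { ++idx->counts[it->second - 1]; ++counted; }
  }
  return counted;
}

// splitmix64 finalizer: deterministic per-(seed, k-mer, genome) coin
static uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static uint64_t fnv1a(const char *s) {
  uint64_t hsh = 0xCBF29CE484222325ULL;
  for (; *s; ++s) { hsh ^= (uint64_t)(unsigned char)*s; hsh *= 0x100000001B3ULL; }
  return hsh;
}

static int lca_walk(int a, int b, const IntegerVector &parent,
                    const std::vector<int> &depth) {
  while (depth[a - 1] > depth[b - 1]) a = parent[a - 1];
  while (depth[b - 1] > depth[a - 1]) b = parent[b - 1];
  while (a != b) { a = parent[a - 1]; b = parent[b - 1]; }
  return a;
}

// Soft-LCA update pass for one genome: each distinct stored k-mer flips a
// deterministic coin with success probability
//   pu(Ni) = min(w / max(Ni + w - s, w) + 1/s^2, 1)
// and on success its label moves to LCA(label, species); label 0 acts as
// the identity.  The coin depends only on (seed, k-mer, genome id), so the
// final label set is invariant to genome processing order.
// [[Rcpp::export]]
int cpp_index_soft_lca_genome(SEXP xp, NumericVector hi, NumericVector lo,
                              int species, IntegerVector parent,
                              double w, double s, double seed,
                              std::string genome_id) {
  LshIndexCpp *idx = get_index(xp);
  int n_tax = parent.size();
  std::vector<int> depth(n_tax, -1);
  for (int i = 0; i < n_tax; ++i) {
    int d = 0, a = i + 1;
    while (parent[a - 1] != 0) { a = parent[a - 1]; ++d; }
    depth[i] = d;
  }
  uint64_t gkey = mix64(fnv1a(genome_id.c_str()));
  uint64_t skey = mix64((uint64_t)seed);
  double inv_s2 = 1.0 / (s * s);
  std::unordered_set<uint64_t> seen;
  int n = hi.size(), updated = 0;
  for (int i = 0; i < n; ++i) {
    uint64_t x = hl2u(hi[i], lo[i]);
    if (!seen.insert(x).second) continue;
    std::unordered_map<uint64_t, int32_t>::iterator it = idx->kmap.find(x);
    if (it == idx->kmap.end()) continue;
    int32_t ki = it->second - 1;
    double ni = (double)idx->counts[ki];
    double denom = ni + w - s > w ? ni + w - s : w;
    double pu = w / denom + inv_s2;
    if (pu > 1.0) pu = 1.0;
    double u = (double)(mix64(skey ^ mix64(x) ^ gkey) >> 11) *
               (1.0 / 9007199254740992.0);
    if (u < pu) {
      int32_t cur = idx->labels[ki];
      idx->labels[ki] = cur == 0 ? species
                                 : lca_walk(cur, species, parent, depth);
      ++updated;
    }
  }
  return updated;
}

// [[Rcpp::export]]
int cpp_index_size(SEXP xp) { return (int)get_index(xp)->K.size(); }

// [[Rcpp::export]]
List cpp_index_kmers(SEXP xp, IntegerVector at) {
  LshIndexCpp *idx = get_index(xp);
  int n = at.size();
  NumericVector hi(n), lo(n);
  for (int i = 0; i < n; ++i) {
    int j = at[i];
    if (j < 1 || j > (int)idx->K.size()) stop("K index out of range");
    u2hl(idx->K[j - 1], &hi[i], &lo[i]);
  }
  return List::create(_["hi"] = hi, _["lo"] = lo);
}

// [[Rcpp::export]]
IntegerVector cpp_index_labels(SEXP xp) {
  LshIndexCpp *idx = get_index(xp);
  return IntegerVector(idx->labels.begin(), idx->labels.end());
}

// [[Rcpp::export]]
void cpp_index_set_labels(SEXP xp, IntegerVector labels) {
  LshIndexCpp *idx = get_index(xp);
  if ((size_t)labels.size() != idx->labels.size())
    stop("labels length must equal |K|");
  for (int i = 0; i < labels.size(); ++i) idx->labels[i] = labels[i];
}

// [[Rcpp::export]]
IntegerVector cpp_index_counts(SEXP xp) {
  LshIndexCpp *idx = get_index(xp);
  return IntegerVector(idx->counts.begin(), idx->counts.end());
}

// [[Rcpp::export]]
void cpp_index_set_counts(SEXP xp, IntegerVector counts) {
  LshIndexCpp *idx = get_index(xp);
  if ((size_t)counts.size() != idx->counts.size())
    stop("counts length must equal |K|");
  for (int i = 0; i < counts.size(); ++i) idx->counts[i] = counts[i];
}

// Full structural export for serialization; kmap is rebuilt on import.
// [[Rcpp::export]]
List cpp_index_export(SEXP xp) {
  LshIndexCpp *idx = get_index(xp);
  int n = idx->K.size();
  NumericVector hi(n), lo(n);
  for (int i = 0; i < n; ++i) u2hl(idx->K[i], &hi[i], &lo[i]);
  IntegerMatrix positions(idx->l, idx->h);
  for (int t = 0; t < idx->l; ++t)
    for (int j = 0; j < idx->h; ++j) positions(t, j) = idx->pos[t][j];
  List tables(idx->l), attempts(idx->l);
  for (int t = 0; t < idx->l; ++t) {
    tables[t] = IntegerVector(idx->tables[t].begin(), idx->tables[t].end());
    attempts[t] =
        IntegerVector(idx->attempts[t].begin(), idx->attempts[t].end());
  }
  return List::create(
      _["k"] = idx->k, _["h"] = idx->h, _["l"] = idx->l, _["b"] = idx->b,
      _["p"] = idx->p, _["dmax"] = idx->dmax, _["positions"] = positions,
      _["K_hi"] = hi, _["K_lo"] = lo,
      _["labels"] = IntegerVector(idx->labels.begin(), idx->labels.end()),
      _["counts"] = IntegerVector(idx->counts.begin(), idx->counts.end()),
      _["tables"] = tables, _["attempts"] = attempts);
}

// [[Rcpp::export]]
SEXP cpp_index_import(List st) {
  int k = st["k"], h = st["h"], l = st["l"], b = st["b"];
  int p = st["p"], dmax = st["dmax"];
  IntegerMatrix positions = st["positions"];
  SEXP xp = cpp_index_new(k, h, l, b, p, dmax, positions);
  LshIndexCpp *idx = get_index(xp);
  NumericVector hi = st["K_hi"], lo = st["K_lo"];
  IntegerVector labels = st["labels"], counts = st["counts"];
  int n = hi.size();
  idx->K.resize(n);
  idx->labels.resize(n);
  idx->counts.resize(n);
  for (int i = 0; i < n; ++i) {
    idx->K[i] = hl2u(hi[i], lo[i]);
    idx->labels[i] = labels[i];
    idx->counts[i] = counts[i];
    idx->kmap[idx->K[i]] = i + 1;
  }
  List tables = st["tables"], attempts = st["attempts"];
  for (int t = 0; t < l; ++t) {
    IntegerVector tv = tables[t], av = attempts[t];
    std::copy(tv.begin(), tv.end(), idx->tables[t].begin());
    std::copy(av.begin(), av.end(), idx->attempts[t].begin());
  }
  return xp;
}
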