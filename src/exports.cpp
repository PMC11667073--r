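#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cmath>
#include "bqf_core.h"

using namespace Rcpp;
using bqfcore::BQF;

// ======================================================== hashing / codec

// [[Rcpp::export(name = ".encode_smer_cpp")]]
NumericVector encode_smer_cpp(CharacterVector seqs) {
  R_xlen_t m = seqs.size();
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    const char* p = CHAR(STRING_ELT(seqs, i));
    int len = (int)LENGTH(STRING_ELT(seqs, i));
    uint64_t code;
    long long bad = bqfcore::encode_dna(p, len, code);
    if (bad >= 0)
      stop("non-ACGT character at position %d of sequence %d", (int)bad + 1, (int)i + 1);
    out[i] = (double)code;
  }
  return out;
}

// [[Rcpp::export(name = ".decode_smer_cpp")]]
CharacterVector decode_smer_cpp(NumericVector codes, int s) {
  R_xlen_t m = codes.size();
  CharacterVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    double v = codes[i];
    if (v < 0 || v >= std::ldexp(1.0, 2 * s))
      stop("code %g out of range [0, 4^s) for s = %d", v, s);
    out[i] = bqfcore::decode_dna((uint64_t)v, s);
  }
  return out;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  R_xlen_t m = seqs.size();
  CharacterVector out(m);
  std::string buf;
  for (R_xlen_t i = 0; i < m; ++i) {
    const char* p = CHAR(STRING_ELT(seqs, i));
    int len = (int)LENGTH(STRING_ELT(seqs, i));
    buf.assign(len, 'A');
    for (int j = 0; j < len; ++j) {
      int b = bqfcore::base_code(p[len - 1 - j]);
      if (b < 0) stop("non-ACGT character at position %d of sequence %d", len - j, (int)i + 1);
      buf[j] = bqfcore::code_base(3 - b);
    }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export(name = ".canonical_cpp")]]
CharacterVector canonical_cpp(CharacterVector seqs) {
  R_xlen_t m = seqs.size();
  CharacterVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    const char* p = CHAR(STRING_ELT(seqs, i));
    int len = (int)LENGTH(STRING_ELT(seqs, i));
    uint64_t code;
    long long bad = bqfcore::encode_dna(p, len, code);
    if (bad >= 0)
      stop("non-ACGT character at position %d of sequence %d", (int)bad + 1, (int)i + 1);
    out[i] = bqfcore::decode_dna(bqfcore::canonical_code(code, len), len);
  }
  return out;
}

// [[Rcpp::export(name = ".hash2s_cpp")]]
NumericVector hash2s_cpp(NumericVector x, int s) {
  R_xlen_t m = x.size();
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i)
    out[i] = (double)bqfcore::hash_2s((uint64_t)x[i], s);
  return out;
}

// [[Rcpp::export(name = ".unhash2s_cpp")]]
NumericVector unhash2s_cpp(NumericVector y, int s) {
  R_xlen_t m = y.size();
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i)
    out[i] = (double)bqfcore::unhash_2s((uint64_t)y[i], s);
  return out;
}

// full-width round-trip check usable beyond double precision (s up to 31)
// [[Rcpp::export(name = ".hash_roundtrip_cpp")]]
bool hash_roundtrip_cpp(int s, int n, double seed) {
  bqfcore::SplitMix rng((uint64_t)seed);
  uint64_t m = bqfcore::width_mask(2 * s);
  for (int i = 0; i < n; ++i) {
    uint64_t x = rng.next() & m;
    if (bqfcore::unhash_2s(bqfcore::hash_2s(x, s), s) != x) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".hash_fingerprint_cpp")]]
double hash_fingerprint_cpp() {
  // header fingerprint, folded to stay exactly representable in a double
  return (double)(bqfcore::hash_fingerprint() >> 12);
}

// ================================================= plain bitvector rank/select

// [[Rcpp::export(name = ".rank_bits_cpp")]]
int rank_bits_cpp(LogicalVector v, int i) {
  if (i < 0 || i >= v.size()) stop("index out of range");
  int cnt = 0;
  for (int t = 0; t <= i; ++t) cnt += (v[t] == TRUE);
  return cnt;
}

// [[Rcpp::export(name = ".select_bits_cpp")]]
int select_bits_cpp(LogicalVector v, int j) {
  if (j < 1) stop("j must be >= 1");
  int seen = 0;
  for (int t = 0; t < v.size(); ++t) {
    if (v[t] == TRUE && ++seen == j) return t;
  }
  return -1;  // fewer than j set bits
}

// ===================================================== filter construction

// [[Rcpp::export(name = ".bqf_new_cpp")]]
SEXP bqf_new_cpp(int q, int s, int k, int c, bool canonical, int mode) {
  BQF* f = new BQF(q, s, k, c, canonical, mode);
  XPtr<BQF> ptr(f, true);
  return ptr;
}

static BQF* get(SEXP xp) {
  XPtr<BQF> ptr(xp);
  if (!ptr) stop("invalid filter pointer");
  return ptr.get();
}

// [[Rcpp::export(name = ".bqf_params_cpp")]]
List bqf_params_cpp(SEXP xp) {
  BQF* f = get(xp);
  return List::create(
      _["q"] = f->q, _["r"] = f->r, _["c"] = f->c, _["k"] = f->k, _["s"] = f->s,
      _["n"] = (double)f->n, _["canonical"] = f->canon, _["counter_mode"] = f->mode,
      _["n_slots"] = (double)f->N, _["n_blocks"] = (double)f->nwords,
      _["size_bits"] = (double)f->size_bits(), _["load_factor"] = f->load_factor());
}

// ======================================================== element-level ops

static uint64_t code_to_hash(const BQF* f, double code) {
  return bqfcore::hash_2s((uint64_t)code, f->s);
}

// [[Rcpp::export(name = ".bqf_insert_codes_cpp")]]
void bqf_insert_codes_cpp(SEXP xp, NumericVector codes, NumericVector counts) {
  BQF* f = get(xp);
  if (codes.size() != counts.size()) stop("codes and counts differ in length");
  for (R_xlen_t i = 0; i < codes.size(); ++i)
    f->insert(code_to_hash(f, codes[i]), (uint64_t)counts[i]);
}

// [[Rcpp::export(name = ".bqf_query_codes_cpp")]]
NumericVector bqf_query_codes_cpp(SEXP xp, NumericVector codes) {
  BQF* f = get(xp);
  NumericVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i)
    out[i] = (double)f->query_stored(code_to_hash(f, codes[i]));
  return out;
}

// [[Rcpp::export(name = ".bqf_delete_codes_cpp")]]
LogicalVector bqf_delete_codes_cpp(SEXP xp, NumericVector codes) {
  BQF* f = get(xp);
  LogicalVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i)
    out[i] = f->erase(code_to_hash(f, codes[i]));
  return out;
}

// insert pre-counted s-mers (strings); duplicates are merged on raw counts
// before encoding; returns the number of distinct records inserted
// [[Rcpp::export(name = ".bqf_insert_smer_counts_cpp")]]
double bqf_insert_smer_counts_cpp(SEXP xp, CharacterVector smers, NumericVector counts,
                                  double min_count) {
  BQF* f = get(xp);
  if (smers.size() != counts.size()) stop("records malformed");
  std::unordered_map<uint64_t, uint64_t> agg;
  agg.reserve((size_t)smers.size() * 2);
  bool dup = false;
  for (R_xlen_t i = 0; i < smers.size(); ++i) {
    const char* p = CHAR(STRING_ELT(smers, i));
    int len = (int)LENGTH(STRING_ELT(smers, i));
    if (len != f->s)
      stop("record %d: s-mer length %d does not match s = %d", (int)i + 1, len, f->s);
    uint64_t code;
    long long bad = bqfcore::encode_dna(p, len, code);
    if (bad >= 0)
      stop("record %d: non-ACGT character at position %d", (int)i + 1, (int)bad + 1);
    if (f->canon) code = bqfcore::canonical_code(code, len);
    auto it = agg.find(code);
    if (it == agg.end()) agg[code] = (uint64_t)counts[i];
    else { it->second += (uint64_t)counts[i]; dup = true; }
  }
  if (dup) warning("duplicate s-mers in input; their counts were merged");
  std::vector<std::pair<uint64_t, uint64_t>> recs(agg.begin(), agg.end());
  std::sort(recs.begin(), recs.end());
  double kept = 0;
  for (const auto& pr : recs) {
    if ((double)pr.second < min_count) continue;
    f->insert(bqfcore::hash_2s(pr.first, f->s), pr.second);
    kept += 1;
  }
  return kept;
}

// [[Rcpp::export(name = ".bqf_enumerate_cpp")]]
List bqf_enumerate_cpp(SEXP xp) {
  BQF* f = get(xp);
  std::vector<bqfcore::Element> els = f->enumerate();
  R_xlen_t m = (R_xlen_t)els.size();
  CharacterVector smer(m);
  NumericVector stored(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    uint64_t code = bqfcore::unhash_2s(els[i].hash, f->s);
    smer[i] = bqfcore::decode_dna(code, f->s);
    stored[i] = (double)els[i].stored;
  }
  return List::create(_["smer"] = smer, _["stored"] = stored);
}

// [[Rcpp::export(name = ".bqf_resize_cpp")]]
void bqf_resize_cpp(SEXP xp) { get(xp)->resize(); }

// [[Rcpp::export(name = ".bqf_validate_cpp")]]
bool bqf_validate_cpp(SEXP xp) {
  get(xp)->validate();
  return true;
}

// ================================================ runend position (two routes)

// block-offset route (the operational implementation)
// [[Rcpp::export(name = ".bqf_runend_cpp")]]
double bqf_runend_cpp(SEXP xp, double slot) {
  BQF* f = get(xp);
  uint64_t i = (uint64_t)slot;
  if (i >= f->N) stop("slot out of range");
  if (!BQF::get_bit(f->occ, i)) return -1;
  return (double)f->md(f->runend_of(i));
}

// naive global route: finds an empty anchor by exhaustively testing walk
// consistency, then evaluates Select(runends, Rank(occupieds, i)) in the
// rotated (linearized) coordinates; independent of the offset checkpoints
// [[Rcpp::export(name = ".bqf_runend_global_cpp")]]
double bqf_runend_global_cpp(SEXP xp, double slot) {
  BQF* f = get(xp);
  uint64_t i = (uint64_t)slot;
  if (i >= f->N) stop("slot out of range");
  if (!BQF::get_bit(f->occ, i)) return -1;
  uint64_t N = f->N;
  if (f->n >= N) return -1;
  // candidate anchors: occ == 0 && rend == 0; accept the first whose
  // pending-run walk is consistent
  for (uint64_t E = 0; E < N; ++E) {
    if (BQF::get_bit(f->occ, E) || BQF::get_bit(f->rend, E)) continue;
    uint64_t open = 0, emitted = 0;
    bool ok = true;
    for (uint64_t t = E + 1; t <= E + N && ok; ++t) {
      uint64_t x = f->md(t);
      if (BQF::get_bit(f->occ, x)) ++open;
      if (open == 0) {
        if (BQF::get_bit(f->rend, x)) ok = false;
        continue;
      }
      ++emitted;
      if (BQF::get_bit(f->rend, x)) --open;
    }
    if (!ok || open != 0 || emitted != f->n) continue;
    // rotated global formula
    uint64_t iu = (i > E) ? i : i + N;
    uint64_t d = 0;
    for (uint64_t t = E + 1; t <= iu; ++t)
      if (BQF::get_bit(f->occ, f->md(t))) ++d;
    uint64_t seen = 0;
    for (uint64_t t = E + 1; t <= E + N; ++t) {
      if (BQF::get_bit(f->rend, f->md(t))) {
        if (++seen == d) return (double)f->md(t);
      }
    }
    return -1;
  }
  stop("no consistent anchor found");
}

// ====================================================== state (serialization)

static RawVector words_to_raw(const std::vector<uint64_t>& w) {
  RawVector out((R_xlen_t)w.size() * 8);
  for (size_t i = 0; i < w.size(); ++i)
    for (int b = 0; b < 8; ++b)
      out[(R_xlen_t)i * 8 + b] = (Rbyte)((w[i] >> (8 * b)) & 0xff);  // little-endian
  return out;
}

static std::vector<uint64_t> raw_to_words(RawVector r) {
  if (r.size() % 8 != 0) stop("payload section not 64-bit aligned");
  std::vector<uint64_t> w(r.size() / 8, 0);
  for (size_t i = 0; i < w.size(); ++i)
    for (int b = 0; b < 8; ++b)
      w[i] |= (uint64_t)(unsigned char)r[(R_xlen_t)i * 8 + b] << (8 * b);
  return w;
}

// [[Rcpp::export(name = ".bqf_state_cpp")]]
List bqf_state_cpp(SEXP xp) {
  BQF* f = get(xp);
  return List::create(
      _["occupieds"] = words_to_raw(f->occ), _["runends"] = words_to_raw(f->rend),
      _["offsets"] = words_to_raw(f->off), _["slots"] = words_to_raw(f->slots));
}

// [[Rcpp::export(name = ".bqf_from_state_cpp")]]
SEXP bqf_from_state_cpp(int q, int s, int k, int c, bool canonical, int mode,
                        double n, RawVector occupieds, RawVector runends,
                        RawVector offsets, RawVector slots) {
  BQF* f = new BQF(q, s, k, c, canonical, mode);
  std::vector<uint64_t> o = raw_to_words(occupieds), re = raw_to_words(runends),
                        of = raw_to_words(offsets), sl = raw_to_words(slots);
  if (o.size() != f->occ.size() || re.size() != f->rend.size() ||
      of.size() != f->off.size() || sl.size() != f->slots.size()) {
    delete f;
    stop("payload section sizes do not match the header geometry");
  }
  f->occ = std::move(o);
  f->rend = std::move(re);
  f->off = std::move(of);
  f->slots = std::move(sl);
  f->n = (uint64_t)n;
  XPtr<BQF> ptr(f, true);
  return ptr;
}

// ===================================================== sequence-level paths

// rolling 2-bit codes of all s-length windows of seq; -1 marks windows
// containing a non-ACGT character; canonical folding optional
static void window_codes(const char* p, int L, int s, bool canon,
                         std::vector<long long>& out) {
  out.clear();
  if (L < s) return;
  out.resize(L - s + 1, -1);
  uint64_t mask = bqfcore::width_mask(2 * s);
  uint64_t fwd = 0, rc = 0;
  int valid = 0;  // length of current valid suffix
  int shift_rc = 2 * (s - 1);
  for (int i = 0; i < L; ++i) {
    int b = bqfcore::base_code(p[i]);
    if (b < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << shift_rc);
    if (++valid >= s) {
      uint64_t code = fwd;
      if (canon && rc < code) code = rc;
      out[i - s + 1] = (long long)code;
    }
  }
}

// [[Rcpp::export(name = ".count_smers_cpp")]]
List count_smers_cpp(CharacterVector reads, int s, bool canonical) {
  std::unordered_map<uint64_t, uint64_t> counts;
  std::vector<long long> codes;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* p = CHAR(STRING_ELT(reads, i));
    int L = (int)LENGTH(STRING_ELT(reads, i));
    window_codes(p, L, s, canonical, codes);
    for (long long cd : codes)
      if (cd >= 0) ++counts[(uint64_t)cd];
  }
  std::vector<std::pair<uint64_t, uint64_t>> recs(counts.begin(), counts.end());
  std::sort(recs.begin(), recs.end());
  R_xlen_t m = (R_xlen_t)recs.size();
  CharacterVector smer(m);
  NumericVector count(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    smer[i] = bqfcore::decode_dna(recs[i].first, s);
    count[i] = (double)recs[i].second;
  }
  return List::create(_["smer"] = smer, _["count"] = count);
}

// smallest q >= 6 with n / 2^q <= 0.95, capped at 2s (where the hash is
// fully consumed by the address and the load may legitimately sit higher)
static int choose_q(double n, int s) {
  int q = 6;
  while (q < 2 * s && n > 0.95 * std::ldexp(1.0, q)) ++q;
  return q;
}

static SEXP build_from_map(std::unordered_map<uint64_t, uint64_t>& counts,
                           int k, int s, int c, bool canonical, int mode,
                           double min_count, int q_user) {
  double kept = 0;
  for (const auto& pr : counts)
    if ((double)pr.second >= min_count) kept += 1;
  int q = q_user > 0 ? q_user : choose_q(kept, s);
  BQF* f = new BQF(q, s, k, c, canonical, mode);
  XPtr<BQF> ptr(f, true);
  std::vector<std::pair<uint64_t, uint64_t>> recs(counts.begin(), counts.end());
  std::sort(recs.begin(), recs.end());
  for (const auto& pr : recs) {
    if ((double)pr.second < min_count) continue;
    f->insert(bqfcore::hash_2s(pr.first, s), pr.second);
  }
  ptr.attr("n_inserted") = kept;
  return ptr;
}

// count the reads' s-mers and build a filter sized for them
// [[Rcpp::export(name = ".bqf_build_reads_cpp")]]
SEXP bqf_build_reads_cpp(CharacterVector reads, int k, int s, int c,
                         bool canonical, int mode, double min_count, int q_user) {
  std::unordered_map<uint64_t, uint64_t> counts;
  std::vector<long long> codes;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* p = CHAR(STRING_ELT(reads, i));
    int L = (int)LENGTH(STRING_ELT(reads, i));
    window_codes(p, L, s, canonical, codes);
    for (long long cd : codes)
      if (cd >= 0) ++counts[(uint64_t)cd];
  }
  return build_from_map(counts, k, s, c, canonical, mode, min_count, q_user);
}

// build from pre-counted records; duplicate s-mers merge their raw counts
// [[Rcpp::export(name = ".bqf_build_counts_cpp")]]
SEXP bqf_build_counts_cpp(CharacterVector smers, NumericVector cnts, int k, int s,
                          int c, bool canonical, int mode, double min_count,
                          int q_user) {
  if (smers.size() != cnts.size()) stop("records malformed");
  std::unordered_map<uint64_t, uint64_t> counts;
  counts.reserve((size_t)smers.size() * 2);
  bool dup = false;
  for (R_xlen_t i = 0; i < smers.size(); ++i) {
    const char* p = CHAR(STRING_ELT(smers, i));
    int len = (int)LENGTH(STRING_ELT(smers, i));
    if (len != s)
      stop("record %d: s-mer length %d does not match s = %d", (int)i + 1, len, s);
    uint64_t code;
    long long bad = bqfcore::encode_dna(p, len, code);
    if (bad >= 0)
      stop("record %d: non-ACGT character at position %d", (int)i + 1, (int)bad + 1);
    if (canonical) code = bqfcore::canonical_code(code, len);
    auto it = counts.find(code);
    if (it == counts.end()) counts[code] = (uint64_t)cnts[i];
    else { it->second += (uint64_t)cnts[i]; dup = true; }
  }
  if (dup) warning("duplicate s-mers in input; their counts were merged");
  return build_from_map(counts, k, s, c, canonical, mode, min_count, q_user);
}

// number of distinct s-mers of a read set (for s-sweeps; no filter needed)
// [[Rcpp::export(name = ".distinct_smers_cpp")]]
double distinct_smers_cpp(CharacterVector reads, int s, bool canonical,
                          double min_count) {
  std::unordered_map<uint64_t, uint64_t> counts;
  std::vector<long long> codes;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* p = CHAR(STRING_ELT(reads, i));
    int L = (int)LENGTH(STRING_ELT(reads, i));
    window_codes(p, L, s, canonical, codes);
    for (long long cd : codes)
      if (cd >= 0) ++counts[(uint64_t)cd];
  }
  double m = 0;
  for (const auto& pr : counts)
    if ((double)pr.second >= min_count) m += 1;
  return m;
}

// per-k-mer-window abundance over one sequence: sliding-window minimum over
// the stored s-mer counters, each s-mer queried exactly once; stored value
// -1 encodes "absent" and propagates through the minimum
static void query_seq_stored(const BQF* f, const char* p, int L,
                             std::vector<long long>& vals,
                             std::vector<long long>& mins) {
  int s = f->s, k = f->k;
  int z = k - s;
  mins.clear();
  if (L < k) return;
  window_codes(p, L, s, f->canon, vals);
  for (size_t i = 0; i < vals.size(); ++i)
    if (vals[i] >= 0)
      vals[i] = f->query_stored(bqfcore::hash_2s((uint64_t)vals[i], s));
  int nk = L - k + 1;
  mins.assign(nk, -1);
  std::deque<int> dq;  // indices with increasing values
  for (int i = 0; i < (int)vals.size(); ++i) {
    while (!dq.empty() && vals[dq.back()] >= vals[i]) dq.pop_back();
    dq.push_back(i);
    int w0 = i - z;  // k-mer window starting here covers s-mers [w0, i]
    if (w0 >= 0) {
      if (dq.front() < w0) dq.pop_front();
      if (w0 < nk) mins[w0] = vals[dq.front()];
    }
  }
}

// [[Rcpp::export(name = ".bqf_query_seqs_cpp")]]
List bqf_query_seqs_cpp(SEXP xp, CharacterVector seqs) {
  BQF* f = get(xp);
  List out(seqs.size());
  std::vector<long long> vals, mins;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* p = CHAR(STRING_ELT(seqs, i));
    int L = (int)LENGTH(STRING_ELT(seqs, i));
    query_seq_stored(f, p, L, vals, mins);
    NumericVector stored(mins.size());
    for (size_t j = 0; j < mins.size(); ++j) stored[j] = (double)mins[j];
    out[i] = stored;
  }
  return out;
}

// ======================================================= synthetic evaluation

// [[Rcpp::export(name = ".gen_reads_cpp")]]
CharacterVector gen_reads_cpp(double n_reads, int read_len, double seed, double gc) {
  if (read_len < 1) stop("read_len must be >= 1");
  R_xlen_t n = (R_xlen_t)n_reads;
  bqfcore::SplitMix rng((uint64_t)seed);
  double at = (1.0 - gc) / 2.0;
  CharacterVector out(n);
  std::string buf(read_len, 'A');
  for (R_xlen_t i = 0; i < n; ++i) {
    for (int j = 0; j < read_len; ++j) {
      double u = rng.unif();
      char ch;
      if (u < at) ch = 'A';
      else if (u < 2 * at) ch = 'T';
      else if (u < 2 * at + gc / 2) ch = 'C';
      else ch = 'G';
      buf[j] = ch;
    }
    out[i] = buf;
  }
  return out;
}

// distinct (canonical) k-mers of a read set, kept as an opaque truth set
// [[Rcpp::export(name = ".kmer_truth_cpp")]]
SEXP kmer_truth_cpp(CharacterVector reads, int k, bool canonical) {
  auto* truth = new std::unordered_set<uint64_t>();
  std::vector<long long> codes;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* p = CHAR(STRING_ELT(reads, i));
    int L = (int)LENGTH(STRING_ELT(reads, i));
    window_codes(p, L, k, canonical, codes);
    for (long long cd : codes)
      if (cd >= 0) truth->insert((uint64_t)cd);
  }
  XPtr<std::unordered_set<uint64_t>> ptr(truth, true);
  ptr.attr("n_kmers") = (double)truth->size();
  return ptr;
}

// [[Rcpp::export(name = ".kmer_truth_size_cpp")]]
double kmer_truth_size_cpp(SEXP xp) {
  XPtr<std::unordered_set<uint64_t>> truth(xp);
  return (double)truth->size();
}

// [[Rcpp::export(name = ".kmer_truth_has_cpp")]]
LogicalVector kmer_truth_has_cpp(SEXP xp, CharacterVector kmers, bool canonical) {
  XPtr<std::unordered_set<uint64_t>> truth(xp);
  LogicalVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* p = CHAR(STRING_ELT(kmers, i));
    int len = (int)LENGTH(STRING_ELT(kmers, i));
    uint64_t code;
    if (bqfcore::encode_dna(p, len, code) >= 0) { out[i] = false; continue; }
    if (canonical) code = bqfcore::canonical_code(code, len);
    out[i] = truth->count(code) > 0;
  }
  return out;
}

// Query n_queries k-mers taken from freshly generated random sequences and
// classify each against the truth set; returns false-positive /
// false-negative / present counts.
// [[Rcpp::export(name = ".measure_fp_cpp")]]
List measure_fp_cpp(SEXP xp, SEXP truth_xp, double n_queries, double seed,
                    int min_len, int max_len) {
  BQF* f = get(xp);
  XPtr<std::unordered_set<uint64_t>> truth(truth_xp);
  if (n_queries < 1) stop("n_queries must be >= 1");
  bqfcore::SplitMix rng((uint64_t)seed);
  int k = f->k;
  uint64_t done = 0, fp = 0, fn = 0, present = 0;
  uint64_t target = (uint64_t)n_queries;
  std::string buf;
  std::vector<long long> vals, mins, kcodes;
  int span = max_len - min_len + 1;
  while (done < target) {
    int L = min_len + (int)(rng.next() % (uint64_t)span);
    if (L < k) L = k;
    buf.assign(L, 'A');
    for (int j = 0; j < L; ++j) buf[j] = bqfcore::code_base((int)(rng.next() & 3));
    query_seq_stored(f, buf.c_str(), L, vals, mins);
    window_codes(buf.c_str(), L, k, f->canon, kcodes);
    for (size_t j = 0; j < mins.size() && done < target; ++j) {
      bool pres = mins[j] >= 0;
      bool intruth = truth->count((uint64_t)kcodes[j]) > 0;
      present += pres;
      fp += (pres && !intruth);
      fn += (!pres && intruth);
      ++done;
    }
  }
  return List::create(_["n_queries"] = (double)done, _["fp"] = (double)fp,
                      _["fn"] = (double)fn, _["present"] = (double)present);
}
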