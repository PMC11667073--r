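#pragma once

#include <cstdint>
#include <vector>
#include <deque>
#include <string>
#include <stdexcept>

// Core of the backpack quotient filter: a rank-and-select quotient filter
// whose 2^q slots each hold an r-bit remainder and a c-bit saturating
// counter, with per-slot occupied/runend metadata bits and one 64-bit
// offset checkpoint per block of 64 slots.  The table is circular: a run
// shifted past slot 2^q - 1 continues at slot 0.  All positions handed
// around internally are "unrolled" (monotone, possibly >= 2^q) and reduced
// modulo 2^q only when touching memory, which keeps cyclic comparisons
// well-defined.

namespace bqfcore {

// ---------------------------------------------------------------- hashing

// Invertible xorshift-multiply mixer on [0, 2^(2s)).  The shift equals the
// half-width s, so each xor-shift step is an involution; the multipliers are
// odd, hence invertible modulo 2^(2s).  Constants are fixed for every s and
// fingerprinted in the serialized header.
constexpr uint64_t HASH_C1 = 0xff51afd7ed558ccdULL;
constexpr uint64_t HASH_C2 = 0xc4ceb9fe1a85ec53ULL;

inline uint64_t width_mask(int w) {
  return (w >= 64) ? ~0ULL : ((1ULL << w) - 1ULL);
}

// inverse of an odd integer modulo 2^64 (Newton doubling)
inline uint64_t modinv_pow2(uint64_t a) {
  uint64_t x = a;
  for (int i = 0; i < 5; ++i) x *= 2 - a * x;
  return x;
}

inline uint64_t hash_2s(uint64_t x, int s) {
  const int w = 2 * s;
  const uint64_t m = width_mask(w);
  uint64_t h = x & m;
  h ^= h >> s;
  h = (h * (HASH_C1 & m)) & m;
  h ^= h >> s;
  h = (h * (HASH_C2 & m)) & m;
  h ^= h >> s;
  return h;
}

inline uint64_t unhash_2s(uint64_t y, int s) {
  const int w = 2 * s;
  const uint64_t m = width_mask(w);
  uint64_t h = y & m;
  h ^= h >> s;
  h = (h * (modinv_pow2(HASH_C2 & m) & m)) & m;
  h ^= h >> s;
  h = (h * (modinv_pow2(HASH_C1 & m) & m)) & m;
  h ^= h >> s;
  return h;
}

inline uint64_t hash_fingerprint() { return HASH_C1 ^ (HASH_C2 >> 1); }

// ------------------------------------------------------------- DNA coding

// A=0, C=1, G=2, T=3, most-significant digit first; complement = 3 - digit.
inline int base_code(char ch) {
  switch (ch) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

inline char code_base(int b) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  return BASES[b & 3];
}

// returns -1 on success, else the 0-based position of the first bad char
inline long long encode_dna(const char* seq, int len, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < len; ++i) {
    int b = base_code(seq[i]);
    if (b < 0) return i;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return -1;
}

inline std::string decode_dna(uint64_t code, int len) {
  std::string s(len, 'A');
  for (int i = len - 1; i >= 0; --i) {
    s[i] = code_base((int)(code & 3));
    code >>= 2;
  }
  return s;
}

inline uint64_t revcomp_code(uint64_t code, int len) {
  uint64_t rc = 0;
  for (int i = 0; i < len; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

inline uint64_t canonical_code(uint64_t code, int len) {
  uint64_t rc = revcomp_code(code, len);
  return rc < code ? rc : code;
}

// ------------------------------------------------------------------- PRNG

// splitmix64: deterministic, seedable, platform-independent
struct SplitMix {
  uint64_t state;
  explicit SplitMix(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// ------------------------------------------------------------ filter core

struct Element {
  uint64_t hash;    // full 2s-bit hash value
  uint64_t stored;  // raw c-bit counter payload
};

class BQF {
public:
  int q;            // address bits
  int r;            // remainder bits, r = 2s - q
  int c;            // counter bits
  int k;            // query word length
  int s;            // indexed word length
  bool canon;       // canonicalize s-mers
  int mode;         // 0 = exact-capped counts, 1 = log2 buckets
  uint64_t n;       // stored elements

  uint64_t N;       // 2^q slots
  uint64_t nwords;  // N / 64
  int slotw;        // r + c bits per slot

  std::vector<uint64_t> occ;    // occupied bits, one per slot
  std::vector<uint64_t> rend;   // runend bits, one per slot
  std::vector<uint64_t> off;    // one 64-bit offset per 64-slot block
  std::vector<uint64_t> slots;  // packed (remainder, counter) records

  BQF(int q_, int s_, int k_, int c_, bool canon_, int mode_)
      : q(q_), c(c_), k(k_), s(s_), canon(canon_), mode(mode_), n(0) {
    if (s < 1 || s > 31) throw std::invalid_argument("s must be in 1..31");
    if (k < s || k > 31) throw std::invalid_argument("k must be in s..31");
    if (c < 1 || c > 8) throw std::invalid_argument("c must be in 1..8");
    if (q < 6) throw std::invalid_argument("q must be >= 6 (one 64-slot block)");
    if (q > 2 * s) throw std::invalid_argument("q must be <= 2s");
    r = 2 * s - q;
    N = 1ULL << q;
    nwords = N >> 6;
    slotw = r + c;
    occ.assign(nwords, 0);
    rend.assign(nwords, 0);
    off.assign(nwords, 0);
    slots.assign((N * (uint64_t)slotw) >> 6, 0);
  }

  uint64_t md(uint64_t p) const { return p & (N - 1); }
  uint64_t rmask() const { return width_mask(r); }
  uint64_t cmask() const { return width_mask(c); }
  uint64_t cap() const { return cmask(); }

  double load_factor() const { return (double)n / (double)N; }
  uint64_t size_bits() const { return N * (uint64_t)(r + c + 3); }

  // ---- bit vector primitives (index must be < N) ----
  static bool get_bit(const std::vector<uint64_t>& v, uint64_t i) {
    return (v[i >> 6] >> (i & 63)) & 1ULL;
  }
  static void set_bit(std::vector<uint64_t>& v, uint64_t i) {
    v[i >> 6] |= 1ULL << (i & 63);
  }
  static void clear_bit(std::vector<uint64_t>& v, uint64_t i) {
    v[i >> 6] &= ~(1ULL << (i & 63));
  }
  static void assign_bit(std::vector<uint64_t>& v, uint64_t i, bool b) {
    if (b) set_bit(v, i); else clear_bit(v, i);
  }

  // ---- packed slot access ----
  uint64_t slot_get(uint64_t i) const {
    uint64_t bo = i * (uint64_t)slotw;
    uint64_t w = bo >> 6;
    int sh = (int)(bo & 63);
    uint64_t lo = slots[w] >> sh;
    int got = 64 - sh;
    if (got < slotw) lo |= slots[w + 1] << got;
    return lo & width_mask(slotw);
  }
  void slot_set(uint64_t i, uint64_t val) {
    uint64_t bo = i * (uint64_t)slotw;
    uint64_t w = bo >> 6;
    int sh = (int)(bo & 63);
    uint64_t m = width_mask(slotw);
    val &= m;
    slots[w] = (slots[w] & ~(m << sh)) | (val << sh);
    int got = 64 - sh;
    if (got < slotw) {
      uint64_t hi_m = m >> got;
      slots[w + 1] = (slots[w + 1] & ~hi_m) | (val >> got);
    }
  }
  uint64_t slot_rem(uint64_t i) const { return slot_get(i) >> c; }
  uint64_t slot_cnt(uint64_t i) const { return slot_get(i) & cmask(); }

  // ---- ranged scans over bitvectors (unrolled coordinates) ----

  // number of set bits of `v` at positions (a, b], b - a < N
  uint64_t range_count(const std::vector<uint64_t>& v, uint64_t a, uint64_t b) const {
    if (b <= a) return 0;
    uint64_t cnt = 0;
    uint64_t p = a + 1;
    while (p <= b) {
      uint64_t i = md(p);
      uint64_t w = i >> 6;
      int bit = (int)(i & 63);
      uint64_t avail = 64 - (uint64_t)bit;
      uint64_t remaining = b - p + 1;
      uint64_t take = remaining < avail ? remaining : avail;
      uint64_t word = v[w] >> bit;
      if (take < 64) word &= (1ULL << take) - 1ULL;
      cnt += __builtin_popcountll(word);
      p += take;
    }
    return cnt;
  }

  // unrolled position of the d-th set bit of `v` at positions >= p (d >= 1);
  // throws if not found within one full revolution
  uint64_t select_from(const std::vector<uint64_t>& v, uint64_t p, uint64_t d) const {
    uint64_t scanned = 0;
    while (scanned <= N + 64) {
      uint64_t i = md(p);
      uint64_t w = i >> 6;
      int bit = (int)(i & 63);
      uint64_t word = v[w] >> bit;
      uint64_t pc = __builtin_popcountll(word);
      if (pc >= d) {
        uint64_t x = word;
        for (uint64_t j = 1; j < d; ++j) x &= x - 1;
        return p + (uint64_t)__builtin_ctzll(x);
      }
      d -= pc;
      uint64_t step = 64 - (uint64_t)bit;
      p += step;
      scanned += step;
    }
    throw std::runtime_error("select: fewer set bits than requested");
  }

  // ---- rank-and-select machinery ----

  struct Cover { bool found; uint64_t pos; };

  // Runend position (unrolled, >= block leader of x) of the last occupied
  // quotient <= x, computed via the block's offset checkpoint.
  // found == false means every quotient <= x has its run ending before x's
  // block leader (so x cannot be covered by any run).
  Cover covering(uint64_t x) const {
    uint64_t j = x & ~63ULL;            // block leader
    uint64_t O = off[j >> 6];
    bool has = get_bit(occ, j) || O > 0 || get_bit(rend, j);
    uint64_t d = range_count(occ, j, x);  // occupied quotients in (j, x]
    if (d == 0) {
      if (!has) return {false, 0};
      return {true, j + O};
    }
    uint64_t from = has ? (j + O + 1) : j;
    return {true, select_from(rend, from, d)};
  }

  // runend of quotient u's own run; requires occ[u] == 1
  uint64_t runend_of(uint64_t u) const {
    Cover cv = covering(u);
    return cv.pos;  // >= u since u itself is occupied
  }

  // first slot of u's run given its runend e (unrolled e >= u)
  uint64_t run_start(uint64_t u, uint64_t e) const {
    uint64_t t = e;
    while (t > u && !get_bit(rend, md(t - 1))) --t;
    return t;
  }

  bool slot_in_use(uint64_t x) const {
    if (get_bit(occ, x)) return true;
    Cover cv = covering(x);
    return cv.found && cv.pos >= x;
  }

  // First empty slot at/after the cluster region, given a known runend t0 of
  // the last quotient <= u (closure over runs that keep the stretch
  // contiguous).  Returns an unrolled position.
  uint64_t first_empty_after(uint64_t u, uint64_t t0) const {
    uint64_t end = t0, vq = u;
    for (;;) {
      uint64_t cnt = range_count(occ, vq, end + 1);
      if (cnt == 0) return end + 1;
      uint64_t old_end = end;
      end = select_from(rend, end + 1, cnt);
      vq = old_end + 1;
    }
  }

  // Recompute the offset checkpoints of every block leader in [u, to]
  // (unrolled), given that the runend of the last quotient <= u is
  // anch_end (or that no such runend lies at/after u when !anch_found).
  void fix_offsets(uint64_t u, uint64_t to, bool anch_found, uint64_t anch_end) {
    uint64_t j = (u + 63) & ~63ULL;  // first leader >= u
    if (j > to) return;
    uint64_t vq = u;
    bool found = anch_found;
    uint64_t ve = anch_end;
    for (; j <= to; j += 64) {
      uint64_t cnt = range_count(occ, vq, j);
      if (cnt > 0) {
        uint64_t from = found ? ve + 1 : vq;
        ve = select_from(rend, from, cnt);
        found = true;
      }
      vq = j;
      off[md(j) >> 6] = (found && ve >= j) ? (ve - j) : 0;
    }
  }

  // ---- counters ----
  uint64_t encode_count(uint64_t count) const {
    if (count == 0) throw std::invalid_argument("count must be >= 1");
    uint64_t v;
    if (mode == 0) {
      v = count;
    } else {
      v = 63 - (uint64_t)__builtin_clzll(count);  // floor(log2(count))
    }
    return v > cap() ? cap() : v;
  }

  // ---- operations ----

  // merge into an existing element; returns true if found
  bool try_merge(uint64_t h, uint64_t count) {
    uint64_t u = h >> r, rm = h & rmask();
    if (!get_bit(occ, u)) return false;
    uint64_t e = runend_of(u);
    uint64_t st = run_start(u, e);
    for (uint64_t t = st; t <= e; ++t) {
      uint64_t i = md(t);
      uint64_t trm = slot_rem(i);
      if (trm == rm) {
        if (mode != 0)
          throw std::runtime_error("incremental updates are not supported with log2 counters");
        uint64_t cur = slot_cnt(i);
        uint64_t nv = cur + count;
        if (nv > cap() || nv < cur) nv = cap();
        slot_set(i, (rm << c) | nv);
        return true;
      }
      if (trm > rm) return false;
    }
    return false;
  }

  void insert(uint64_t h, uint64_t count) {
    uint64_t stored = encode_count(count);  // validates count >= 1
    if (try_merge(h, count)) return;
    while (r > 0 && (n + 1) * 20ULL > 19ULL * N) resize();
    if (n == N) throw std::runtime_error("filter full and r = 0: cannot resize");
    insert_new(h, stored);
  }

  // place a new element with a pre-encoded counter payload
  void insert_new(uint64_t h, uint64_t stored) {
    uint64_t u = h >> r, rm = h & rmask();
    bool newrun = !get_bit(occ, u);
    uint64_t p, f, e = 0;

    if (!newrun) {
      e = runend_of(u);
      uint64_t st = run_start(u, e);
      p = e + 1;
      for (uint64_t t = st; t <= e; ++t) {
        if (slot_rem(md(t)) > rm) { p = t; break; }
      }
      f = first_empty_after(u, e);
    } else {
      Cover cv = covering(u);
      if (!cv.found || cv.pos < u) {
        // home slot is free
        slot_set(u, (rm << c) | stored);
        set_bit(occ, u);
        set_bit(rend, u);
        ++n;
        fix_offsets(u, u, true, u);
        return;
      }
      p = cv.pos + 1;
      f = first_empty_after(u, cv.pos);
    }

    // shift [p, f-1] one slot to the right (remainder+counter and runend
    // bits move together); slot f is empty
    for (uint64_t x = f; x > p; --x) {
      uint64_t i = md(x), i1 = md(x - 1);
      slot_set(i, slot_get(i1));
      assign_bit(rend, i, get_bit(rend, i1));
    }
    if (f > p) clear_bit(rend, md(p));
    slot_set(md(p), (rm << c) | stored);

    uint64_t new_e;
    if (newrun) {
      set_bit(occ, u);
      set_bit(rend, md(p));
      new_e = p;
    } else if (p == e + 1) {   // appended as the run's new largest remainder
      clear_bit(rend, md(e));
      set_bit(rend, md(p));
      new_e = p;
    } else {
      new_e = e + 1;           // runend bit moved with the shift
    }
    ++n;
    fix_offsets(u, f, true, new_e);
  }

  // stored counter payload or -1 when absent
  long long query_stored(uint64_t h) const {
    uint64_t u = h >> r, rm = h & rmask();
    if (!get_bit(occ, u)) return -1;
    uint64_t e = runend_of(u);
    uint64_t st = run_start(u, e);
    for (uint64_t t = st; t <= e; ++t) {
      uint64_t trm = slot_rem(md(t));
      if (trm == rm) return (long long)slot_cnt(md(t));
      if (trm > rm) return -1;
    }
    return -1;
  }

  // returns false (with no change) when the element is absent
  bool erase(uint64_t h) {
    uint64_t u = h >> r, rm = h & rmask();
    if (!get_bit(occ, u)) return false;
    uint64_t e = runend_of(u);
    uint64_t st = run_start(u, e);
    uint64_t p = e + 1;
    for (uint64_t t = st; t <= e; ++t) {
      uint64_t trm = slot_rem(md(t));
      if (trm == rm) { p = t; break; }
      if (trm > rm) return false;
    }
    if (p == e + 1) return false;

    // how far left-shifting may propagate: stop before a run that sits at
    // its home quotient (it must not move left of its address) or at the
    // cluster end
    uint64_t bnd;
    {
      uint64_t cur_end = e, vq = u;
      for (;;) {
        uint64_t cnt = range_count(occ, vq, cur_end + 1);
        if (cnt == 0) { bnd = cur_end; break; }
        uint64_t v = select_from(occ, vq + 1, 1);   // next occupied quotient
        if (v == cur_end + 1) { bnd = cur_end; break; }
        uint64_t vend = select_from(rend, cur_end + 1, 1);
        vq = v;
        cur_end = vend;
      }
    }

    for (uint64_t x = p; x < bnd; ++x) {
      uint64_t i = md(x), i1 = md(x + 1);
      slot_set(i, slot_get(i1));
      assign_bit(rend, i, get_bit(rend, i1));
    }
    clear_bit(rend, md(bnd));

    bool singleton = (st == e);
    if (singleton) {
      clear_bit(occ, u);
    } else if (p == e) {
      set_bit(rend, md(e - 1));  // run lost its last slot
    }
    --n;

    bool anch_found;
    uint64_t anch_end = 0;
    if (singleton) {
      anch_found = (st > u);
      if (anch_found) anch_end = st - 1;  // previous run's end, untouched
    } else {
      anch_found = true;
      anch_end = e - 1;
    }
    fix_offsets(u, bnd, anch_found, anch_end);
    return true;
  }

  // find one empty slot by linear scan (n < N must hold)
  uint64_t find_any_empty() const {
    for (uint64_t x = 0; x < N; ++x)
      if (!slot_in_use(x)) return x;
    throw std::runtime_error("no empty slot");
  }

  // every stored element exactly once, in quotient order from the anchor
  std::vector<Element> enumerate() const {
    std::vector<Element> out;
    out.reserve((size_t)n);
    if (n == 0) return out;
    if (n == N) {  // only possible at r = 0: every run is a singleton
      for (uint64_t i = 0; i < N; ++i)
        out.push_back({(i << r) | slot_rem(i), slot_cnt(i)});
      return out;
    }
    uint64_t E = find_any_empty();
    std::deque<uint64_t> pend;
    for (uint64_t t = E + 1; t <= E + N; ++t) {
      uint64_t i = md(t);
      if (get_bit(occ, i)) pend.push_back(i);
      if (pend.empty()) continue;
      uint64_t quot = pend.front();
      uint64_t v = slot_get(i);
      out.push_back({(quot << r) | (v >> c), v & cmask()});
      if (get_bit(rend, i)) pend.pop_front();
    }
    return out;
  }

  // double the slot count: the same 2s-bit hash is re-split with q+1
  // address bits and r-1 remainder bits; counters carry over unchanged
  void resize() {
    if (r == 0)
      throw std::runtime_error("cannot resize: remainder is empty (r = 0)");
    BQF big(q + 1, s, k, c, canon, mode);
    for (const Element& el : enumerate()) big.insert_new(el.hash, el.stored);
    *this = std::move(big);
  }

  // ---- structural self-check (testing aid) ----
  // verifies metadata invariants and recomputes every offset checkpoint
  // from an anchored full pass; throws with a message on any violation
  void validate() const {
    uint64_t po = 0, pr = 0;
    for (uint64_t w = 0; w < nwords; ++w) {
      po += __builtin_popcountll(occ[w]);
      pr += __builtin_popcountll(rend[w]);
    }
    if (po != pr) throw std::runtime_error("popcount(occupieds) != popcount(runends)");
    if (n == 0) {
      for (uint64_t b = 0; b < nwords; ++b)
        if (off[b] != 0) throw std::runtime_error("nonzero offset in empty filter");
      if (po != 0) throw std::runtime_error("metadata bits set in empty filter");
      return;
    }
    if (n == N) return;
    uint64_t E = find_any_empty();
    std::deque<uint64_t> pend;
    std::vector<std::pair<uint64_t, uint64_t>> ends;  // (quotient, runend), unrolled
    uint64_t emitted = 0, last_rem = 0;
    bool in_run = false;
    for (uint64_t t = E + 1; t <= E + N; ++t) {
      uint64_t i = md(t);
      if (get_bit(occ, i)) pend.push_back(t);  // quotient, unrolled past anchor
      if (pend.empty()) {
        if (get_bit(rend, i)) throw std::runtime_error("runend bit on empty slot");
        in_run = false;
        continue;
      }
      uint64_t rm = slot_rem(i);
      if (in_run && rm <= last_rem)
        throw std::runtime_error("remainders not strictly ascending in run");
      last_rem = rm;
      in_run = true;
      ++emitted;
      if (get_bit(rend, i)) {
        ends.push_back({pend.front(), t});
        pend.pop_front();
        in_run = false;
      }
    }
    if (emitted != n) throw std::runtime_error("enumerated count != n");
    if (!pend.empty()) throw std::runtime_error("unterminated run");
    // offsets: for each block leader, expected offset from the pass
    for (uint64_t b = 0; b < nwords; ++b) {
      uint64_t j = b << 6;
      uint64_t ju = (j > E) ? j : j + N;  // leader in anchored frame
      // last (quotient <= ju) pair
      bool found = false;
      uint64_t ve = 0;
      for (const auto& pr2 : ends) {
        if (pr2.first <= ju) { found = true; ve = pr2.second; }
        else break;
      }
      uint64_t expect = (found && ve >= ju) ? (ve - ju) : 0;
      if (off[b] != expect)
        throw std::runtime_error("offset checkpoint mismatch at block " + std::to_string(b));
    }
  }
};

}  // namespace bqfcore
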