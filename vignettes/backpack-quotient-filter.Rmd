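---
title: "The backpack quotient filter: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The backpack quotient filter: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bqf)
```

This vignette is the package's own account of the method: what the index
stores, the assumptions behind each parameter, the numerical conventions the
implementation commits to, and what the synthetic experiments do and do not
demonstrate.

## The model

The index answers abundance queries about k-mers by storing the dataset's
s-mers, s ≤ k, in a quotient filter whose slots each carry a small counter.

**Hashing.** A fixed bijection on [0, 4^s) maps the 2-bit encoding of an
s-mer (A=0, C=1, G=2, T=3, most-significant digit first, so complementing a
base is `3 - digit` and the encoding is lexicographically monotone) to a
2s-bit hash. The mixer alternates xor-with-right-shift-by-s steps (each an
involution at width 2s) with multiplications by fixed odd constants modulo
2^(2s), so the map is invertible for every s, with the inverse running the
steps backwards through modular inverses. Injectivity is what makes the
filter exact at the s-mer level — a stored (quotient, remainder) pair
reconstructs the full hash, hence the s-mer — and what makes enumeration and
resizing possible at all. The constants are identical for all s and
fingerprinted in the serialized header, so an index refuses to load into a
build with different constants.

**The slot table.** The top q bits of the hash address one of 2^q slots; the
low r = 2s − q bits are stored as the remainder next to a c-bit counter.
Elements that share a quotient form a run, kept in ascending remainder
order; runs are laid out greedily after their home slot, never before it,
and two metadata bitvectors (occupieds: "this quotient received at least one
element"; runends: "this slot ends a run") recover each run through

    runend_position(i) = Select(runends, Rank(occupieds, i)).

Scanning whole bitvectors per query would be linear in the table, so every
64-slot block stores a 64-bit offset checkpoint: for block-leading slot j,
the distance from j to the runend of the last run at a quotient ≤ j (0 when
that run ends before j). Rank then only scans within a block and Select
starts from the checkpointed position. We deliberately spend a full 64-bit
word per block — 1 bit per slot, 3 metadata bits per slot in total — rather
than a compressed 0.125-bit encoding: the accounting

    size_bits = 2^q × (r + c + 3)

stays exact, sections stay word-aligned, and the serialized payload is
bit-for-bit the in-memory structure.

**Abundance.** Each slot's counter is part of the slot ("every element
carries its own backpack"), so an element costs one slot regardless of its
abundance — in contrast to counting filters that spend extra slots encoding
large counts. Counters saturate: a stored value of 2^c − 1 means the true
count is *at least* 2^c − 1, and query results carry a `saturated` flag. We
report the bound "≥ 2^c − 1" because it is the provably correct one — the
stored cap itself is the last representable value. In `log2` mode the
counter stores floor(log2(count)) instead, trading precision for range;
since two log-bucketed counts cannot be meaningfully added, incremental
updates and deletions are refused in that mode (build once from counted
input).

**The fimpera layer.** A k-mer is present iff all of its k − s + 1 s-mers
are present, with abundance their minimum: if a word occurs t times, each of
its sub-words occurs at least t times. Storing s-mers shrinks every slot by
2(k − s) bits. The cost is a new error mode, the *construction false
positive*: an absent k-mer whose s-mers are all individually present (each
contributed by some other k-mer). Under a uniform ACGT model, a fixed s-mer
appears somewhere in a text of effective length l with probability

    p_appear(s, l) = 1 − (1 − 4^(−s))^l,

computed via `log1p`/`expm1` so it is accurate for l in the billions. Once
p_appear approaches 1 nearly every k-mer can be assembled from stored
s-mers; the usable regime is where it is small. l is well approximated by
the number of distinct k-mers of the dataset. Note that the probability
saturates to 1.0 in double precision for small s, so monotonicity in s is
weak (≤) in the saturated range and strict below it.

**Dynamics.** Insertion places the remainder in its run (merging counters
saturatingly if the element exists), shifting subsequent records — remainder
and counter move together, runend bits move with them — up to the first
empty slot, then repairs the affected offset checkpoints. Before any
inserting step, if (n+1)/2^q > 0.95 (evaluated exactly as the integer test
20(n+1) > 19·2^q) the table doubles: every element keeps its 2s-bit hash,
re-split with q+1 address bits and r−1 remainder bits. Because the quotient
is the *most significant* part of the hash, doubling splits each run into
two runs of adjacent quotients and preserves ascending order. Deletion
removes a slot, shifts the cluster back until the first run that sits at its
home quotient, and repairs metadata; it is only offered with exact counters.

## Parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| k | query word length (nt) | 31 in examples | standard pseudo-alignment word size; ≤ 31 keeps a 2k-bit word in 64 bits |
| s | indexed word length (nt) | 19 in examples | smallest s whose chance-occurrence probability stays negligible at metagenome scale; each unit of s costs 2 bits/slot |
| c | counter bits | 5 | counts up to 31 exactly; metagenomic k-mer spectra are dominated by low counts, so 5 bits cover the bulk and the cap flags the rest |
| q | address bits | chosen from n | smallest q with n/2^q ≤ 0.95 (capped at 2s); resizing corrects underestimates, so q is a starting point, not a commitment |
| canonical | fold reverse complements | TRUE | matches the convention of standard k-mer counters, whose dumps this package consumes |
| min_count | abundance floor at build | 1 | the common "present at least twice" noise filter is min_count = 2; we expose it rather than hard-code it |

## Numerical and edge-case conventions

* **Circularity.** The table is a ring: a run shifted past slot 2^q − 1
  continues at slot 0. Internally all positions are handled in "unrolled"
  coordinates (monotone, reduced modulo 2^q only at memory access), which
  keeps cyclic comparisons well-defined. The textbook
  Select(runends, Rank(occupieds, i)) formula assumes a linear layout; with
  wrap-around it is evaluated in coordinates rotated so that an empty slot
  is the origin — a pure relabeling that coincides with the raw formula
  whenever no run crosses the boundary. The test suite checks the
  block-offset path against this rotated global formula on every slot of
  randomized filters, and against an independent greedy reconstruction of
  the layout from the element set.
* **Empty slots** are recognized purely from metadata (a run "covering" test
  via the offset checkpoints), never by a sentinel remainder — a remainder
  of zero is a legal value.
* **Offset convention.** The checkpoint of block leader j is
  max(0, runend(last quotient ≤ j) − j). The clamp makes "covered by a run
  ending at j" and "no coverage" both store 0 for unoccupied leaders; the
  runend bit at j disambiguates the two when emptiness must be decided.
* **r = 0.** When q = 2s the address consumes the whole hash: every run is a
  singleton and the filter degenerates into a direct-addressed counter
  table. Resizing is impossible (no remainder bit to promote), so the 95%
  trigger is waived there and insertion fails only when the table is
  literally full. The s-sweep reaches this regime legitimately at small s,
  where at most 4^s distinct s-mers exist.
* **Counter merging** uses saturating addition, which is associative, so
  batch and sequential insertion of the same multiset agree exactly.
* **Ties.** Remainders within a run are strictly increasing (equal
  remainder = same element = merge), so lookup can stop at the first larger
  remainder.
* **Degenerate inputs.** Reads shorter than s contribute nothing; windows
  containing non-ACGT characters are skipped at build time and reported
  absent at query time, leaving neighboring windows untouched; querying an
  empty filter answers absent everywhere; an empty build yields a valid,
  serializable index.

## The synthetic generator, and what the experiments show

`gen_reads()` draws i.i.d. uniform bases from a seeded, platform-independent
generator (an optional GC dial skews the base composition; it defaults to
0.5 and is unused by the standard experiments). This matches the model under
which p_appear is derived and the convention that negative queries are
k-mers of random sequences (80–120 nt).

Uniform reads emulate the *hard* part of metagenomic indexing — huge numbers
of distinct, low-abundance, weakly correlated k-mers — but not the local
repetitiveness, coverage structure, or GC skew of real data. Consequences to
keep in mind: real datasets share long exact repeats, so their distinct-s-mer
counts grow differently with s, and sequence correlation moves the
false-positive blow-up threshold (uniform texts push it to smaller s than
real metagenomes, where the practical rule of thumb is s > 17 for k = 31).
The s-sweep therefore *reports* the curve rather than asserting a universal
threshold. What the passing tests do establish: exactness at the s-mer
level, the min-over-s-mers semantics, the size accounting, the resize
discipline, and that the measured construction false-positive rate on the
reference synthetic build (5×10⁴ reads × 150 nt, k = 31, s = 19, 10⁷
negative queries) sits below 10⁻⁵ %.

Problem sizes were chosen so the whole suite exercises every path at desk
scale: exhaustive universes for hashing (4^s for s ≤ 8) and for the fimpera
semantics (all 4^8 k-mers against an s = 5 index), ~10⁵ randomized
filter operations against a dictionary oracle across q = 6..16, and the
single large build above for the false-positive measurement.

## Open design choices, resolved

* **Hash constants.** Any documented bijection satisfies the contract
  (injective and reversible); we fix two odd 64-bit multipliers (masked to
  2s bits, where they remain odd) and embed a fingerprint in the header.
  Bit-compatibility with other implementations' index files is a non-goal.
* **Canonicalization** is a flag (default on) rather than a hard-coded
  behavior, because counted dumps in the wild come both ways; the flag is
  recorded in the header and applied symmetrically at build and query time.
* **Quotient from the top bits.** Taking h₀ as the most-significant q bits
  makes resize a local split of each run (the promoted remainder bit is the
  new low quotient bit), preserving run order — the alternative (low bits)
  would interleave runs globally.
* **Initial q from the element count** avoids pointless doubling cascades
  when building from counted input; a user override exists for
  benchmarking.
* **Counter zero is never stored**: presence implies abundance ≥ 1, so the
  insertable minimum count is 1 and "absent" and "count 0" coincide in
  tabular output (with an explicit `present` column for disambiguation).

## Limitations

One index describes one sample: colored/multi-sample queries are out of
scope. k-mers cannot be enumerated (only the stored s-mers can — the k-mers
were never materialized). Abundances can be overestimated by the min-over-
s-mers rule when every s-mer of a rare k-mer also occurs elsewhere; the
package reports the minimum, which is an upper bound on the truth only in
that specific collision sense, and exact whenever any constituent s-mer is
unique to the k-mer. Word lengths are capped at 31 nt so every hash fits a
64-bit word; counter widths at 8 bits so a slot never spans more than two
words. The numeric R-level codec helpers are exact up to 26 nt (double
precision); the index itself uses 64-bit integers throughout.
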