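# Synthetic data generation and the evaluation procedures: construction
# false-positive rate, s-sweeps, and the bits-per-element bounds.

#' Generate uniform random reads
#'
#' I.i.d. bases with equal A/C/G/T frequencies by default (the model under
#' which the chance-occurrence probability [p_appear()] is derived); a GC
#' bias can be dialed in. Deterministic for a given seed, independently of
#' R's RNG state.
#'
#' @param n_reads number of reads.
#' @param read_len length of every read (nt).
#' @param seed integer seed.
#' @param gc GC fraction (default 0.5 = uniform).
#' @return character vector of reads.
#' @export
gen_reads <- function(n_reads, read_len, seed, gc = 0.5) {
  if (n_reads < 0) stop("n_reads must be >= 0")
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  if (n_reads == 0) return(character(0))
  .gen_reads_cpp(as.numeric(n_reads), as.integer(read_len),
                 as.numeric(seed), as.numeric(gc))
}

#' Probability that an s-mer occurs by chance in a text of length l
#'
#' Under a uniform ACGT model, a fixed word of length s appears at a given
#' position with probability `4^-s`, so the probability of appearing at
#' least once among l draws is `1 - (1 - 4^-s)^l`, evaluated stably via
#' `log1p` for large l. This drives the construction false-positive rate:
#' once it nears 1, almost any k-mer can be assembled from stored s-mers.
#'
#' @param s word length.
#' @param l text length (number of draws); often approximated by the number
#'   of distinct k-mers of the dataset.
#' @return probability in `[0, 1]`; vectorized over both arguments.
#' @examples
#' p_appear(17, 2.63e8)  # ~0.0152
#' @export
p_appear <- function(s, l) {
  if (any(s < 1)) stop("s must be >= 1")
  if (any(l < 0)) stop("l must be >= 0")
  -expm1(l * log1p(-(4^-s)))
}

#' Distinct k-mer truth set of a read set
#'
#' Collects the exact set of (canonical) k-mers present in the reads, used
#' as ground truth when measuring construction false positives.
#'
#' @param reads character vector of sequences.
#' @param k word length (<= 31).
#' @param canonical fold windows onto canonical form.
#' @return an opaque truth-set handle with attribute `n_kmers`.
#' @export
kmer_truth <- function(reads, k, canonical = TRUE) {
  ptr <- .kmer_truth_cpp(as.character(reads), as.integer(k), isTRUE(canonical))
  structure(list(ptr = ptr, k = as.integer(k), canonical = isTRUE(canonical),
                 n_kmers = .kmer_truth_size_cpp(ptr)),
            class = "bqf_truth")
}

#' Construction false-positive rate under random negative queries
#'
#' Draws fresh uniform random sequences (80-120 nt by default), queries all
#' their k-mers against the index, and classifies each answer against the
#' exact truth set built from the indexed reads. A false positive is a
#' k-mer reported present that the reads never contained (possible only
#' because all its s-mers happen to be stored); false negatives are
#' structurally impossible and are reported as a cross-check.
#'
#' @param x a `bqf` index.
#' @param truth a [kmer_truth()] handle built from the same reads.
#' @param n_queries number of k-mer queries (>= 1).
#' @param seed integer seed for the query generator.
#' @param len_range length range of the random query sequences.
#' @return list with `fp_rate`, `fp`, `fn`, `present`, `n_queries`, `seed`.
#' @export
measure_fp_rate <- function(x, truth, n_queries, seed, len_range = c(80L, 120L)) {
  .check_bqf(x)
  if (!inherits(truth, "bqf_truth")) stop("`truth` must come from kmer_truth()")
  if (n_queries < 1) stop("n_queries must be >= 1 (rate undefined otherwise)")
  p <- .params(x)
  if (truth$k != p$k) stop("truth set was built for k = ", truth$k,
                           " but the index has k = ", p$k)
  res <- .measure_fp_cpp(x$ptr, truth$ptr, as.numeric(n_queries),
                         as.numeric(seed), as.integer(len_range[1]),
                         as.integer(len_range[2]))
  list(fp_rate = res$fp / res$n_queries, fp = res$fp, fn = res$fn,
       present = res$present, n_queries = res$n_queries, seed = seed)
}

#' Sweep the indexed word length s
#'
#' For each s: counts distinct s-mers, builds an index, measures the
#' construction false-positive rate against the k-mer truth set, and
#' evaluates both bits-per-element bounds. Exposes the two opposite effects
#' of shrinking s: slots lose 2 bits per unit of s, while small s saturates
#' the s-mer space (`4^s`) and lets false positives explode.
#'
#' @param reads character vector of sequences to index.
#' @param k query word length.
#' @param s_values which s to evaluate (subset of `1..k`).
#' @param c counter bits.
#' @param n_queries negative queries per s.
#' @param seed integer seed.
#' @param canonical canonicalize (default `TRUE`).
#' @param min_count drop s-mers below this count.
#' @return data frame with one row per s: `s`, `n_distinct`, `fp_rate`,
#'   `low_bound`, `high_bound` (bits/element at 95% and 50% load), plus
#'   attributes `seed`, `n_reads`, `read_len_total`, `n_queries`.
#' @export
s_sweep <- function(reads, k, s_values, c = 5L, n_queries = 1e5, seed = 1,
                    canonical = TRUE, min_count = 1) {
  stopifnot(all(s_values >= 1), all(s_values <= k))
  truth <- kmer_truth(reads, k, canonical)
  rows <- lapply(sort(as.integer(s_values), decreasing = TRUE), function(s) {
    idx <- bqf_build(reads = reads, k = k, s = s, c = c, canonical = canonical,
                     counter_mode = "exact", min_count = min_count)
    nd <- .params(idx)$n
    fpr <- measure_fp_rate(idx, truth, n_queries, seed + s)$fp_rate
    b <- bits_per_element_bounds(nd, s, c)
    data.frame(s = s, n_distinct = nd, fp_rate = fpr,
               low_bound = b[["low_bound"]], high_bound = b[["high_bound"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "n_reads") <- length(reads)
  attr(out, "read_len_total") <- sum(nchar(reads))
  attr(out, "n_queries") <- n_queries
  out
}

#' Bits-per-element bounds for a planned index
#'
#' Chooses the smallest `q` giving load factor at most 95% for `n_elements`
#' s-mers (capped at `q = 2s`, where the address consumes the whole hash and
#' the slot reduces to its `c + 3` counter and metadata bits), then reports
#' the slot width `(2s - q) + c + 3` divided by the two
#' reference load factors: `low_bound` at 95% (a just-about-to-double,
#' "full" table) and `high_bound` at 50% (a freshly doubled table). Real
#' indexes live between the two; `low_bound = high_bound * 0.5/0.95`
#' exactly.
#'
#' @param n_elements number of distinct s-mers to store (>= 1).
#' @param s indexed word length.
#' @param c counter bits.
#' @return named numeric vector `c(low_bound=, high_bound=, q=, width=)`.
#' @export
bits_per_element_bounds <- function(n_elements, s, c = 5L) {
  if (n_elements < 1) stop("n_elements must be >= 1")
  if (n_elements > 4^s)
    stop("s = ", s, " is too small for ", n_elements,
         " elements: only 4^s = ", 4^s, " distinct s-mers exist")
  q <- 6L
  while (n_elements / 2^q > 0.95 && q < 2L * s) q <- q + 1L
  width <- (2L * s - q) + c + 3L
  c(low_bound = width / 0.95, high_bound = width / 0.5,
    q = as.numeric(q), width = as.numeric(width))
}
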