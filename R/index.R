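# Building an index and answering k-mer queries through the fimpera scheme:
# the filter stores s-mers; a k-mer is reported with the minimum abundance
# of its k - s + 1 constituent s-mers, and is absent as soon as any of them
# is absent.

#' Build a backpack quotient filter from reads or counted s-mers
#'
#' Counts the s-mers of `reads` (or takes pre-counted records), drops those
#' below `min_count`, sizes the table to the smallest `q` with load factor
#' at most 95%, and inserts every record. Counts are encoded per
#' `counter_mode` and saturate at `2^c - 1`.
#'
#' @param reads character vector of read sequences (windows containing
#'   non-ACGT characters are skipped), or `NULL`.
#' @param counts data frame with columns `smer`, `count` (as returned by
#'   [read_counted_tsv()] or [count_smers()]), or `NULL`. Exactly one of
#'   `reads`/`counts` must be given. Duplicate s-mers (e.g. a canonical
#'   pair) have their raw counts merged with a warning.
#' @param k query word length (<= 31).
#' @param s indexed word length (<= k). Smaller s shrinks every slot by
#'   `2(k - s)` bits but raises the construction false-positive rate once
#'   random s-mers become likely to occur by chance in the indexed text.
#' @param c counter bits per slot (1..8).
#' @param q address bits; `NULL` (default) picks the smallest table with
#'   load factor <= 95%.
#' @param canonical canonicalize s-mers (default `TRUE`, matching the
#'   convention of standard k-mer counting tools).
#' @param counter_mode `"exact"` or `"log2"` (see [bqf_new()]).
#' @param min_count drop records with count below this (the standard
#'   "present at least twice" filter of metagenomic practice is
#'   `min_count = 2`; default 1 keeps everything).
#' @return a `bqf` index handle.
#' @examples
#' idx <- bqf_build(reads = c("ACGTACGTACGT", "TTTTACGTACGA"), k = 8, s = 5)
#' bqf_query_kmer(idx, "ACGTACGT")
#' @export
bqf_build <- function(reads = NULL, counts = NULL, k, s, c = 5L, q = NULL,
                      canonical = TRUE, counter_mode = c("exact", "log2"),
                      min_count = 1) {
  if (is.null(reads) == is.null(counts))
    stop("give exactly one of `reads` or `counts`")
  k <- as.integer(k); s <- as.integer(s); c <- as.integer(c)
  if (s > k) stop("s must be <= k (s-mers must fit inside the query words)")
  if (min_count < 1) stop("min_count must be >= 1")
  mode <- .counter_mode_int(counter_mode)
  qq <- if (is.null(q)) -1L else as.integer(q)
  ptr <- if (!is.null(reads)) {
    .bqf_build_reads_cpp(as.character(reads), k, s, c, isTRUE(canonical),
                         mode, as.numeric(min_count), qq)
  } else {
    if (!all(c("smer", "count") %in% names(counts)))
      stop("`counts` needs columns smer and count")
    if (any(counts$count < 1)) stop("counts must be >= 1")
    .bqf_build_counts_cpp(as.character(counts$smer), as.numeric(counts$count),
                          k, s, c, isTRUE(canonical), mode,
                          as.numeric(min_count), qq)
  }
  .new_handle(ptr)
}

#' Count the s-mers of a read set
#'
#' Exact multiplicities of every (canonical) s-length window across the
#' reads; windows containing non-ACGT characters are skipped, and reads
#' shorter than s contribute nothing.
#'
#' @param reads character vector of sequences.
#' @param s window length.
#' @param canonical fold each window onto its canonical form.
#' @param min_count drop s-mers seen fewer times than this.
#' @return data frame with columns `smer`, `count`, sorted by encoded value.
#' @export
count_smers <- function(reads, s, canonical = TRUE, min_count = 1) {
  res <- .count_smers_cpp(as.character(reads), as.integer(s), isTRUE(canonical))
  out <- data.frame(smer = res$smer, count = res$count)
  out[out$count >= min_count, , drop = FALSE]
}

#' Query k-mer abundances
#'
#' Each k-mer is present iff all of its `k - s + 1` s-mers are stored, with
#' abundance the minimum of their counters. A saturated answer means the
#' minimum hit the counter cap, so the true abundance is `>= 2^c - 1`.
#' k-mers containing non-ACGT characters are reported absent.
#'
#' @param x a `bqf` index.
#' @param kmers character vector of words of length `k`.
#' @return data frame with columns `kmer`, `present`, `count`, `saturated`.
#' @export
bqf_query_kmer <- function(x, kmers) {
  .check_bqf(x)
  p <- .params(x)
  kmers <- as.character(kmers)
  if (any(nchar(kmers) != p$k)) stop("query words must have length k = ", p$k)
  stored <- vapply(.bqf_query_seqs_cpp(x$ptr, kmers), function(v) v[1], numeric(1))
  cbind(data.frame(kmer = kmers), .decode_stored(stored, p$c, p$counter_mode))
}

#' Query every k-mer of longer sequences
#'
#' Slides a window of length k over each sequence, computing all answers in
#' one pass: each s-mer is looked up once and the per-window minimum is
#' maintained with a monotone queue, which is exactly equivalent to calling
#' [bqf_query_kmer()] on every window. Sequences shorter than k produce no
#' rows.
#'
#' @param x a `bqf` index.
#' @param seqs character vector of sequences; names are used as ids.
#' @return data frame with columns `id`, `pos` (0-based window start),
#'   `present`, `count` (0 when absent), `saturated`.
#' @export
bqf_query_sequence <- function(x, seqs) {
  .check_bqf(x)
  p <- .params(x)
  ids <- names(seqs)
  seqs <- as.character(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  res <- .bqf_query_seqs_cpp(x$ptr, seqs)
  nwin <- lengths(res)
  stored <- unlist(res, use.names = FALSE)
  if (is.null(stored)) stored <- numeric(0)
  pos <- unlist(lapply(nwin, function(m) seq_len(m) - 1L), use.names = FALSE)
  if (is.null(pos)) pos <- integer(0)
  out <- cbind(
    data.frame(id = rep(ids, nwin), pos = pos),
    .decode_stored(stored, p$c, p$counter_mode))
  rownames(out) <- NULL
  out
}
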