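# The filter handle: an S3 object wrapping the C++ structure.

.new_handle <- function(ptr) {
  structure(list(ptr = ptr), class = "bqf")
}

.check_bqf <- function(x) {
  if (!inherits(x, "bqf")) stop("not a bqf index", call. = FALSE)
  x
}

.params <- function(x) .bqf_params_cpp(x$ptr)

.counter_mode_int <- function(counter_mode) {
  match(match.arg(counter_mode, c("exact", "log2")), c("exact", "log2")) - 1L
}

.decode_stored <- function(stored, c_bits, mode) {
  cap <- 2^c_bits - 1
  present <- stored >= 0
  count <- ifelse(present, if (mode == 0L) stored else 2^stored, 0)
  saturated <- present & stored == cap
  data.frame(present = present, count = count, saturated = saturated)
}

#' Create an empty backpack quotient filter
#'
#' Allocates a table of `2^q` slots, each holding an r = 2s - q bit
#' remainder and a `c`-bit counter, plus three metadata bits per slot
#' (occupied, runend, and one 64-bit offset checkpoint per 64-slot block).
#' Prefer [bqf_build()] when the elements are already known: it sizes `q`
#' automatically.
#'
#' @param s indexed word length in nucleotides (1..31).
#' @param k query word length (`s <= k <= 31`); defaults to `s`.
#' @param c counter bits per slot (1..8); counts saturate at `2^c - 1`.
#' @param q address bits; the table has `2^q` slots and `q <= 2s`. The
#'   default caps the usual 16 at what the hash width allows.
#' @param canonical store canonical s-mers (identify a word with its reverse
#'   complement). Matches the default behavior of common k-mer counters.
#' @param counter_mode `"exact"` stores counts capped at `2^c - 1`;
#'   `"log2"` stores `floor(log2(count))` (orders of magnitude), in which
#'   case incremental updates are refused.
#' @return a `bqf` index handle.
#' @export
bqf_new <- function(s, k = s, c = 5L, q = max(6L, min(16L, 2L * s - 1L)),
                    canonical = TRUE, counter_mode = c("exact", "log2")) {
  mode <- .counter_mode_int(counter_mode)
  .new_handle(.bqf_new_cpp(as.integer(q), as.integer(s), as.integer(k),
                           as.integer(c), isTRUE(canonical), mode))
}

#' @export
print.bqf <- function(x, ...) {
  p <- .params(x)
  cat(sprintf("backpack quotient filter: %s / %s slots (q = %d), load %.1f%%\n",
              format(p$n, big.mark = ","), format(p$n_slots, big.mark = ","),
              p$q, 100 * p$load_factor))
  cat(sprintf("  s = %d, k = %d, r = %d remainder bits, c = %d counter bits (cap %d, %s)\n",
              p$s, p$k, p$r, p$c, 2^p$c - 1,
              if (p$counter_mode == 0) "exact" else "log2"))
  cat(sprintf("  canonical: %s; size: %s bits (%.2f MiB)",
              if (p$canonical) "yes" else "no",
              format(p$size_bits, big.mark = ","), p$size_bits / 8 / 2^20))
  if (p$n > 0) cat(sprintf("; %.2f bits/element", p$size_bits / p$n))
  cat("\n")
  invisible(x)
}

#' Insert s-mers with counts
#'
#' Inserts each s-mer (canonicalized if the index is canonical) with the
#' given count. Re-inserting an existing s-mer adds to its counter with
#' saturation at `2^c - 1` (exact mode only; log2 mode refuses updates).
#' When the pre-insert load factor would exceed 95% the table doubles first,
#' so insertion never fails for capacity reasons (unless r = 0, where no
#' remainder bit is left to promote into the address).
#'
#' @param x a `bqf` index.
#' @param smers character vector of s-mers.
#' @param count integer counts (recycled), each >= 1.
#' @return the index, invisibly.
#' @export
bqf_insert <- function(x, smers, count = 1) {
  .check_bqf(x)
  p <- .params(x)
  smers <- as.character(smers)
  if (any(nchar(smers) != p$s))
    stop("s-mers must have length s = ", p$s)
  count <- rep_len(as.numeric(count), length(smers))
  if (any(count < 1)) stop("counts must be >= 1")
  codes <- .smer_codes(smers, p)
  .bqf_insert_codes_cpp(x$ptr, codes, count)
  invisible(x)
}

.smer_codes <- function(smers, p) {
  if (p$s > .MAX_NUMERIC_S)
    stop("direct s-mer operations on s > ", .MAX_NUMERIC_S,
         " use the build/query interfaces")
  codes <- .encode_smer_cpp(smers)
  if (p$canonical) {
    rc <- .encode_smer_cpp(.revcomp_cpp(smers))
    codes <- pmin(codes, rc)
  }
  codes
}

#' Query stored s-mer abundances
#'
#' Looks each s-mer up directly in the filter (no fimpera windowing). The
#' injective hash makes the answer exact: no false positives and no false
#' negatives at the s-mer level.
#'
#' @param x a `bqf` index.
#' @param smers character vector of s-mers.
#' @return data frame with columns `smer`, `present`, `count` (0 when
#'   absent), and `saturated` (`TRUE` when the stored counter hit its cap
#'   `2^c - 1`, so the true count is `>= 2^c - 1`).
#' @export
bqf_query_smer <- function(x, smers) {
  .check_bqf(x)
  p <- .params(x)
  smers <- as.character(smers)
  if (any(nchar(smers) != p$s)) stop("s-mers must have length s = ", p$s)
  stored <- .bqf_query_codes_cpp(x$ptr, .smer_codes(smers, p))
  cbind(data.frame(smer = smers), .decode_stored(stored, p$c, p$counter_mode))
}

#' Delete s-mers from the filter
#'
#' Removes elements and compacts their runs. Only exact-counter indexes
#' support deletion; absent elements trigger a warning and leave the filter
#' unchanged.
#'
#' @param x a `bqf` index.
#' @param smers character vector of s-mers.
#' @return logical vector, `TRUE` where an element was removed, invisibly.
#' @export
bqf_delete <- function(x, smers) {
  .check_bqf(x)
  p <- .params(x)
  if (p$counter_mode != 0L)
    stop("deletion requires exact counters (log2 mode cannot be updated)")
  smers <- as.character(smers)
  if (any(nchar(smers) != p$s)) stop("s-mers must have length s = ", p$s)
  ok <- .bqf_delete_codes_cpp(x$ptr, .smer_codes(smers, p))
  if (any(!ok)) warning(sum(!ok), " element(s) not present; filter unchanged for those")
  invisible(ok)
}

#' Enumerate the stored s-mers
#'
#' Reconstructs every stored element by joining the run's quotient with the
#' stored remainder and inverting the hash, then decoding to the s-mer
#' string. Only s-mers can be enumerated (never the k-mers they emulate).
#'
#' @param x a `bqf` index.
#' @return data frame with columns `smer`, `count` (decoded per counter
#'   mode; a log2 index reports `2^stored` as a lower bound), `saturated`.
#' @export
bqf_smers <- function(x) {
  .check_bqf(x)
  p <- .params(x)
  e <- .bqf_enumerate_cpp(x$ptr)
  dec <- .decode_stored(e$stored, p$c, p$counter_mode)
  data.frame(smer = e$smer, count = dec$count, saturated = dec$saturated)
}

#' Double the number of slots
#'
#' Re-splits every element's unchanged 2s-bit hash with `q + 1` address bits
#' and r - 1 remainder bits; counters are preserved and the load factor
#' halves. Fails when r = 0 (the hash is fully consumed by the address).
#'
#' @param x a `bqf` index.
#' @return the index, invisibly.
#' @export
bqf_resize <- function(x) {
  .check_bqf(x)
  .bqf_resize_cpp(x$ptr)
  invisible(x)
}

#' Total size of the structure in bits
#'
#' Exactly `2^q * (r + c + 3)`: r remainder bits and c counter bits per
#' slot, plus 3 metadata bits per slot (occupied, runend, and the 64-bit
#' offset checkpoint amortized over each 64-slot block).
#'
#' @param x a `bqf` index.
#' @return numeric scalar (bits).
#' @export
bqf_size_bits <- function(x) {
  .check_bqf(x)
  .params(x)$size_bits
}

#' Load factor
#'
#' Stored elements divided by slot count. Automatic resizing keeps this at
#' or below 95% (whenever a remainder bit is available to promote).
#'
#' @param x a `bqf` index.
#' @return numeric scalar in `[0, 1]`.
#' @export
bqf_load_factor <- function(x) {
  .check_bqf(x)
  .params(x)$load_factor
}

#' Runend position of a quotient's run
#'
#' For an occupied quotient `i`, the slot holding the last remainder of the
#' run inserted at address `i`. The `"block"` method uses the per-block
#' offset checkpoints (the operational path); `"global"` evaluates
#' `Select(runends, Rank(occupieds, i))` naively in coordinates rotated to
#' an empty anchor slot (identical to the textbook formula whenever no run
#' wraps past the last slot), independently of the checkpoints.
#'
#' @param x a `bqf` index.
#' @param i slot index (0-based).
#' @param method `"block"` or `"global"`.
#' @return 0-based slot index, or `NA` if quotient `i` is unoccupied.
#' @export
bqf_runend_position <- function(x, i, method = c("block", "global")) {
  .check_bqf(x)
  method <- match.arg(method)
  res <- vapply(as.numeric(i), function(ii) {
    if (method == "block") .bqf_runend_cpp(x$ptr, ii)
    else .bqf_runend_global_cpp(x$ptr, ii)
  }, numeric(1))
  res[res < 0] <- NA_real_
  res
}

# internal: structural self-check (throws on violation)
.validate <- function(x) .bqf_validate_cpp(x$ptr)
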