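# File formats: counted-dump TSV, FASTA/FASTQ input, and the binary index
# serialization.

.BQF_MAGIC <- charToRaw("BQFX")
.BQF_VERSION <- 1L

#' Read a counted s-mer dump (KMC-style TSV)
#'
#' Each line is `SEQUENCE<TAB>COUNT`, no header. Malformed lines (wrong
#' field count, non-ACGT sequence, count below 1 or non-integer) raise an
#' error naming the offending line.
#'
#' @param path file path (plain or gzip; `gzfile` handles both).
#' @return data frame with columns `smer` (character), `count` (numeric).
#' @export
read_counted_tsv <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0)
    return(data.frame(smer = character(0), count = numeric(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("line ", bad[1], ": expected SEQUENCE<TAB>COUNT, got ",
         deparse(lines[bad[1]]), call. = FALSE)
  smer <- vapply(parts, `[[`, character(1), 1L)
  cnt_str <- vapply(parts, `[[`, character(1), 2L)
  cnt <- suppressWarnings(as.numeric(cnt_str))
  bad <- which(is.na(cnt) | cnt < 1 | cnt != floor(cnt))
  if (length(bad))
    stop("line ", bad[1], ": count must be an integer >= 1, got ",
         deparse(cnt_str[bad[1]]), call. = FALSE)
  bad <- which(grepl("[^ACGTacgt]", smer))
  if (length(bad))
    stop("line ", bad[1], ": sequence contains non-ACGT characters",
         call. = FALSE)
  data.frame(smer = toupper(smer), count = cnt)
}

#' Write a counted s-mer dump
#'
#' @param records data frame with columns `smer`, `count`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counted_tsv <- function(records, path) {
  writeLines(paste(records$smer, format(records$count, scientific = FALSE,
                                        trim = TRUE), sep = "\t"), path)
  invisible(path)
}

#' Read sequences from FASTA or FASTQ
#'
#' The format is auto-detected from the first byte of the (possibly
#' gzip-compressed, detected by magic bytes) file: `>` means FASTA, `@`
#' means FASTQ; quality lines are ignored. Sequences are uppercased.
#'
#' @param path file path.
#' @return named character vector of sequences, in file order.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- gzfile(path, "rt")  # transparently handles plain text too
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0 || !nzchar(first)) {
    warning("empty sequence file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  fmt <- if (startsWith(first, ">")) "fasta"
         else if (startsWith(first, "@")) "fastq"
         else stop("file is neither FASTA nor FASTQ: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Serialize an index to disk
#'
#' Little-endian binary layout: a fixed header (magic, version, geometry,
#' element count, hash-constant fingerprint) followed by the occupieds,
#' runends, offsets and slots sections as contiguous packed words. The
#' payload sections together hold exactly [bqf_size_bits()] bits.
#'
#' @param x a `bqf` index.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
bqf_save <- function(x, path) {
  .check_bqf(x)
  p <- .params(x)
  st <- .bqf_state_cpp(x$ptr)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.BQF_MAGIC, con)
  writeBin(as.integer(c(.BQF_VERSION, p$q, p$r, p$c, p$s, p$k,
                        as.integer(p$canonical), p$counter_mode)),
           con, size = 4L, endian = "little")
  writeBin(c(p$n, .hash_fingerprint_cpp()), con, size = 8L, endian = "little")
  writeBin(st$occupieds, con)
  writeBin(st$runends, con)
  writeBin(st$offsets, con)
  writeBin(st$slots, con)
  invisible(path)
}

#' Load a serialized index
#'
#' Refuses files with a wrong magic tag, version, inconsistent geometry
#' (`r` must equal `2s - q`), a different hash-constant fingerprint, or
#' truncated payload sections.
#'
#' @param path an index file written by [bqf_save()].
#' @return a `bqf` index handle.
#' @export
bqf_load <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (length(magic) < 4L || !identical(magic, .BQF_MAGIC))
    stop("not a bqf index file (bad magic tag)", call. = FALSE)
  ints <- readBin(con, "integer", 8L, size = 4L, endian = "little")
  if (length(ints) < 8L) stop("truncated index header", call. = FALSE)
  version <- ints[1]; q <- ints[2]; r <- ints[3]; c <- ints[4]
  s <- ints[5]; k <- ints[6]; canonical <- ints[7] == 1L; mode <- ints[8]
  if (version != .BQF_VERSION)
    stop("unsupported index format version ", version, call. = FALSE)
  if (r != 2L * s - q)
    stop("corrupt header: r != 2s - q", call. = FALSE)
  dbls <- readBin(con, "numeric", 2L, size = 8L, endian = "little")
  if (length(dbls) < 2L) stop("truncated index header", call. = FALSE)
  n <- dbls[1]
  if (dbls[2] != .hash_fingerprint_cpp())
    stop("index was built with different hash constants", call. = FALSE)
  nslots <- 2^q
  sect <- function(nbytes) {
    r <- readBin(con, "raw", nbytes)
    if (length(r) < nbytes) stop("truncated index payload", call. = FALSE)
    r
  }
  occ <- sect(nslots / 8)
  rend <- sect(nslots / 8)
  off <- sect(nslots / 64 * 8)
  slots <- sect(nslots * (r + c) / 8)
  .new_handle(.bqf_from_state_cpp(q, s, k, c, canonical, mode, n,
                                  occ, rend, off, slots))
}

#' Index statistics
#'
#' @param x a `bqf` index.
#' @return a list with the geometry (`q`, `r`, `c`, `s`, `k`), element
#'   count `n`, `load_factor`, `size_bits`, `size_bytes`, bits per element,
#'   and the number of 64-slot blocks (= offset checkpoints).
#' @export
bqf_stats <- function(x) {
  .check_bqf(x)
  p <- .params(x)
  list(q = p$q, r = p$r, c = p$c, s = p$s, k = p$k, n = p$n,
       n_slots = p$n_slots, n_blocks = p$n_blocks,
       load_factor = p$load_factor,
       size_bits = p$size_bits, size_bytes = p$size_bits / 8,
       bits_per_element = if (p$n > 0) p$size_bits / p$n else NA_real_,
       canonical = p$canonical,
       counter_mode = if (p$counter_mode == 0) "exact" else "log2")
}
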