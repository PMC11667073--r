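# 2-bit DNA codec and the invertible 2s-bit hash.
#
# The numeric R-level helpers are exact for words up to 26 nt (2s <= 52 bits,
# within double precision). Longer words (up to 31 nt) are fully supported
# inside the index, which works on 64-bit integers in C++.

.MAX_NUMERIC_S <- 26L

.check_numeric_s <- function(s) {
  if (s < 1L || s > .MAX_NUMERIC_S)
    stop("numeric codec helpers support word lengths 1..", .MAX_NUMERIC_S,
         " (2s must fit double precision); got s = ", s, call. = FALSE)
}

#' Encode DNA words as base-4 integers
#'
#' Maps `A=0, C=1, G=2, T=3`, most-significant digit first, so the encoding
#' is strictly monotone in lexicographic order and the complement of a digit
#' is `3 - digit`. Lowercase input is accepted (soft-masked FASTA is common).
#'
#' @param seq character vector of ACGT words, each at most 26 nt.
#' @return numeric vector of codes in `[0, 4^s)`.
#' @examples
#' encode_smer("ACGT")  # 27
#' @seealso [decode_smer()], [hash_smer_code()]
#' @export
encode_smer <- function(seq) {
  seq <- as.character(seq)
  ns <- nchar(seq)
  if (any(ns < 1L | ns > .MAX_NUMERIC_S))
    stop("words must be 1..", .MAX_NUMERIC_S, " nt for the numeric codec")
  .encode_smer_cpp(seq)
}

#' Decode base-4 integer codes back to DNA words
#'
#' Exact inverse of [encode_smer()] at the stated word length.
#'
#' @param code numeric vector of codes in `[0, 4^s)`.
#' @param s word length in nucleotides (1..26).
#' @return character vector of ACGT words.
#' @export
decode_smer <- function(code, s) {
  s <- as.integer(s)
  .check_numeric_s(s)
  .decode_smer_cpp(as.numeric(code), s)
}

#' Reverse complement of DNA words
#'
#' @param seq character vector of ACGT words.
#' @return character vector.
#' @export
revcomp_dna <- function(seq) {
  .revcomp_cpp(as.character(seq))
}

#' Canonical form of DNA words
#'
#' Returns the smaller of a word and its reverse complement under the
#' [encode_smer()] ordering (equivalently, lexicographic with A<C<G<T).
#' `canonical_smer()` is idempotent and identifies a word with its reverse
#' complement.
#'
#' @param seq character vector of ACGT words.
#' @return character vector of canonical words.
#' @export
canonical_smer <- function(seq) {
  .canonical_cpp(as.character(seq))
}

#' Invertible 2s-bit hash of s-mer codes
#'
#' A fixed bijection on `[0, 4^s)` built from invertible steps: xor with a
#' right shift by s bits (an involution at this width) and multiplication by
#' fixed odd constants modulo `2^(2s)`. The same constants are used for every
#' s and are fingerprinted in serialized index headers. The top q bits of the
#' hash address a slot (the quotient) and the remaining r = 2s - q bits are
#' stored as the remainder.
#'
#' @param x numeric vector of s-mer codes in `[0, 4^s)`.
#' @param s word length in nucleotides (1..26 for the numeric helper).
#' @return numeric vector of hash values in `[0, 4^s)`.
#' @seealso [unhash_smer_code()]
#' @export
hash_smer_code <- function(x, s) {
  s <- as.integer(s)
  .check_numeric_s(s)
  x <- as.numeric(x)
  if (any(x < 0 | x >= 4^s)) stop("codes must lie in [0, 4^s)")
  .hash2s_cpp(x, s)
}

#' Invert the 2s-bit hash
#'
#' Exact inverse of [hash_smer_code()]: each step is inverted in reverse
#' order, the odd multipliers through their modular inverses.
#'
#' @param y numeric vector of hash values in `[0, 4^s)`.
#' @param s word length in nucleotides (1..26 for the numeric helper).
#' @return numeric vector of s-mer codes.
#' @export
unhash_smer_code <- function(y, s) {
  s <- as.integer(s)
  .check_numeric_s(s)
  y <- as.numeric(y)
  if (any(y < 0 | y >= 4^s)) stop("hash values must lie in [0, 4^s)")
  .unhash2s_cpp(y, s)
}

#' Rank over a bitvector
#'
#' Number of set bits in `v[0..i]` inclusive, with `i` a 0-based position —
#' the Rank primitive the filter uses over its occupieds vector.
#'
#' @param v logical (or 0/1) vector.
#' @param i 0-based position.
#' @return integer count.
#' @export
rank_bits <- function(v, i) {
  v <- as.logical(v)
  if (anyNA(v)) stop("bitvector contains NA")
  .rank_bits_cpp(v, as.integer(i))
}

#' Select over a bitvector
#'
#' 0-based position of the j-th set bit (j counted from 1) — the Select
#' primitive the filter uses over its runends vector. Returns `NA` when the
#' vector has fewer than `j` set bits.
#'
#' @param v logical (or 0/1) vector.
#' @param j which set bit to locate (>= 1).
#' @return 0-based position, or `NA_integer_`.
#' @export
select_bits <- function(v, j) {
  v <- as.logical(v)
  if (anyNA(v)) stop("bitvector contains NA")
  res <- .select_bits_cpp(v, as.integer(j))
  if (res < 0) NA_integer_ else res
}
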