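# Test helpers: random DNA, an independent canonical-layout oracle for the
# quotient filter, and naive rank/select references.

rand_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = "")
  }, character(1))
}

# naive bit-scan references for rank/select
rank_naive <- function(v, i) sum(v[seq_len(i + 1)])
select_naive <- function(v, j) {
  w <- which(as.logical(v))
  if (length(w) < j) NA_integer_ else w[j] - 1L
}

# Independent reconstruction of the unique slot layout of a circular
# quotient filter from its element set: runs are placed greedily in
# quotient order (each run as early as possible at/after its home slot,
# after the previous run), iterated to a fixpoint to resolve wrap-around.
# Returns occupieds/runends bitvectors and the runend slot per quotient.
ref_layout <- function(quot, rem, N) {
  stopifnot(length(quot) == length(rem), length(quot) < N)
  ord <- order(quot, rem)
  quot <- quot[ord]; rem <- rem[ord]
  qs <- unique(quot)
  lens <- as.integer(table(factor(quot, levels = qs)))
  m <- length(qs)
  starts <- numeric(m)
  carry <- qs[1]
  repeat {
    pos <- carry
    for (i in seq_len(m)) {
      starts[i] <- max(qs[i], pos)
      pos <- starts[i] + lens[i]
    }
    newcarry <- max(qs[1], pos - N)
    if (newcarry <= carry) break
    carry <- newcarry
  }
  occ <- logical(N); rend <- logical(N)
  occ[qs + 1] <- TRUE
  ends <- (starts + lens - 1) %% N
  rend[ends + 1] <- TRUE
  slot_of <- rep(NA_real_, N)  # remainder stored in each slot
  off <- 0
  for (i in seq_len(m)) {
    idx <- (starts[i] + seq_len(lens[i]) - 1) %% N
    slot_of[idx + 1] <- rem[off + seq_len(lens[i])]
    off <- off + lens[i]
  }
  list(occ = occ, rend = rend, quotients = qs, runends = ends,
       slot_rem = slot_of)
}

# decode the packed occupieds/runends sections of a filter into logicals
state_bits <- function(x) {
  st <- bqf:::.bqf_state_cpp(x$ptr)
  p <- bqf:::.params(x)
  N <- p$n_slots
  list(occ = as.logical(rawToBits(st$occupieds))[seq_len(N)],
       rend = as.logical(rawToBits(st$runends))[seq_len(N)])
}

# insert elements with a prescribed (quotient, remainder) split by inverting
# the hash; returns the s-mer codes used
codes_for <- function(x, quot, rem) {
  p <- bqf:::.params(x)
  h <- quot * 2^p$r + rem
  unhash_smer_code(h, p$s)
}

insert_qr <- function(x, quot, rem, count = 1) {
  codes <- codes_for(x, quot, rem)
  bqf:::.bqf_insert_codes_cpp(x$ptr, codes, rep_len(count, length(codes)))
  codes
}
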