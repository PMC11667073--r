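# The user-facing index: building from counts/reads and answering k-mer
# queries as the minimum over constituent s-mer abundances.

test_that("stored counters saturate at 2^c - 1 and min_count filters records", {
  cnts <- data.frame(smer = c("AAACT", "CCGTA", "ACGGG"), count = c(2, 40, 31))
  x <- bqf_build(counts = cnts, k = 7, s = 5, c = 5, canonical = FALSE)
  res <- bqf_query_smer(x, cnts$smer)
  expect_equal(res$count, c(2, 31, 31))
  expect_equal(res$saturated, c(FALSE, TRUE, TRUE))
  # the "present at least twice" convention drops count-1 records
  cnts2 <- data.frame(smer = c("AAACT", "CCGTA"), count = c(1, 3))
  y <- bqf_build(counts = cnts2, k = 7, s = 5, min_count = 2, canonical = FALSE)
  expect_equal(bqf:::.params(y)$n, 1)
  expect_false(bqf_query_smer(y, "AAACT")$present)
  # empty input still yields a valid empty index
  z <- bqf_build(counts = data.frame(smer = character(0), count = numeric(0)),
                 k = 7, s = 5)
  expect_equal(bqf:::.params(z)$n, 0)
  expect_false(bqf_query_kmer(z, "ACGTACG")$present)
})

test_that("malformed count records are rejected with their position", {
  expect_error(bqf_build(counts = data.frame(smer = c("AAACT", "ACG"),
                                             count = c(1, 2)),
                         k = 7, s = 5), "record 2")
  expect_error(bqf_build(counts = data.frame(smer = "AANCT", count = 1),
                         k = 7, s = 5), "position 3")
  expect_warning(bqf_build(counts = data.frame(smer = c("AAACT", "AAACT"),
                                               count = c(1, 2)),
                           k = 7, s = 5, canonical = FALSE), "merged")
})

test_that("count_smers enumerates windows exactly", {
  # the 5 windows of ACGTACGT: ACGT, CGTA, GTAC, TACG, ACGT
  res <- count_smers("ACGTACGT", s = 4, canonical = FALSE)
  expect_equal(res$count[match(c("ACGT", "CGTA", "GTAC", "TACG"), res$smer)],
               c(2, 1, 1, 1))
  expect_equal(sum(res$count), 5)
  # reads shorter than s contribute nothing
  expect_equal(nrow(count_smers(c("ACG", "A", ""), s = 4)), 0)
  # windows containing non-ACGT are skipped
  res2 <- count_smers("ACGNACGT", s = 4, canonical = FALSE)
  expect_equal(res2$smer, "ACGT")
})

test_that("count_smers agrees with a naive dictionary counter", {
  set.seed(31)
  for (canonical in c(FALSE, TRUE)) {
    reads <- rand_dna(50, sample(20:60, 50, replace = TRUE))
    s <- 5
    got <- count_smers(reads, s, canonical = canonical)
    wins <- unlist(lapply(reads, function(rd) {
      L <- nchar(rd)
      if (L < s) return(character(0))
      substring(rd, 1:(L - s + 1), s:L)
    }))
    if (canonical) wins <- canonical_smer(wins)
    want <- table(wins)
    expect_equal(nrow(got), length(want))
    expect_equal(got$count[match(names(want), got$smer)], as.numeric(want))
  }
})

test_that("a k-mer reports the minimum abundance of its s-mers", {
  # k = 5, s = 3: the three s-mers of ACGTA with counts 4, 2, 7
  cnts <- data.frame(smer = c("ACG", "CGT", "GTA"), count = c(4, 2, 7))
  x <- bqf_build(counts = cnts, k = 5, s = 3, c = 5, canonical = FALSE)
  res <- bqf_query_kmer(x, "ACGTA")
  expect_true(res$present)
  expect_equal(res$count, 2)
  # absent as soon as any s-mer is absent
  y <- bqf_build(counts = cnts[-2, ], k = 5, s = 3, c = 5, canonical = FALSE)
  expect_false(bqf_query_kmer(y, "ACGTA")$present)
  expect_equal(bqf_query_kmer(y, "ACGTA")$count, 0)
})

test_that("with s = k the index answers like the plain filter", {
  set.seed(32)
  reads <- rand_dna(30, 40)
  x <- bqf_build(reads = reads, k = 9, s = 9, c = 5)
  probe <- c(substring(reads[1], 1, 9), rand_dna(50, 9))
  a <- bqf_query_kmer(x, probe)
  b <- bqf_query_smer(x, probe)
  expect_identical(a$present, b$present)
  expect_identical(a$count, b$count)
  # and equals a capped counting dictionary
  truthc <- count_smers(reads, 9, canonical = TRUE)
  probe_can <- canonical_smer(probe)
  want <- pmin(31, truthc$count[match(probe_can, truthc$smer)])
  want[is.na(want)] <- 0
  expect_equal(a$count, want)
})

test_that("sliding-window queries equal naive per-k-mer queries", {
  set.seed(33)
  reads <- rand_dna(40, 50)
  x <- bqf_build(reads = reads, k = 11, s = 7, c = 4)
  seqs <- c(rand_dna(5, 200), reads[1], substr(reads[2], 1, 11))
  res <- bqf_query_sequence(x, seqs)
  naive <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    L <- nchar(seqs[i])
    kmers <- substring(seqs[i], 1:(L - 11 + 1), 11:L)
    bqf_query_kmer(x, kmers)
  }))
  expect_equal(nrow(res), sum(pmax(0, nchar(seqs) - 11 + 1)))
  expect_identical(res$present, naive$present)
  expect_identical(res$count, naive$count)
  expect_identical(res$saturated, naive$saturated)
  # a window containing N is absent; its neighbors are untouched
  sq <- paste0(substr(reads[1], 1, 11), "N", substr(reads[1], 12, 22))
  rs <- bqf_query_sequence(x, sq)
  expect_true(rs$present[1])
  expect_false(rs$present[2])
  # sequences shorter than k produce no rows
  expect_equal(nrow(bqf_query_sequence(x, "ACGTACGT")), 0)
})

test_that("no construction false negatives: every indexed k-mer is found", {
  set.seed(34)
  reads <- rand_dna(30, 80)
  x <- bqf_build(reads = reads, k = 13, s = 8, c = 5)
  res <- bqf_query_sequence(x, reads)
  expect_true(all(res$present))
  # and any k-mer reported present has all of its s-mers genuinely in the reads
  smer_truth <- count_smers(reads, 8, canonical = TRUE)
  probes <- rand_dna(3000, 13)
  pres <- bqf_query_kmer(x, probes)$present
  for (p in probes[pres]) {
    subs <- canonical_smer(substring(p, 1:6, 8:13))
    expect_true(all(subs %in% smer_truth$smer))
  }
})

test_that("log2 counters store orders of magnitude and refuse updates", {
  cnts <- data.frame(smer = c("AAACT", "CCGTA", "ACGGG"), count = c(1, 9, 300))
  x <- bqf_build(counts = cnts, k = 7, s = 5, c = 3, canonical = FALSE,
                 counter_mode = "log2")
  res <- bqf_query_smer(x, cnts$smer)
  # floor(log2(c(1, 9, 300))) = 0, 3, 8 -> capped at 7
  expect_equal(res$count, c(2^0, 2^3, 2^7))
  expect_equal(res$saturated, c(FALSE, FALSE, TRUE))
  expect_error(bqf_insert(x, "AAACT", 2), "log2")
  expect_error(bqf_delete(x, "AAACT"), "exact")
})

test_that("enumerated records rebuild into an equivalent index", {
  set.seed(35)
  reads <- rand_dna(20, 60)
  x <- bqf_build(reads = reads, k = 10, s = 6, c = 5)
  recs <- bqf_smers(x)
  expect_equal(nrow(recs), bqf:::.params(x)$n)
  y <- bqf_build(counts = recs[, c("smer", "count")], k = 10, s = 6, c = 5)
  probe <- rand_dna(1000, 10)
  expect_identical(bqf_query_kmer(x, probe), bqf_query_kmer(y, probe))
})

test_that("interface guards: lengths and parameter constraints", {
  x <- bqf_build(counts = data.frame(smer = "ACGTA", count = 1), k = 7, s = 5)
  expect_error(bqf_query_kmer(x, "ACGT"), "length k")
  expect_error(bqf_query_smer(x, "ACGTAA"), "length s")
  expect_error(bqf_build(counts = data.frame(smer = "ACGTA", count = 1),
                         k = 4, s = 5), "s must be <= k")
})
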