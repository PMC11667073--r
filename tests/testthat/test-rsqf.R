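# The rank-and-select quotient filter: runs, shifting, offsets, resize,
# delete, and the size accounting.

new_filter <- function(q = 6, s = 6, c = 5, k = s) {
  bqf_new(s = s, k = k, c = c, q = q, canonical = FALSE)
}

test_that("a lone element sits in its home slot with both metadata bits", {
  x <- new_filter()
  insert_qr(x, quot = 3, rem = 7)
  bits <- state_bits(x)
  expect_true(bits$occ[4])   # occupied[3]
  expect_true(bits$rend[4])  # runend[3]
  expect_equal(bqf_runend_position(x, 3), 3)
  expect_true(bqf:::.validate(x))
})

test_that("remainders sharing a quotient form a run in ascending order", {
  x <- new_filter()
  insert_qr(x, quot = c(8, 8, 8), rem = c(30, 10, 20))  # out of order on purpose
  expect_equal(bqf_runend_position(x, 8), 10)  # run occupies slots 8, 9, 10
  bits <- state_bits(x)
  expect_identical(which(bits$rend) - 1L, 10L)
  st <- ref_layout(c(8, 8, 8), c(30, 10, 20), 64)
  expect_identical(state_bits(x)$occ, st$occ)
  expect_identical(state_bits(x)$rend, st$rend)
  # three singleton runs on consecutive quotients stay in place
  y <- new_filter()
  insert_qr(y, quot = c(13, 14, 15), rem = c(5, 6, 7))
  for (i in 13:15) expect_equal(bqf_runend_position(y, i), i)
})

test_that("layout equals the greedy canonical reconstruction, incl. wrap-around", {
  set.seed(21)
  for (rep in 1:40) {
    N <- 64
    x <- new_filter(q = 6)
    m <- sample(10:55, 1)
    # bias quotients toward the end of the table to exercise wrap-around
    quot <- sample(0:63, m, replace = TRUE, prob = c(rep(1, 48), rep(4, 16)))
    rem <- sample(0:63, m, replace = TRUE)
    keep <- !duplicated(paste(quot, rem))
    quot <- quot[keep]; rem <- rem[keep]
    insert_qr(x, quot, rem)
    ref <- ref_layout(quot, rem, N)
    bits <- state_bits(x)
    expect_identical(bits$occ, ref$occ)
    expect_identical(bits$rend, ref$rend)
    for (i in seq_along(ref$quotients)) {
      expect_equal(bqf_runend_position(x, ref$quotients[i]), ref$runends[i])
    }
    expect_true(bqf:::.validate(x))
  }
})

test_that("block-offset runend equals the global rank/select formula", {
  set.seed(22)
  for (rep in 1:25) {
    q <- sample(6:8, 1)
    x <- new_filter(q = q)
    N <- 2^q
    r <- 2 * 6 - q
    m <- floor(N * runif(1, 0.2, 0.9))
    quot <- sample(0:(N - 1), m, replace = TRUE)
    rem <- sample(0:(2^r - 1), m, replace = TRUE)
    keep <- !duplicated(paste(quot, rem))
    insert_qr(x, quot[keep], rem[keep])
    for (i in 0:(N - 1)) {
      a <- bqf_runend_position(x, i, "block")
      b <- bqf_runend_position(x, i, "global")
      expect_identical(is.na(a), is.na(b))
      if (!is.na(a)) expect_equal(a, b)
    }
  }
})

test_that("the raw (unrotated) global formula holds when no run wraps", {
  set.seed(23)
  x <- new_filter(q = 6)
  quot <- sample(5:50, 30, replace = TRUE)  # keep clear of the table ends
  rem <- sample(0:63, 30)
  keep <- !duplicated(paste(quot, rem))
  insert_qr(x, quot[keep], rem[keep])
  bits <- state_bits(x)
  for (i in unique(quot[keep])) {
    d <- rank_bits(bits$occ, i)
    expect_equal(bqf_runend_position(x, i), select_bits(bits$rend, d))
  }
})

test_that("duplicate insertion merges counters with saturation", {
  x <- new_filter(c = 5)
  code <- decode_smer(1234, 6)
  bqf_insert(x, code, 2)
  bqf_insert(x, code, 3)
  res <- bqf_query_smer(x, code)
  expect_equal(res$count, 5)
  expect_false(res$saturated)
  bqf_insert(x, code, 100)
  res <- bqf_query_smer(x, code)
  expect_equal(res$count, 31)  # capped at 2^c - 1
  expect_true(res$saturated)
  expect_equal(bqf:::.params(x)$n, 1)
})

test_that("query on an empty filter is absent; counters answer exactly", {
  x <- new_filter()
  res <- bqf_query_smer(x, decode_smer(0:9, 6))
  expect_false(any(res$present))
  expect_true(all(res$count == 0))
})

test_that("membership is exact over an exhaustive small universe", {
  # s = 6: insert a known subset of all 4^6 s-mers, query the whole universe
  set.seed(24)
  univ <- 0:(4^6 - 1)
  inset <- sort(sample(univ, 800))
  x <- bqf_new(s = 6, c = 3, q = 10, canonical = FALSE)
  bqf:::.bqf_insert_codes_cpp(x$ptr, inset, rep(1, length(inset)))
  res <- bqf:::.bqf_query_codes_cpp(x$ptr, univ)
  expect_identical(res >= 0, univ %in% inset)  # zero FP and zero FN
})

test_that("resize preserves every element and halves the load factor", {
  set.seed(25)
  x <- bqf_new(s = 9, c = 5, q = 8, canonical = FALSE)
  codes <- sample(0:(4^9 - 1), 200)
  cnts <- sample(1:31, 200, replace = TRUE)
  bqf:::.bqf_insert_codes_cpp(x$ptr, codes, cnts)
  before <- bqf_smers(x)
  lf <- bqf_load_factor(x)
  n_before <- bqf:::.params(x)$n
  bqf_resize(x)
  expect_equal(bqf:::.params(x)$n, n_before)
  expect_equal(bqf_load_factor(x), lf / 2)
  after <- bqf_smers(x)
  expect_equal(before[order(before$smer), ], after[order(after$smer), ],
               ignore_attr = TRUE)
  expect_true(bqf:::.validate(x))
  # resize of an empty filter: empty, twice the slots
  y <- bqf_new(s = 6, c = 2, q = 6, canonical = FALSE)
  bqf_resize(y)
  p <- bqf:::.params(y)
  expect_equal(p$q, 7)
  expect_equal(p$n, 0)
})

test_that("automatic doubling fires exactly past the 95% load threshold", {
  x <- bqf_new(s = 7, c = 2, q = 7, canonical = FALSE)  # 128 slots
  codes <- 0:121
  for (i in 1:121) {
    bqf:::.bqf_insert_codes_cpp(x$ptr, codes[i], 1)
    expect_lte(bqf_load_factor(x), 0.95)
  }
  expect_equal(bqf:::.params(x)$q, 7)  # 121/128 = 0.945: no resize yet
  bqf:::.bqf_insert_codes_cpp(x$ptr, codes[122], 1)
  p <- bqf:::.params(x)
  expect_equal(p$q, 8)                 # (121+1)/128 > 0.95 triggered doubling
  expect_equal(p$n, 122)
  expect_equal(bqf_load_factor(x), 122 / 256)
})

test_that("delete removes elements, compacts runs, and repairs metadata", {
  x <- new_filter()
  code <- decode_smer(777, 6)
  bqf_insert(x, code, 4)
  bqf_delete(x, code)
  expect_false(bqf_query_smer(x, code)$present)
  expect_equal(bqf:::.params(x)$n, 0)
  # delete on an empty filter warns and leaves the state unchanged
  expect_warning(bqf_delete(x, code), "not present")
  expect_true(bqf:::.validate(x))
  # middle element of a 3-element run
  y <- new_filter()
  cds <- insert_qr(y, quot = c(20, 20, 20), rem = c(3, 9, 15))
  bqf:::.bqf_delete_codes_cpp(y$ptr, cds[2])
  left <- bqf:::.bqf_query_codes_cpp(y$ptr, cds)
  expect_identical(left >= 0, c(TRUE, FALSE, TRUE))
  expect_equal(bqf_runend_position(y, 20), 21)
  expect_true(bqf:::.validate(y))
})

test_that("randomized delete interleaving matches a dictionary oracle", {
  set.seed(26)
  x <- bqf_new(s = 8, c = 5, q = 7, canonical = FALSE)
  oracle <- numeric(0)
  cap <- 31
  for (round in 1:40) {
    codes <- sample(0:(4^8 - 1), 30, replace = TRUE)
    cnts <- sample(1:40, 30, replace = TRUE)
    bqf:::.bqf_insert_codes_cpp(x$ptr, codes, cnts)
    for (i in seq_along(codes)) {
      key <- as.character(codes[i])
      oracle[key] <- min(cap, ifelse(is.na(oracle[key]), 0, oracle[key]) + cnts[i])
    }
    dels <- sample(codes, 8)
    bqf:::.bqf_delete_codes_cpp(x$ptr, dels)
    oracle <- oracle[!(names(oracle) %in% as.character(dels))]
    probe <- unique(c(codes, sample(0:(4^8 - 1), 40)))
    got <- bqf:::.bqf_query_codes_cpp(x$ptr, probe)
    want <- unname(oracle[as.character(probe)])
    want[is.na(want)] <- -1
    expect_identical(got, want)
    expect_true(bqf:::.validate(x))
  }
})

test_that("size accounting is exactly 2^q x (r + c + 3)", {
  x <- bqf_new(s = 19, k = 31, c = 5, q = 10, canonical = FALSE)
  expect_equal(bqf_size_bits(x), 36864)  # 2^10 * (28 + 5 + 3)
  bqf_resize(x)
  expect_equal(bqf_size_bits(x), 71680)  # 2^11 * (27 + 5 + 2 + 1)
  # metadata share is exactly 3 bits/slot: occupied + runend + amortized offset
  p <- bqf:::.params(x)
  expect_equal(p$size_bits - p$n_slots * (p$r + p$c), 3 * p$n_slots)
})

test_that("load factor is n / 2^q", {
  x <- bqf_new(s = 7, c = 2, q = 7, canonical = FALSE)
  expect_equal(bqf_load_factor(x), 0)
  bqf:::.bqf_insert_codes_cpp(x$ptr, 0:63, rep(1, 64))
  expect_equal(bqf_load_factor(x), 0.5)
})

test_that("enumerate-then-rebuild reproduces identical query behavior", {
  set.seed(27)
  x <- bqf_new(s = 8, c = 4, q = 8, canonical = FALSE)
  codes <- sample(0:(4^8 - 1), 150)
  bqf:::.bqf_insert_codes_cpp(x$ptr, codes, sample(1:15, 150, replace = TRUE))
  recs <- bqf_smers(x)
  y <- bqf_build(counts = data.frame(smer = recs$smer, count = recs$count),
                 k = 8, s = 8, c = 4, canonical = FALSE)
  probe <- decode_smer(sample(0:(4^8 - 1), 500), 8)
  expect_identical(bqf_query_smer(x, probe), bqf_query_smer(y, probe))
})
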