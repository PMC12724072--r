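test_that("banded rows: aligned strings and single edits behave as expected", {
  s <- "ACGTACGTA"
  m <- banded_rows(s, s, 2)
  expect_equal(m[nchar(s) + 1, nchar(s) + 1], 0)    # identical strings
  del <- "ACGTCGTA"                                  # one char deleted
  m2 <- banded_rows(s, del, 2)
  expect_equal(m2[nchar(del) + 1, nchar(s) + 1], 1)
  # band boundary: cells outside |i - j| <= k are NA
  expect_true(is.na(banded_rows(s, s, 1)[1, 4]))
})

test_that("bit-parallel rows equal scalar rows on random triples", {
  set.seed(515)
  for (r in 1:2000) {
    k <- sample(0:13, 1)
    pat <- sample(1:4, sample(1:40, 1), replace = TRUE)
    txt <- sample(1:5, sample(1:40, 1), replace = TRUE)   # incl. fifth char
    expect_identical(banded_rows(pat, txt, k, "bitparallel"),
                     banded_rows(pat, txt, k, "scalar"))
  }
})

test_that("single-row scalar updates reproduce the banded matrix rows", {
  set.seed(525)
  for (r in 1:25) {
    k <- sample(0:4, 1)
    pat <- rand_text(sample(5:15, 1))
    txt <- rand_text(sample(5:15, 1))
    ref <- banded_rows(pat, txt, k, "scalar")
    row <- band_row_init(pat, k)
    for (i in 1:nchar(txt)) {
      row <- band_row_update(row, substr(txt, i, i), pat, k)
      got <- ifelse(is.finite(row), pmin(row, k + 1), NA_integer_)
      expect_equal(unname(got), unname(ref[i + 1, ]))
    }
  }
})

test_that("execute_search finds planted occurrences", {
  set.seed(535)
  txt <- rand_text(1200)
  idx <- build_index(c(x = txt))
  st <- 400
  pat <- substr(txt, st + 1, st + 50)
  # k = 0: single exact search
  s0 <- pigeonhole_scheme(0)$searches[[1]]
  occ <- execute_search(idx, pat, s0, uniform_partition(50, 1), 0)
  expect_true(any(occ$start == st & occ$d == 0))
  # pigeonhole k = 1 on a read with one substitution: found at d = 1
  pat2 <- pat
  substr(pat2, 25, 25) <- setdiff(BASES, substr(pat, 25, 25))[1]
  sch <- pigeonhole_scheme(1)
  cand <- do.call(rbind, lapply(sch$searches, function(s)
    execute_search(idx, pat2, s, uniform_partition(50, 2), 1)))
  expect_true(any(cand$start == st & cand$d == 1))
})

test_that("all mode is lossless against the scalar-DP oracle", {
  set.seed(545)
  for (rep in 1:12) {
    n <- sample(300:2500, 1)
    txt <- rand_text(n)
    idx <- build_index(c(x = txt))
    for (r2 in 1:4) {
      k <- sample(0:4, 1)
      m <- sample((max(2, k + 2)):60, 1)
      m <- max(m, 5 * (k + 1))
      st <- sample(n - m, 1)
      pat <- mutate_seq(substr(txt, st + 1, st + m), sample(0:k, 1))
      if (nchar(pat) <= k) next
      occ <- approximate_match(idx, pat, k, cluster = FALSE)
      expect_identical(sort(unique(occ$end)),
                       as.numeric(sort(oracle_ends(txt, pat, k))))
    }
  }
})

test_that("k = 0 matching equals exact location", {
  set.seed(555)
  txt <- rand_text(900)
  idx <- build_index(c(x = txt))
  pat <- substr(txt, 101, 130)
  occ <- approximate_match(idx, pat, 0, cluster = FALSE)
  expect_identical(sort(occ$start), as.numeric(naive_occ(txt, pat)))
  expect_true(all(occ$d == 0))
})

test_that("output is invariant to partition, scheme, and in-text threshold", {
  set.seed(565)
  for (rep in 1:15) {
    n <- sample(300:1500, 1)
    txt <- rand_text(n)
    idx <- build_index(c(x = txt))
    k <- sample(1:3, 1)
    m <- sample(30:60, 1)
    st <- sample(n - m, 1)
    pat <- mutate_seq(substr(txt, st + 1, st + m), sample(0:k, 1))
    base <- approximate_match(idx, pat, k, partition = "uniform",
                              in_text_threshold = 4)
    expect_identical(approximate_match(idx, pat, k, partition = "dynamic"), base)
    expect_identical(approximate_match(idx, pat, k, scheme = trivial_scheme(k),
                                       partition = "uniform"), base)
    for (thr in c(1, 64))
      expect_identical(approximate_match(idx, pat, k, partition = "uniform",
                                         in_text_threshold = thr), base)
  }
})

test_that("in-text verification agrees with its contract", {
  expect_equal(4, formals(approximate_match)$in_text_threshold)  # default
  slice <- "ACGTTGCA"
  v <- in_text_verify(slice, slice, 0)
  expect_true(any(v$start == 0 & v$end == 8 & v$d == 0))
  # empty remaining pattern: zero-length completions, distance unchanged
  v2 <- in_text_verify(slice, "", 0)
  expect_true(all(v2$d == 0) && all(v2$start == v2$end))
  # anchor shifts coordinates into global space
  v3 <- in_text_verify(slice, slice, 0, anchor = 100)
  expect_true(any(v3$start == 100 & v3$end == 108))
})

test_that("dedupe collapses identical tuples and is idempotent", {
  occ <- data.frame(start = c(5, 5, 9), end = c(15, 15, 19), d = c(1, 1, 2))
  dd <- dedupe_occurrences(occ)
  expect_equal(nrow(dd), 2)
  expect_identical(dedupe_occurrences(dd), dd)
  # distinct tuples untouched
  occ2 <- data.frame(start = c(1, 2), end = c(10, 11), d = c(1, 1))
  expect_equal(nrow(dedupe_occurrences(occ2)), 2)
})

test_that("clustering keeps minimal-distance leftmost-longest representatives", {
  occ <- data.frame(start = c(100, 101), end = c(110, 110), d = c(1, 1))
  cl <- cluster_occurrences(occ)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$start, 100)
  occ2 <- data.frame(start = c(100, 100), end = c(110, 111), d = c(2, 1))
  cl2 <- cluster_occurrences(occ2)
  expect_equal(cl2$d, 1)
  expect_equal(cl2$end, 111)
  # non-overlapping occurrences are never merged
  occ3 <- data.frame(start = c(100, 200), end = c(110, 210), d = c(1, 0))
  expect_equal(nrow(cluster_occurrences(occ3)), 2)
  # every oracle hit is covered by a representative with d <= oracle d
  set.seed(575)
  txt <- rand_text(1000)
  idx <- build_index(c(x = txt))
  pat <- mutate_seq(substr(txt, 301, 350), 2)
  k <- 3
  reps <- approximate_match(idx, pat, k)          # clustered
  for (e in oracle_ends(txt, pat, k)) {
    covering <- reps$start < e + k + 1 & reps$end >= e - k
    expect_true(any(covering))
    d_or <- sellers_scan(txt, pat)[e + 1]
    expect_true(min(reps$d[covering]) <= d_or)
  }
})

test_that("all-best strata match the oracle minimum", {
  set.seed(585)
  txt <- rand_text(1500)
  idx <- build_index(c(x = txt))
  # exact hit present: stratum 0, no d > 0 records
  pat <- substr(txt, 701, 760)
  ab <- all_best_match(idx, pat, 3)
  expect_equal(ab$stratum, 0)
  expect_true(all(ab$occurrences$d == 0))
  # planted distance-2 read with k_max = 4
  pat2 <- pat
  substr(pat2, 10, 10) <- setdiff(BASES, substr(pat, 10, 10))[1]
  substr(pat2, 40, 40) <- setdiff(BASES, substr(pat, 40, 40))[1]
  or_min <- min(sellers_scan(txt, pat2))
  ab2 <- all_best_match(idx, pat2, 4)
  expect_equal(ab2$stratum, or_min)
  expect_equal(ab2$stratum, 2)
  # nothing within k_max: empty result, stratum NA
  ab3 <- all_best_match(idx, strrep("ACGT", 20), 0)
  expect_true(is.na(ab3$stratum) || min(sellers_scan(txt, strrep("ACGT", 20))) == 0)
  # argument guards
  expect_error(approximate_match(idx, pat, 14), "13")
  expect_error(approximate_match(idx, "ACG", 3), "longer than k")
})
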