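test_that("error budgets resolve as documented", {
  expect_equal(resolve_error_budget(error_rate = 0, read_length = 151), 0)
  expect_equal(resolve_error_budget(error_rate = 0.02, read_length = 151), 3)
  expect_equal(resolve_error_budget(error_rate = 0.08, read_length = 150), 12)
  expect_equal(resolve_error_budget(error_rate = 0.2, read_length = 150), 13)
  expect_equal(resolve_error_budget(k = 7), 7)
  expect_error(resolve_error_budget(k = 14), "13")
  expect_error(resolve_error_budget(error_rate = 1, read_length = 100), "\\[0, 1\\)")
})

test_that("single-end mapping: strands, primaries, unmapped", {
  set.seed(616)
  g <- random_genome(8000, n_records = 2, seed = 9)
  idx <- build_index(g$sequences)
  seg <- substr(g$sequences[2], 1001, 1080)
  # exact forward read: one primary record on the forward strand
  rec <- map_single(list(name = "f", seq = seg), idx, k = 2)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$flag, 0L)
  expect_equal(rec$rname, "chr2")
  expect_equal(rec$pos, 1001L)              # 0-based 1000 -> 1-based 1001
  expect_equal(rec$mapq, 60L)
  expect_equal(nm_of(rec$tags), 0L)
  # reverse-complement read: reverse FLAG bit, SEQ back on the forward strand
  rc <- map_single(list(name = "r", seq = revcomp(seg)), idx, k = 2)
  expect_equal(bitwAnd(rc$flag, 16L), 16L)
  expect_equal(rc$pos, 1001L)
  expect_equal(rc$seq, unname(seg))
  # unmapped is a record, not an error
  un <- map_single(list(name = "u", seq = strrep("ACGT", 15)), idx, k = 0)
  expect_equal(un$flag, 4L)
  expect_equal(un$rname, "*")
})

test_that("record counts and positions match oracle clusters on synthetic reads", {
  set.seed(626)
  g <- random_genome(6000, seed = 12)
  idx <- build_index(g$sequences)
  txt <- g$sequences[[1]]
  for (r in 1:10) {
    st <- sample(5900, 1)
    pat <- mutate_seq(substr(txt, st, st + 59), sample(0:2, 1))
    strand <- sample(c("+", "-"), 1)
    seq <- if (strand == "-") revcomp(pat) else pat
    rec <- map_single(list(name = "x", seq = seq), idx, k = 2, mode = "all")
    # oracle clusters per strand
    n_or <- 0L
    for (p2 in c(pat, revcomp(pat))) {
      ends <- oracle_ends(txt, p2, 2)
      if (length(ends)) n_or <- n_or + sum(diff(c(-1e9, ends)) > nchar(p2) + 2)
    }
    n_rec <- sum(rec$flag != 4L)
    # cluster count equality: both count one representative per isolated group
    expect_equal(n_rec >= 1, n_or >= 1)
    if (n_or == 1) expect_equal(n_rec, 1)
  }
})

test_that("fragment model is recovered from planted pairs and falls back", {
  g <- random_genome(60000, seed = 21)
  idx <- build_index(g$sequences)
  sr <- sample_reads(g, 120, 70, sub_rate = 0.005, ins_rate = 0, del_rate = 0,
                     paired = c(400, 30), seed = 22)
  r1 <- sr$reads[sr$reads$mate == 1, ]
  r2 <- sr$reads[sr$reads$mate == 2, ]
  fm <- infer_fragment_model(r1, r2, idx, k = 1)
  expect_false(fm$fallback)
  se <- fm$sd / sqrt(fm$n_used)
  expect_lt(abs(fm$mean - 400), 3 * se + 1)   # +1: planted lengths are rounded
  expect_equal(fm$window[2] - fm$mean, 6 * fm$sd)   # six standard deviations
  # discordant input: documented fallback, flagged
  expect_message(
    fm2 <- infer_fragment_model(r1[1:5, ], r2[5:1, ], idx, k = 0, min_pairs = 5),
    "fallback")
  expect_true(fm2$fallback)
  expect_equal(fm2$mean, 400)
})

test_that("proper pairs: planted concordant pair, window rule, fallback", {
  g <- random_genome(30000, seed = 31)
  idx <- build_index(g$sequences)
  txt <- g$sequences[[1]]
  frag <- 350
  st <- 2000
  m1 <- substr(txt, st + 1, st + 70)
  m2 <- revcomp(substr(txt, st + frag - 69, st + frag))
  fm <- structure(list(mean = 360, sd = 20, window = c(240, 480),
                       n_used = 100, fallback = FALSE), class = "fragment_model")
  mp <- map_pair(list(name = "p", seq = m1), list(name = "p", seq = m2),
                 idx, k = 1, fragment_model = fm)
  expect_true(mp$proper)
  expect_equal(mp$stratum, 0)
  expect_equal(nrow(mp$pairs), 1)
  expect_equal(mp$pairs$frag, frag)
  expect_equal(sort(abs(mp$records$tlen)), c(frag, frag))
  expect_true(all(bitwAnd(mp$records$flag, 2L) == 2L))
  expect_equal(sort(mp$records$pos), c(st + 1, st + frag - 70 + 1))
  # both mates unique but fragment outside the window: unpaired fallback
  narrow <- structure(list(mean = 100, sd = 5, window = c(70, 130),
                           n_used = 100, fallback = FALSE), class = "fragment_model")
  mp2 <- map_pair(list(name = "p", seq = m1), list(name = "p", seq = m2),
                  idx, k = 1, fragment_model = narrow)
  expect_false(mp2$proper)
  expect_true(all(bitwAnd(mp2$records$flag, 2L) == 0L))
  expect_true(all(bitwAnd(mp2$records$flag, 1L) == 1L))
})

test_that("reported proper pairs equal the cross-product oracle", {
  set.seed(646)
  g <- random_genome(20000, seed = 41)
  idx <- build_index(g$sequences)
  txt <- g$sequences[[1]]
  fm <- structure(list(mean = 300, sd = 25, window = c(150, 450),
                       n_used = 50, fallback = FALSE), class = "fragment_model")
  k <- 2
  for (r in 1:6) {
    frag <- sample(250:350, 1)
    st <- sample(19000, 1)
    m1 <- mutate_seq(substr(txt, st + 1, st + 60), sample(0:2, 1))
    m2 <- mutate_seq(revcomp(substr(txt, st + frag - 59, st + frag)), sample(0:2, 1))
    mp <- map_pair(list(name = "p", seq = m1), list(name = "p", seq = m2),
                   idx, k = k, fragment_model = fm)
    # oracle: enumerate convergent end-position pairs from Sellers scans
    best <- Inf
    for (orient in 1:2) {
      fwd_p <- if (orient == 1) m1 else m2
      rev_p <- if (orient == 1) revcomp(m2) else revcomp(m1)
      df <- sellers_scan(txt, fwd_p); dr <- sellers_scan(txt, rev_p)
      fe <- which(df <= k) - 1L; re <- which(dr <= k) - 1L
      for (e1 in fe) for (e2 in re) {
        s1 <- r_best_start(txt, e1, fwd_p, k)
        frag_o <- e2 - s1[["start"]]
        if (frag_o >= fm$window[1] && frag_o <= fm$window[2] &&
            s1[["start"]] <= e2 - nchar(rev_p) + k)
          best <- min(best, df[e1 + 1] + dr[e2 + 1])
      }
    }
    if (is.finite(best)) {
      expect_true(mp$proper)
      expect_equal(mp$stratum, best)
    } else {
      expect_false(mp$proper)
    }
  }
})

test_that("SAM records are internally consistent and parse externally", {
  set.seed(656)
  g <- random_genome(12000, n_records = 2, seed = 51)
  idx <- build_index(g$sequences)
  sr <- sample_reads(g, 25, 80, sub_rate = 0.01, ins_rate = 0.003,
                     del_rate = 0.003, seed = 52)
  res <- align_reads(idx, sr$reads, k = 3, mode = "all",
                     out_sam = sam <- tempfile(fileext = ".sam"))
  rec <- res$records
  mapped <- rec[rec$flag != 4L, ]
  primary <- mapped[bitwAnd(mapped$flag, 256L) == 0L, ]
  # CIGAR read-axis length equals read length; POS within record bounds
  expect_true(all(vapply(seq_len(nrow(primary)), function(i)
    cigar_read_len(primary$cigar[i]) == nchar(primary$seq[i]), logical(1))))
  lens <- setNames(idx$records$length, idx$records$name)
  expect_true(all(primary$pos >= 1 & primary$pos <= lens[primary$rname]))
  # NM tag equals the reported edit distance and bounds interval stretch
  expect_true(all(vapply(seq_len(nrow(primary)), function(i) {
    abs(cigar_ref_len(primary$cigar[i]) - nchar(primary$seq[i])) <=
      nm_of(primary$tags[i])
  }, logical(1))))
  # external parser check
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  expect_true(file.exists(bam))
  got <- Rsamtools::scanBam(bam)[[1]]
  expect_equal(length(got$qname), nrow(rec))
})
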