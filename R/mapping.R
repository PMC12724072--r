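#' Resolve an error budget to an integer k
#'
#' Either an explicit number of errors or a maximum error rate may be
#' given. A rate is converted as `k = floor(rate * read_length)` and capped
#' at the supported ceiling of 13 errors; an explicit `k` beyond 13 is an
#' error. At 151 bp a 2% rate resolves to 3 errors; at 150 bp an 8% rate
#' resolves to 12.
#'
#' @param k Explicit error count (or `NULL`).
#' @param error_rate Maximum error rate in `[0, 1)` (or `NULL`).
#' @param read_length Read length used to convert a rate.
#' @return Integer `k` in `0..13`.
#' @export
resolve_error_budget <- function(k = NULL, error_rate = NULL, read_length = NULL) {
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 0) stop("k must be non-negative")
    if (k > 13) stop("at most k = 13 errors are supported")
    return(k)
  }
  if (is.null(error_rate)) stop("supply either k or error_rate")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (is.null(read_length)) stop("read_length needed to convert an error rate")
  min(as.integer(floor(error_rate * read_length)), 13L)
}

.FLAG <- c(paired = 1L, proper = 2L, unmapped = 4L, mate_unmapped = 8L,
           reverse = 16L, mate_reverse = 32L, first = 64L, second = 128L,
           secondary = 256L)

.mapq_for <- function(n_best) {
  if (n_best == 1) 60L else if (n_best <= 9) 3L else 0L
}

.as_read <- function(read) {
  if (is.character(read)) read <- list(name = "read", seq = read)
  if (is.data.frame(read)) read <- as.list(read[1, ])
  if (is.null(read$qual)) read$qual <- "*"
  read$name <- unname(read$name)
  read$qual <- unname(read$qual)
  read$seq <- unname(toupper(read$seq))
  read
}

# occurrence table over both strands for one read
.strand_occ <- function(index, seq, k, mode, scheme, partition, thr) {
  run1 <- function(s, kk) {
    occ <- approximate_match(index, s, kk, scheme = scheme,
                             partition = partition, in_text_threshold = thr)
    occ
  }
  rc <- revcomp(seq)
  if (mode == "all") {
    of <- run1(seq, k); orv <- run1(rc, k)
  } else {
    of <- orv <- NULL
    for (kk in 0:k) {
      of <- run1(seq, kk); orv <- run1(rc, kk)
      if (nrow(of) + nrow(orv) > 0) break
    }
    if (nrow(of) + nrow(orv) > 0) {
      s <- min(c(of$d, orv$d))
      of <- of[of$d == s, , drop = FALSE]
      orv <- orv[orv$d == s, , drop = FALSE]
    }
  }
  of$strand <- rep("+", nrow(of))
  orv$strand <- rep("-", nrow(orv))
  occ <- rbind(of, orv)
  if (nrow(occ) > 0)
    occ <- occ[order(occ$d, occ$start, occ$strand), , drop = FALSE]
  occ
}

# occurrence (global coords) -> per-record RNAME / 1-based POS
.occ_record <- function(occ, index) {
  rec <- index$records
  ri <- findInterval(occ$start, rec$offset)
  data.frame(rname = rec$name[ri], pos = as.integer(occ$start - rec$offset[ri] + 1L))
}

.occ_cigar <- function(index, occ, pattern_codes_by_strand) {
  vapply(seq_len(nrow(occ)), function(i) {
    slice <- cpp_index_text(.fm_ptr(index), as.integer(occ$start[i]),
                            as.integer(occ$end[i]))
    cpp_align_global(slice, pattern_codes_by_strand[[occ$strand[i]]])$cigar
  }, character(1))
}

.unmapped_record <- function(read, extra_flag = 0L) {
  data.frame(qname = read$name, flag = .FLAG[["unmapped"]] + extra_flag,
             rname = "*", pos = 0L, mapq = 0L, cigar = "*", rnext = "*",
             pnext = 0L, tlen = 0L, seq = read$seq, qual = read$qual,
             tags = "", stringsAsFactors = FALSE)
}

.occ_records <- function(read, occ, index, extra_flag = 0L) {
  if (nrow(occ) == 0) return(.unmapped_record(read, extra_flag))
  pats <- list("+" = dna_codes(read$seq), "-" = revcomp_codes(dna_codes(read$seq)))
  loc <- .occ_record(occ, index)
  cig <- .occ_cigar(index, occ, pats)
  n_best <- sum(occ$d == min(occ$d))
  mapq <- .mapq_for(n_best)
  rev_qual <- if (read$qual == "*") "*" else
    paste(rev(strsplit(read$qual, "")[[1]]), collapse = "")
  primary <- seq_len(nrow(occ)) == 1L   # occ sorted: best d, leftmost, + first
  data.frame(
    qname = read$name,
    flag = extra_flag +
      ifelse(occ$strand == "-", .FLAG[["reverse"]], 0L) +
      ifelse(primary, 0L, .FLAG[["secondary"]]),
    rname = loc$rname, pos = loc$pos,
    mapq = ifelse(primary, mapq, 0L),
    cigar = cig, rnext = "*", pnext = 0L, tlen = 0L,
    seq = ifelse(primary, ifelse(occ$strand == "-", revcomp(read$seq), read$seq), "*"),
    qual = ifelse(primary, ifelse(occ$strand == "-", rev_qual, read$qual), "*"),
    tags = sprintf("NM:i:%d\tAS:i:%d", occ$d, -occ$d),
    stringsAsFactors = FALSE)
}

#' Map a single read
#'
#' Aligns the read and its reverse complement, clusters redundant variants
#' per strand, and emits SAM records: one primary (smallest edit distance,
#' ties broken by leftmost reference position, then forward strand), the
#' remainder flagged secondary. A read with no occurrence yields an
#' unmapped record (`FLAG` 4), not an error. MAPQ is a documented
#' convention, not a probability: 60 for a unique best occurrence, 3 for
#' 2-9 co-optimal, 0 for 10 or more.
#'
#' @param read A character string, or a list / one-row data frame with
#'   `name`, `seq` and optional `qual`.
#' @param index An `fm_index`.
#' @param k,error_rate Error budget (see [resolve_error_budget()]).
#' @param mode `"all"` (every occurrence within `k`) or `"all-best"`
#'   (strata: only minimal-distance occurrences).
#' @param scheme,partition,in_text_threshold Passed to
#'   [approximate_match()].
#' @return Data frame of SAM records (1-based `pos`; `NM` tag carries the
#'   edit distance, `AS` its negation).
#' @export
map_single <- function(read, index, k = NULL, error_rate = NULL,
                       mode = c("all-best", "all"), scheme = NULL,
                       partition = "dynamic", in_text_threshold = 4) {
  mode <- match.arg(mode)
  read <- .as_read(read)
  k <- resolve_error_budget(k, error_rate, nchar(read$seq))
  occ <- .strand_occ(index, read$seq, k, mode, scheme, partition, in_text_threshold)
  .occ_records(read, occ, index)
}

#' Infer the fragment-size model from the first read pairs
#'
#' Takes the first `n_pairs` pairs in which both mates have a unique best
#' alignment in convergent orientation and computes the sample mean and
#' standard deviation of the outer fragment length (leftmost start to
#' rightmost end). A pair is accepted as proper when its fragment length
#' lies within six standard deviations of the mean. When fewer than
#' `min_pairs` pairs qualify, a documented fallback model (mean 400, sd
#' 100) is returned and flagged.
#'
#' @param reads1,reads2 Data frames of mates (`name`, `seq`, `qual`).
#' @param index An `fm_index`.
#' @param k Error budget used for the probe alignments (default 2).
#' @param n_pairs Number of leading pairs to examine (default 1000).
#' @param min_pairs Minimum qualifying pairs before falling back.
#' @return A `fragment_model`: list with `mean`, `sd`, `window`
#'   (`mean` &plusmn; 6 `sd`), `n_used`, `fallback`.
#' @export
infer_fragment_model <- function(reads1, reads2, index, k = 2,
                                 n_pairs = 1000, min_pairs = 50) {
  n <- min(nrow(reads1), nrow(reads2), n_pairs)
  frags <- numeric(0)
  for (i in seq_len(n)) {
    o1 <- .strand_occ(index, toupper(reads1$seq[i]), k, "all-best", NULL, "dynamic", 4)
    o2 <- .strand_occ(index, toupper(reads2$seq[i]), k, "all-best", NULL, "dynamic", 4)
    if (nrow(o1) != 1 || nrow(o2) != 1) next
    if (o1$strand == o2$strand) next
    fwd <- if (o1$strand == "+") o1 else o2
    rev_ <- if (o1$strand == "+") o2 else o1
    if (fwd$start > rev_$start) next        # convergent: forward mate leftmost
    frags <- c(frags, rev_$end - fwd$start)
  }
  if (length(frags) >= min_pairs) {
    mu <- mean(frags); s <- stats::sd(frags)
    fb <- FALSE
  } else {
    message("fragment-model inference: fewer than ", min_pairs,
            " concordant unique pairs; using fallback model (mean 400, sd 100)")
    mu <- 400; s <- 100
    fb <- TRUE
  }
  structure(list(mean = mu, sd = s,
                 window = c(max(0, mu - 6 * s), mu + 6 * s),
                 n_used = length(frags), fallback = fb),
            class = "fragment_model")
}

#' @export
print.fragment_model <- function(x, ...) {
  cat(sprintf("fragment model: mean %.1f, sd %.1f, window [%.1f, %.1f]%s (n = %d)\n",
              x$mean, x$sd, x$window[1], x$window[2],
              if (x$fallback) " [fallback]" else "", x$n_used))
  invisible(x)
}

# enumerate candidate proper pairs from two occurrence tables
.enumerate_pairs <- function(occ1, occ2, window) {
  out <- list()
  add <- function(fwd, rev_, first_is_fwd) {
    if (nrow(fwd) == 0 || nrow(rev_) == 0) return()
    for (i in seq_len(nrow(fwd))) for (j in seq_len(nrow(rev_))) {
      if (fwd$start[i] > rev_$start[j]) next
      frag <- rev_$end[j] - fwd$start[i]
      if (frag < window[1] || frag > window[2]) next
      out[[length(out) + 1L]] <<- data.frame(
        fwd_start = fwd$start[i], fwd_end = fwd$end[i], fwd_d = fwd$d[i],
        rev_start = rev_$start[j], rev_end = rev_$end[j], rev_d = rev_$d[j],
        frag = frag, total = fwd$d[i] + rev_$d[j],
        first_is_fwd = first_is_fwd)
    }
  }
  add(occ1[occ1$strand == "+", , drop = FALSE],
      occ2[occ2$strand == "-", , drop = FALSE], TRUE)
  add(occ2[occ2$strand == "+", , drop = FALSE],
      occ1[occ1$strand == "-", , drop = FALSE], FALSE)
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Map a read pair with proper-pair resolution
#'
#' Both mates' occurrence sets are computed in all mode up to `k` errors
#' each; every cross-product combination in convergent orientation
#' (leftmost mate on the forward strand) whose outer fragment length lies
#' in the model window is enumerated, and all pairs minimising the total
#' edit distance `d1 + d2` are reported as proper pairs with pair FLAG bits
#' and `TLEN`. When no combination qualifies, the mates fall back to two
#' independent single-end mappings without the proper-pair bit.
#'
#' @param read1,read2 Mates (as in [map_single()]).
#' @param index An `fm_index`.
#' @param k,error_rate Per-mate error budget.
#' @param fragment_model A `fragment_model` from [infer_fragment_model()].
#' @param scheme,partition,in_text_threshold Passed to
#'   [approximate_match()].
#' @return List with `records` (SAM data frame), `proper` (logical),
#'   `pairs` (the retained pair table, `NULL` on fallback) and `stratum`
#'   (minimal `d1 + d2`, `NA` on fallback).
#' @export
map_pair <- function(read1, read2, index, k = NULL, error_rate = NULL,
                     fragment_model, scheme = NULL, partition = "dynamic",
                     in_text_threshold = 4) {
  read1 <- .as_read(read1); read2 <- .as_read(read2)
  k1 <- resolve_error_budget(k, error_rate, nchar(read1$seq))
  k2 <- resolve_error_budget(k, error_rate, nchar(read2$seq))
  occ1 <- .strand_occ(index, read1$seq, k1, "all", scheme, partition, in_text_threshold)
  occ2 <- .strand_occ(index, read2$seq, k2, "all", scheme, partition, in_text_threshold)
  pairs <- .enumerate_pairs(occ1, occ2, fragment_model$window)
  if (is.null(pairs)) {
    r1 <- map_single(read1, index, k = k1, mode = "all-best",
                     scheme = scheme, partition = partition,
                     in_text_threshold = in_text_threshold)
    r2 <- map_single(read2, index, k = k2, mode = "all-best",
                     scheme = scheme, partition = partition,
                     in_text_threshold = in_text_threshold)
    r1$flag <- r1$flag + .FLAG[["paired"]] + .FLAG[["first"]]
    r2$flag <- r2$flag + .FLAG[["paired"]] + .FLAG[["second"]]
    return(list(records = rbind(r1, r2), proper = FALSE, pairs = NULL,
                stratum = NA_integer_))
  }
  stratum <- min(pairs$total)
  pairs <- pairs[pairs$total == stratum, , drop = FALSE]
  pairs <- pairs[order(pairs$fwd_start, pairs$rev_start), , drop = FALSE]
  recs <- lapply(seq_len(nrow(pairs)), function(i) {
    pr <- pairs[i, ]
    sec <- if (i == 1) 0L else .FLAG[["secondary"]]
    mk <- function(read, occ_start, occ_end, d, strand, is_first, mate_strand,
                   mate_pos1, tlen) {
      occ <- data.frame(start = occ_start, end = occ_end, d = d, strand = strand)
      rec <- .occ_records(read, occ, index,
                          extra_flag = .FLAG[["paired"]] + .FLAG[["proper"]] +
                            (if (is_first) .FLAG[["first"]] else .FLAG[["second"]]) +
                            (if (mate_strand == "-") .FLAG[["mate_reverse"]] else 0L) +
                            sec)
      rec$rnext <- "="
      rec$pnext <- mate_pos1
      rec$tlen <- tlen
      rec
    }
    loc_f <- .occ_record(data.frame(start = pr$fwd_start), index)
    loc_r <- .occ_record(data.frame(start = pr$rev_start), index)
    fwd_read <- if (pr$first_is_fwd) read1 else read2
    rev_read <- if (pr$first_is_fwd) read2 else read1
    rbind(
      mk(fwd_read, pr$fwd_start, pr$fwd_end, pr$fwd_d, "+", pr$first_is_fwd,
         "-", loc_r$pos, pr$frag),
      mk(rev_read, pr$rev_start, pr$rev_end, pr$rev_d, "-", !pr$first_is_fwd,
         "+", loc_f$pos, -pr$frag))
  })
  recs <- do.call(rbind, recs)
  # MAPQ reflects the number of co-optimal proper pairs; secondary records 0
  recs$mapq <- ifelse(bitwAnd(recs$flag, .FLAG[["secondary"]]) > 0L,
                      0L, .mapq_for(nrow(pairs)))
  list(records = recs, proper = TRUE, pairs = pairs, stratum = stratum)
}

#' Align a batch of reads and write SAM
#'
#' High-level driver: streams single- or paired-end reads through
#' [map_single()] / [map_pair()], optionally inferring the fragment model
#' from the leading pairs, writes SAM and returns a run summary.
#'
#' @param index An `fm_index`.
#' @param reads,reads2 Data frames (`name`, `seq`, `qual`) or FASTQ/FASTA
#'   paths; `reads2` gives the second mates for paired mode.
#' @param k,error_rate Error budget (see [resolve_error_budget()]).
#' @param mode `"all-best"` or `"all"` (single-end only).
#' @param out_sam Output SAM path, or `NULL` to skip writing.
#' @param fragment_model Optional precomputed `fragment_model`.
#' @param scheme,partition,in_text_threshold Passed down.
#' @param cl Command line recorded in the SAM `@PG` header.
#' @return (Invisibly) list with `records` and `summary` (reads in, reads
#'   aligned, records out, strata histogram, aligned fraction).
#' @export
align_reads <- function(index, reads, reads2 = NULL, k = NULL,
                        error_rate = NULL, mode = c("all-best", "all"),
                        out_sam = NULL, fragment_model = NULL, scheme = NULL,
                        partition = "dynamic", in_text_threshold = 4,
                        cl = NULL) {
  mode <- match.arg(mode)
  load_reads <- function(x) {
    if (is.character(x) && length(x) == 1) {
      first <- substr(readLines(x, n = 1), 1, 1)
      if (first == "@") read_fastq(x) else {
        fa <- read_fasta(x); fa$qual <- strrep("I", nchar(fa$seq)); fa
      }
    } else x
  }
  reads <- load_reads(reads)
  paired <- !is.null(reads2)
  if (paired) {
    reads2 <- load_reads(reads2)
    if (nrow(reads) != nrow(reads2))
      stop("mate-count mismatch between paired files")
    if (is.null(fragment_model))
      fragment_model <- infer_fragment_model(reads, reads2, index)
  }
  all_records <- list()
  strata <- integer(0)
  n_aligned <- 0L
  for (i in seq_len(nrow(reads))) {
    if (paired) {
      mp <- map_pair(reads[i, ], reads2[i, ], index, k = k,
                     error_rate = error_rate,
                     fragment_model = fragment_model, scheme = scheme,
                     partition = partition,
                     in_text_threshold = in_text_threshold)
      rec <- mp$records
      if (!is.na(mp$stratum)) strata <- c(strata, mp$stratum)
      if (any(bitwAnd(rec$flag, .FLAG[["unmapped"]]) == 0)) n_aligned <- n_aligned + 1L
    } else {
      rec <- map_single(reads[i, ], index, k = k, error_rate = error_rate,
                        mode = mode, scheme = scheme, partition = partition,
                        in_text_threshold = in_text_threshold)
      if (rec$flag[1] != .FLAG[["unmapped"]]) {
        n_aligned <- n_aligned + 1L
        strata <- c(strata, min(as.integer(sub(".*NM:i:(\\d+).*", "\\1", rec$tags))))
      }
    }
    all_records[[i]] <- rec
  }
  records <- do.call(rbind, all_records)
  summary <- list(
    reads_in = nrow(reads) * (1L + paired),
    reads_aligned = n_aligned,
    records_out = nrow(records),
    aligned_fraction = n_aligned / nrow(reads),
    strata = table(strata))
  if (!is.null(out_sam))
    write_sam(records, list(records = index$records, cl = cl), out_sam)
  invisible(list(records = records, summary = summary))
}
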