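#' Generate a random genome with known composition
#'
#' Deterministic for a fixed seed. Bases are drawn i.i.d. with the
#' requested GC fraction (split evenly between G and C, and between A and
#' T); the total length is divided over `n_records` as evenly as possible.
#'
#' @param length Total genome length.
#' @param n_records Number of FASTA records (default 1).
#' @param gc Target GC fraction (default 0.5).
#' @param seed Random seed.
#' @return List with `sequences` (named character vector) and
#'   `record_table` (`name`, `offset`, `length`).
#' @export
random_genome <- function(length, n_records = 1, gc = 0.5, seed = 1) {
  if (length < n_records) stop("length must be at least n_records")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  lens <- rep(length %/% n_records, n_records)
  extra <- length %% n_records
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  seqs <- vapply(lens, function(l)
    paste(sample(names(probs), l, replace = TRUE, prob = probs), collapse = ""),
    character(1))
  names(seqs) <- paste0("chr", seq_len(n_records))
  list(sequences = seqs,
       record_table = data.frame(name = names(seqs),
                                 offset = cumsum(c(0L, lens[-n_records])),
                                 length = as.integer(lens),
                                 stringsAsFactors = FALSE))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# plant substitutions / insertions / deletions into a coded read
.plant_errors <- function(codes, sub_rate, ins_rate, del_rate) {
  n_sub <- stats::rbinom(1, length(codes), sub_rate)
  n_ins <- stats::rbinom(1, length(codes), ins_rate)
  n_del <- stats::rbinom(1, length(codes), del_rate)
  ops <- character(0)
  if (n_sub > 0) for (z in seq_len(n_sub)) {
    i <- sample(length(codes), 1)
    codes[i] <- sample(setdiff(1:4, codes[i]), 1)
    ops <- c(ops, sprintf("S%d", i))
  }
  if (n_del > 0) for (z in seq_len(n_del)) {
    if (length(codes) < 2) break
    i <- sample(length(codes), 1)
    codes <- codes[-i]
    ops <- c(ops, sprintf("D%d", i))
  }
  if (n_ins > 0) for (z in seq_len(n_ins)) {
    i <- sample(length(codes) + 1L, 1) - 1L
    codes <- append(codes, sample(1:4, 1), after = i)
    ops <- c(ops, sprintf("I%d", i))
  }
  list(codes = codes, ops = ops)
}

#' Sample reads with planted errors and a truth table
#'
#' Draws read origins uniformly from the genome (strand uniform),
#' reverse-complements reads from the minus strand, and plants
#' substitutions, insertions and deletions at the requested per-base
#' rates. Every read carries a truth entry: origin record and position,
#' strand, the planted operations, and the *DP-verified* edit distance to
#' the origin segment (adjacent planted operations can cancel, so the true
#' distance may be below the operation count). In paired mode convergent
#' pairs are planted at fragment lengths drawn from a normal distribution.
#'
#' @param genome Output of [random_genome()] (or a compatible list).
#' @param n_reads Number of reads (pairs, in paired mode).
#' @param read_length Read length before indels.
#' @param sub_rate,ins_rate,del_rate Per-base error rates.
#' @param paired `NULL` for single-end, or `c(fragment_mean, fragment_sd)`.
#' @param seed Random seed.
#' @return List with `reads` (`name`, `seq`, `qual`, `mate`) and `truth`
#'   (`name`, `record`, `pos` 0-based within the record, `strand`, `ops`,
#'   `true_d`), plus `write_truth()`-friendly columns.
#' @export
sample_reads <- function(genome, n_reads, read_length, sub_rate = 0.01,
                         ins_rate = 0.002, del_rate = 0.002, paired = NULL,
                         seed = 1) {
  if ((sub_rate + ins_rate + del_rate) * read_length > 13)
    stop("expected number of planted errors exceeds the supported 13")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rec <- genome$record_table
  seqs <- genome$sequences
  reads <- list(); truth <- list()
  emit <- function(name, ri, pos0, strand, mate) {
    segment <- substr(seqs[ri], pos0 + 1L, pos0 + read_length)
    codes <- dna_codes(segment)
    if (strand == "-") codes <- revcomp_codes(codes)
    pl <- .plant_errors(codes, sub_rate, ins_rate, del_rate)
    seq <- codes_to_dna(pl$codes)
    cmp <- if (strand == "-") revcomp(seq) else seq
    true_d <- as.integer(utils::adist(cmp, segment))
    reads[[length(reads) + 1L]] <<- data.frame(
      name = name, seq = seq, qual = strrep("I", nchar(seq)), mate = mate,
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      name = name, record = rec$name[ri], pos = pos0, strand = strand,
      ops = paste(pl$ops, collapse = ";"), true_d = true_d,
      stringsAsFactors = FALSE)
  }
  for (r in seq_len(n_reads)) {
    if (is.null(paired)) {
      ri <- sample(nrow(rec), 1, prob = rec$length)
      if (rec$length[ri] < read_length) stop("read longer than genome record")
      pos0 <- sample(rec$length[ri] - read_length + 1L, 1) - 1L
      strand <- sample(c("+", "-"), 1)
      emit(sprintf("read%04d", r), ri, pos0, strand, 0L)
    } else {
      frag <- max(read_length, round(stats::rnorm(1, paired[1], paired[2])))
      ri <- sample(nrow(rec), 1, prob = rec$length)
      if (rec$length[ri] < frag) frag <- rec$length[ri]
      pos0 <- sample(rec$length[ri] - frag + 1L, 1) - 1L
      # convergent pair: forward-strand mate at the left end of the
      # fragment, reverse-strand mate at the right end; which of the two
      # is "mate 1" is drawn uniformly
      first_fwd <- sample(c(TRUE, FALSE), 1)
      nm <- sprintf("pair%04d", r)
      pos2 <- pos0 + frag - read_length
      if (first_fwd) {
        emit(nm, ri, pos0, "+", 1L)
        emit(nm, ri, pos2, "-", 2L)
      } else {
        emit(nm, ri, pos2, "-", 1L)
        emit(nm, ri, pos0, "+", 2L)
      }
      truth[[length(truth)]]$frag <- frag
      truth[[length(truth) - 1L]]$frag <- frag
    }
  }
  reads <- do.call(rbind, reads)
  truth <- do.call(rbind, truth)
  list(reads = reads, truth = truth)
}

#' Write a truth table as its tab-separated sidecar file
#'
#' @param truth Truth data frame from [sample_reads()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
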