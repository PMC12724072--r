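#' Build a bidirectional FM-index over a reference
#'
#' Concatenates all FASTA records into a single text (with one terminal
#' sentinel), replaces non-ACGT characters by a reserved fifth character that
#' matches nothing, and builds the Burrows-Wheeler transforms of the text and
#' its reverse together with per-character rank structures and a sampled
#' suffix array.
#'
#' Occurrences are always reported in concatenated 0-based coordinates and
#' are discarded at location time if they cross a record boundary, so no
#' per-record separators are needed.
#'
#' @param reference Path to a FASTA file, or a named character vector of
#'   sequences (one element per record).
#' @param sa_sampling Suffix-array sampling factor; every position divisible
#'   by this factor is retained. Default 4.
#' @return An object of class `fm_index` with elements `n` (text length
#'   including the sentinel), `sa_sampling`, and `records`, a data frame with
#'   columns `name`, `offset` (0-based start in the concatenation) and
#'   `length`.
#' @examples
#' idx <- build_index(c(chr1 = "ACAACG"))
#' bwt(idx)
#' @export
build_index <- function(reference, sa_sampling = 4) {
  if (is.character(reference) && length(reference) == 1 && file.exists(reference)) {
    fa <- read_fasta(reference)
    seqs <- stats::setNames(fa$seq, fa$name)
  } else if (is.character(reference)) {
    seqs <- reference
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  } else {
    stop("reference must be a FASTA path or a named character vector")
  }
  if (sa_sampling < 1) stop("sa_sampling must be a positive integer")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (sum(lens) == 0) stop("empty reference after sanitization")
  codes <- unlist(lapply(seqs, dna_codes), use.names = FALSE)
  records <- data.frame(
    name = names(seqs),
    offset = unname(cumsum(c(0L, lens[-length(lens)]))),
    length = as.integer(unname(lens)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  ptr <- cpp_index_build(codes, as.integer(sa_sampling))
  structure(
    list(ptr = ptr, n = length(codes) + 1L, sa_sampling = as.integer(sa_sampling),
         records = records),
    class = "fm_index"
  )
}

#' @export
print.fm_index <- function(x, ...) {
  cat("Bidirectional FM-index\n")
  cat("  text length (incl. sentinel):", x$n, "\n")
  cat("  SA sampling factor:", x$sa_sampling, "\n")
  cat("  records:", nrow(x$records), "\n")
  invisible(x)
}

.fm_ptr <- function(index) {
  stopifnot(inherits(index, "fm_index"))
  index$ptr
}

#' Burrows-Wheeler transform of the indexed text
#'
#' @param index An `fm_index`.
#' @param reverse Return the BWT of the reversed text instead.
#' @return A character string over `$ACGTN`.
#' @export
bwt <- function(index, reverse = FALSE) {
  codes_to_dna(cpp_index_bwt(.fm_ptr(index), reverse))
}

#' Extract a slice of the sanitized concatenated reference
#'
#' @param index An `fm_index`.
#' @param start,end 0-based half-open interval.
#' @return Character string (non-ACGT positions appear as `N`).
#' @export
reference_slice <- function(index, start, end) {
  codes_to_dna(cpp_index_text(.fm_ptr(index), as.integer(start), as.integer(end)))
}

#' The bidirectional range of the empty pattern
#'
#' A bidirectional range is a synchronized pair of half-open intervals over
#' the suffix arrays of the text and its reverse; it is the unit of search
#' state. The empty pattern matches every suffix, so its range has width `n`.
#'
#' @param index An `fm_index`.
#' @return A `bi_range`: numeric vector `(b, e, rb, re)`.
#' @export
full_range <- function(index) {
  structure(cpp_full_range(.fm_ptr(index)), class = "bi_range")
}

#' @export
print.bi_range <- function(x, ...) {
  cat(sprintf("bi_range [%d, %d) / [%d, %d)  width %d\n",
              x[1], x[2], x[3], x[4], x[2] - x[1]))
  invisible(x)
}

#' Width (number of occurrences) of a bidirectional range
#' @param range A `bi_range`.
#' @export
range_width <- function(range) as.numeric(range[2] - range[1])

.extend <- function(index, range, c, left) {
  code <- if (is.character(c)) dna_codes(c)[1] else as.integer(c)
  if (code == 0L) stop("cannot extend by the sentinel")
  structure(cpp_extend(.fm_ptr(index), as.numeric(range), code, left),
            class = "bi_range")
}

#' Extend a partial match by one character
#'
#' `extend_left` turns the range of a partial match `M` into the range of
#' `cM`; `extend_right` into the range of `Mc`. Both keep the forward and
#' reverse intervals synchronized so extension remains possible on either
#' side. Extending by a character absent at that position yields an empty
#' range, not an error.
#'
#' @param index An `fm_index`.
#' @param range A `bi_range`.
#' @param c A single character (`A`, `C`, `G`, `T`, or `N`; `N` and any
#'   other non-ACGT character match only the reserved fifth character,
#'   i.e. nothing in a clean genome).
#' @return A `bi_range`.
#' @export
extend_left <- function(index, range, c) .extend(index, range, c, TRUE)

#' @rdname extend_left
#' @export
extend_right <- function(index, range, c) .extend(index, range, c, FALSE)

#' Locate the text positions of a range
#'
#' Recovers the starting positions in the concatenated text of every suffix
#' in the forward interval, LF-walking to sampled suffix-array entries.
#'
#' @param index An `fm_index`.
#' @param range A `bi_range`.
#' @return Sorted numeric vector of 0-based positions; length equals the
#'   range width.
#' @export
locate <- function(index, range) {
  cpp_locate(.fm_ptr(index), as.numeric(range[1]), as.numeric(range[2]))
}

#' Count exact occurrences of a pattern
#'
#' Used as the workload estimate for dynamic partitioning and dynamic scheme
#' selection. Patterns containing non-ACGT characters have no exact
#' occurrences by construction.
#'
#' @param index An `fm_index`.
#' @param pattern A character string.
#' @return Non-negative number of occurrences in the concatenated text.
#' @export
count_exact <- function(index, pattern) {
  codes <- if (is.character(pattern)) dna_codes(pattern) else as.integer(pattern)
  cpp_count_exact(.fm_ptr(index), codes)
}
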