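#' Banded edit-distance rows
#'
#' Computes the banded unit-cost edit-distance matrix between a text (rows;
#' one row per consumed character) and a pattern (columns), restricted to
#' the diagonal band of half-width `k`. Cells outside the band are `NA`;
#' inside the band any value exceeding `k` is reported as `k + 1` (such
#' cells cannot take part in an alignment with at most `k` errors).
#'
#' Two implementations share this contract: `"bitparallel"` maintains each
#' row as Myers-style delta bit vectors and updates all cells of a row
#' simultaneously; `"scalar"` is the plain dynamic-programming reference
#' used as its oracle.
#'
#' @param pattern,text Character strings (or integer code vectors).
#' @param k Band half-width / error budget, `0..13`.
#' @param method `"bitparallel"` or `"scalar"`.
#' @return Integer matrix of dimension `(nchar(text)+1) x (nchar(pattern)+1)`.
#' @export
banded_rows <- function(pattern, text, k, method = c("bitparallel", "scalar")) {
  method <- match.arg(method)
  p <- if (is.character(pattern)) dna_codes(pattern) else as.integer(pattern)
  t <- if (is.character(text)) dna_codes(text) else as.integer(text)
  if (method == "bitparallel") cpp_banded_rows_bitpar(p, t, as.integer(k))
  else cpp_banded_rows_scalar(p, t, as.integer(k))
}

#' Single banded-row update (scalar reference form)
#'
#' Advances one row of the banded edit-distance matrix after consuming one
#' more text character. The row is a numeric vector of length
#' `nchar(pattern) + 1` holding distance values, `Inf` outside the band,
#' with the consumed-text length in attribute `row`. Use
#' `band_row_init(pattern, k)` for the standard boundary row.
#'
#' @param row Current row (from `band_row_init` or a previous update).
#' @param new_char The consumed text character.
#' @param pattern The pattern the text is aligned against.
#' @param k Band half-width.
#' @return The next row.
#' @export
band_row_update <- function(row, new_char, pattern, k) {
  pc <- dna_codes(pattern)
  tc <- dna_codes(new_char)[1]
  m <- attr(row, "row") + 1L
  plen <- length(pc)
  out <- rep(Inf, plen + 1L)
  lo <- max(0L, m - k); hi <- min(plen, m + k)
  if (lo > hi) { attr(out, "row") <- m; return(out) }   # band left the pattern
  for (j in lo:hi) {
    diag_v <- if (j >= 1) row[j] + (if (pc[j] == tc && tc <= 4L) 0 else 1) else Inf
    up_v <- if (j + 1L <= plen + 1L) row[j + 1L] + 1 else Inf
    left_v <- if (j >= 1 && is.finite(out[j])) out[j] + 1 else Inf
    v <- min(diag_v, up_v, left_v, if (j == 0) m else Inf)
    out[j + 1L] <- v
  }
  attr(out, "row") <- m
  out
}

#' @rdname band_row_update
#' @export
band_row_init <- function(pattern, k) {
  plen <- nchar(pattern)
  out <- rep(Inf, plen + 1L)
  out[seq_len(min(plen, k) + 1L)] <- 0:min(plen, k)
  attr(out, "row") <- 0L
  out
}

#' Scalar edit-distance scan (reference oracle)
#'
#' For every end position in the text, the minimal edit distance between
#' the pattern and any substring ending there (free start), computed by the
#' plain quadratic dynamic programme. This is the independent reference
#' against which the index-based search is tested.
#'
#' @param text,pattern Character strings (or integer code vectors).
#' @return Integer vector of length `nchar(text) + 1` (ends `0..n`).
#' @export
sellers_scan <- function(text, pattern) {
  t <- if (is.character(text)) dna_codes(text) else as.integer(text)
  p <- if (is.character(pattern)) dna_codes(pattern) else as.integer(pattern)
  cpp_oracle_scan(t, p)
}

#' Verify a pattern directly against a text slice
#'
#' In-text verification: once the number of index candidates for a partial
#' match drops below a threshold, the remaining work is done against the
#' located text directly, bit-parallel. For every end position in the slice
#' whose minimal edit distance is within budget, reports the leftmost
#' minimal-distance start.
#'
#' @param text_slice Character string (the located slice, already padded).
#' @param pattern Character string to verify.
#' @param k_budget Remaining error budget.
#' @param anchor Global 0-based position of the slice start; added to the
#'   returned coordinates.
#' @return Data frame with 0-based half-open `start`, `end` and `d`.
#' @export
in_text_verify <- function(text_slice, pattern, k_budget, anchor = 0) {
  t <- if (is.character(text_slice)) dna_codes(text_slice) else as.integer(text_slice)
  p <- if (is.character(pattern)) dna_codes(pattern) else as.integer(pattern)
  hits <- cpp_canonical_hits(t, p, as.integer(k_budget))
  data.frame(start = hits$start + anchor, end = hits$end + anchor, d = hits$d)
}

#' Execute one search of a scheme over the index
#'
#' Depth-first exploration in part order: the bidirectional range is grown
#' character by character in the current direction while a banded
#' bit-parallel row tracks the edit distance against the processed pattern
#' region; branches are pruned when the in-band minimum exceeds the
#' cumulative upper bound of the current part or the total budget. When the
#' range width drops below `in_text_threshold` the branch switches to
#' in-text verification. Candidates are raw: they may contain redundant
#' variants of the same alignment, which [approximate_match()] resolves.
#'
#' @param index An `fm_index`.
#' @param pattern Character string.
#' @param search An [ss_search()].
#' @param partition Cut positions ([uniform_partition()] /
#'   [dynamic_partition()]) with `p` parts.
#' @param k Error budget.
#' @param in_text_threshold Switch to in-text verification below this range
#'   width (default 4).
#' @return Data frame `start`, `end`, `d`, `source` (`"index"` or
#'   `"verify"`), 0-based half-open.
#' @export
execute_search <- function(index, pattern, search, partition, k,
                           in_text_threshold = 4) {
  p <- length(search$pi)
  stopifnot(length(partition) == p + 1L)
  v <- validate_search(search, p)
  if (!isTRUE(v)) stop(v)
  pc <- dna_codes(pattern)
  res <- cpp_execute_search(.fm_ptr(index), pc, as.integer(partition),
                            search$pi - 1L, pmin(search$L, 13L),
                            pmin(search$U, as.integer(k)),
                            as.integer(k), as.integer(in_text_threshold))
  data.frame(start = res$start, end = res$end, d = res$d,
             source = c("index", "verify")[res$source + 1L],
             stringsAsFactors = FALSE)
}

# drop occurrences that cross a record boundary of the concatenated text
.filter_record_bounds <- function(occ, index) {
  if (nrow(occ) == 0) return(occ)
  rec <- index$records
  starts <- rec$offset
  ends <- rec$offset + rec$length
  ri <- findInterval(occ$start, starts)
  ok <- ri >= 1 & occ$end <= ends[pmax(ri, 1L)] & occ$end > occ$start
  occ[ok, , drop = FALSE]
}

#' Collapse exact duplicate occurrences
#'
#' Occurrence identity is `(start, end, d)` plus `strand` when present;
#' differing alignment paths between identical tuples are not
#' distinguished. Idempotent.
#'
#' @param occ Data frame of occurrences.
#' @return Deduplicated data frame.
#' @export
dedupe_occurrences <- function(occ) {
  if (nrow(occ) == 0) return(occ)
  cols <- intersect(c("start", "end", "d", "strand"), names(occ))
  occ[!duplicated(occ[cols]), , drop = FALSE]
}

#' Cluster redundant occurrence variants
#'
#' Under edit distance the same alignment can be reported with slightly
#' shifted ends (a leading or trailing gap exchanged for a substitution).
#' Occurrences whose reference intervals overlap are grouped; each group is
#' represented by its minimal-distance occurrence, ties broken by leftmost
#' start, then longest interval. Non-overlapping occurrences are never
#' merged. Input should be deduplicated and single-strand (callers cluster
#' per strand).
#'
#' @param occ Data frame with `start`, `end` (0-based half-open), `d`.
#' @param read_length Unused by the overlap-based rule; accepted for
#'   interface stability.
#' @return Data frame of representatives, plus `n_variants`, the group
#'   size.
#' @export
cluster_occurrences <- function(occ, read_length = NULL) {
  if (nrow(occ) == 0) return(cbind(occ, n_variants = integer(0)))
  ir <- IRanges::IRanges(start = occ$start + 1L, end = occ$end)
  grp <- S4Vectors::subjectHits(
    IRanges::findOverlaps(ir, IRanges::reduce(ir)))
  keep <- integer(0)
  sizes <- integer(0)
  for (g in unique(grp)) {
    ix <- which(grp == g)
    sub <- occ[ix, , drop = FALSE]
    cand <- ix[sub$d == min(sub$d)]
    sub <- occ[cand, , drop = FALSE]
    cand <- cand[sub$start == min(sub$start)]
    sub <- occ[cand, , drop = FALSE]
    best <- cand[which.max(sub$end)]
    keep <- c(keep, best)
    sizes <- c(sizes, length(ix))
  }
  out <- occ[keep, , drop = FALSE]
  out$n_variants <- sizes
  out[order(out$start, out$end), , drop = FALSE]
}

# canonicalize candidate occurrences: every candidate end is re-scored by a
# local scan and given the leftmost minimal-distance start, making the final
# set independent of partition, scheme and verification threshold
.canonicalize <- function(cand, index, pc, k) {
  if (nrow(cand) == 0)
    return(data.frame(start = numeric(0), end = numeric(0), d = integer(0)))
  n <- index$n
  plen <- length(pc)
  ends <- sort(unique(cand$end))
  lo <- pmax(0, ends - plen - k)
  hi <- pmin(n - 1, ends)
  # merge overlapping windows
  merged <- list()
  cur_lo <- lo[1]; cur_hi <- hi[1]
  if (length(ends) > 1) {
    for (i in 2:length(ends)) {
      if (lo[i] <= cur_hi) cur_hi <- max(cur_hi, hi[i])
      else { merged[[length(merged) + 1L]] <- c(cur_lo, cur_hi); cur_lo <- lo[i]; cur_hi <- hi[i] }
    }
  }
  merged[[length(merged) + 1L]] <- c(cur_lo, cur_hi)
  out <- lapply(merged, function(w) {
    slice <- cpp_index_text(.fm_ptr(index), w[1], w[2])
    hits <- cpp_canonical_hits(slice, pc, as.integer(k))
    data.frame(start = hits$start + w[1], end = hits$end + w[1], d = hits$d)
  })
  dedupe_occurrences(do.call(rbind, out))
}

#' Find all approximate occurrences of a pattern (all mode)
#'
#' The full lossless pipeline: partition the pattern (uniformly or
#' dynamically), pick a search scheme (a supplied one, the bundled
#' pigeonhole scheme, or the lowest-workload candidate under dynamic
#' selection), execute every search over the index, canonicalize the
#' candidate set, then collapse duplicates and (optionally) cluster
#' redundant variants. For every text position at which some substring is
#' within edit distance `k` of the pattern, a covering occurrence is
#' reported.
#'
#' @param index An `fm_index`.
#' @param pattern Character string, longer than `k`.
#' @param k Error budget, `0..13`.
#' @param scheme A [search_scheme()], a list of candidate schemes (dynamic
#'   selection picks one), or `NULL` for the pigeonhole scheme.
#' @param partition `"dynamic"` (default), `"uniform"`, or an explicit cut
#'   vector.
#' @param in_text_threshold Switch to in-text verification below this
#'   candidate count (default 4).
#' @param cluster Cluster redundant overlapping variants (default `TRUE`);
#'   with `FALSE` every hit end position is returned.
#' @return Data frame with 0-based half-open `start`, `end`, edit distance
#'   `d` (and `n_variants` when clustered).
#' @export
approximate_match <- function(index, pattern, k, scheme = NULL,
                              partition = "dynamic", in_text_threshold = 4,
                              cluster = TRUE) {
  k <- as.integer(k)
  if (k < 0 || k > 13) stop("k must be between 0 and 13 errors")
  plen <- nchar(pattern)
  if (plen <= k) stop("pattern must be longer than k")
  if (is.null(scheme)) scheme <- pigeonhole_scheme(k)
  if (is.list(scheme) && !inherits(scheme, "search_scheme")) {
    cuts0 <- uniform_partition(plen, scheme[[1]]$p)
    scheme <- select_scheme(scheme, pattern, cuts0, index)
  }
  if (plen < scheme$p) stop("pattern shorter than the number of parts")
  cuts <- if (is.numeric(partition)) as.integer(partition)
  else if (identical(partition, "dynamic")) dynamic_partition(pattern, scheme$p, index)
  else uniform_partition(plen, scheme$p)
  pc <- dna_codes(pattern)
  cand <- do.call(rbind, lapply(scheme$searches, function(s)
    execute_search(index, pattern, s, cuts, k, in_text_threshold)))
  occ <- .canonicalize(cand[cand$d <= k, , drop = FALSE], index, pc, k)
  occ <- .filter_record_bounds(occ, index)
  if (cluster) cluster_occurrences(occ) else occ
}

#' Find all optimal occurrences (all-best mode)
#'
#' Strata-based search: error budgets `0, 1, ..., k_max` are tried in turn
#' and the first non-empty result is kept, so only occurrences at the
#' minimal edit distance (the read's stratum) are reported.
#'
#' @inheritParams approximate_match
#' @param k_max Largest stratum to try, `0..13`.
#' @return List with `occurrences` (as [approximate_match()], filtered to
#'   the minimal distance) and `stratum` (`NA` if nothing was found up to
#'   `k_max`).
#' @export
all_best_match <- function(index, pattern, k_max, scheme = NULL,
                           partition = "dynamic", in_text_threshold = 4,
                           cluster = TRUE) {
  for (k in 0:k_max) {
    occ <- approximate_match(index, pattern, k, scheme = scheme,
                             partition = partition,
                             in_text_threshold = in_text_threshold,
                             cluster = cluster)
    if (nrow(occ) > 0) {
      stratum <- min(occ$d)
      return(list(occurrences = occ[occ$d == stratum, , drop = FALSE],
                  stratum = stratum))
    }
  }
  list(occurrences = occ, stratum = NA_integer_)
}
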