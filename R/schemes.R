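#' Construct a single search of a search scheme
#'
#' A search is the triple `(pi, L, U)`: `pi` is the order in which the parts
#' of the pattern are matched (1-based part numbers) and must satisfy the
#' connectivity property (each next part is adjacent to the contiguous block
#' of already-processed parts, so index extension is always on one end);
#' `L` and `U` are non-decreasing lower and upper bounds on the cumulative
#' number of errors after each processed part.
#'
#' @param pi Integer permutation of `1..p`.
#' @param L,U Integer vectors of length `p`.
#' @return An object of class `ss_search`.
#' @export
ss_search <- function(pi, L, U) {
  s <- structure(list(pi = as.integer(pi), L = as.integer(L), U = as.integer(U)),
                 class = "ss_search")
  s
}

#' @export
print.ss_search <- function(x, ...) {
  cat(format_search(x), "\n")
  invisible(x)
}

format_search <- function(s) {
  sprintf("{%s} {%s} {%s}",
          paste(s$pi, collapse = ","),
          paste(s$L, collapse = ","),
          paste(s$U, collapse = ","))
}

#' Validate a search against the search-scheme invariants
#'
#' Checks, in order: that `pi` is a permutation of `1..p` processed
#' contiguously (connectivity), that `L` and `U` are non-decreasing, and
#' that `L[i] <= U[i]` everywhere. Never raises; returns `TRUE` or a string
#' describing the first violated rule.
#'
#' @param s An [ss_search()].
#' @param p Number of parts.
#' @return `TRUE`, or a character description of the violation.
#' @export
validate_search <- function(s, p) {
  if (length(s$pi) != p || length(s$L) != p || length(s$U) != p)
    return(sprintf("pi, L and U must all have length p = %d", p))
  if (!setequal(s$pi, seq_len(p)))
    return(sprintf("pi = (%s) is not a permutation of 1..%d",
                   paste(s$pi, collapse = ","), p))
  if (p > 1) {
    lo <- hi <- s$pi[1]
    for (i in 2:p) {
      q <- s$pi[i]
      if (q != lo - 1L && q != hi + 1L)
        return(sprintf("connectivity violation: part %d is not adjacent to processed block [%d,%d]",
                       q, lo, hi))
      lo <- min(lo, q); hi <- max(hi, q)
    }
  }
  if (any(diff(s$L) < 0)) return("L must be non-decreasing")
  if (any(diff(s$U) < 0)) return("U must be non-decreasing")
  if (any(s$L > s$U)) return("L[i] <= U[i] violated")
  TRUE
}

#' Construct a search scheme
#'
#' A search scheme for `k` errors is a collection of searches over the same
#' `p` parts that jointly cover every distribution of at most `k` errors, so
#' every approximate occurrence is found by at least one search.
#'
#' @param k Maximum number of errors.
#' @param searches Non-empty list of [ss_search()] objects with a common `p`.
#' @param check_coverage Also verify coverage with [covers()].
#' @return An object of class `search_scheme` with elements `k`, `p`,
#'   `searches`.
#' @export
search_scheme <- function(k, searches, check_coverage = FALSE) {
  if (length(searches) == 0) stop("a scheme needs at least one search")
  p <- length(searches[[1]]$pi)
  for (i in seq_along(searches)) {
    v <- validate_search(searches[[i]], p)
    if (!isTRUE(v)) stop(sprintf("search %d invalid: %s", i, v))
  }
  sch <- structure(list(k = as.integer(k), p = as.integer(p), searches = searches),
                   class = "search_scheme")
  if (check_coverage) {
    cv <- covers(sch, k)
    if (!isTRUE(cv))
      stop(sprintf("scheme does not cover all error distributions; witness (%s)",
                   paste(attr(cv, "witness"), collapse = ",")))
  }
  sch
}

#' @export
print.search_scheme <- function(x, ...) {
  cat(sprintf("search scheme: k = %d, p = %d, %d searches\n",
              x$k, x$p, length(x$searches)))
  for (s in x$searches) cat(" ", format_search(s), "\n")
  invisible(x)
}

#' Does a scheme cover every error distribution?
#'
#' A scheme covers `k` if for every error vector `(a_1..a_p)` with sum at
#' most `k` some search admits it, i.e. all cumulative sums in that search's
#' processing order lie within its `[L, U]` bounds. Coverage is decided by
#' exhaustive enumeration of error vectors; for schemes in which every
#' search matches its first part exactly (`U[1] = 0`, `L = 0`,
#' `U[i] >= k` beyond the first part) with first parts covering all of
#' `1..p >= k+1` parts, coverage follows structurally from the pigeonhole
#' principle (every vector with sum `<= k < p` has a zero part) and the
#' enumeration is skipped, which keeps large `k` tractable.
#'
#' @param scheme A [search_scheme()].
#' @param k Error budget to check (defaults to `scheme$k`).
#' @return `TRUE`, or `FALSE` with attribute `witness`, the first uncovered
#'   error vector.
#' @export
covers <- function(scheme, k = scheme$k) {
  p <- scheme$p
  firsts <- vapply(scheme$searches, function(s) s$pi[1], integer(1))
  structural <- p >= k + 1 &&
    all(vapply(scheme$searches, function(s)
      s$U[1] == 0 && all(s$L == 0) && (p == 1 || all(s$U[-1] >= k)),
      logical(1))) &&
    setequal(firsts, seq_len(p))
  if (structural) return(TRUE)
  if (choose(k + p, p) > 5e6)
    stop("coverage enumeration too large for this k and p")
  ns <- length(scheme$searches)
  pis <- t(vapply(scheme$searches, function(s) s$pi - 1L, integer(p)))
  Ls <- t(vapply(scheme$searches, function(s) s$L, integer(p)))
  Us <- t(vapply(scheme$searches, function(s) s$U, integer(p)))
  if (p == 1) { pis <- matrix(pis, ns, p); Ls <- matrix(Ls, ns, p); Us <- matrix(Us, ns, p) }
  w <- cpp_coverage_witness(pis, Ls, Us, p, as.integer(k))
  if (length(w) == 0) TRUE else structure(FALSE, witness = as.integer(w))
}

#' Pigeonhole search scheme for k errors
#'
#' The simplest lossless scheme: the pattern is split into `p = k + 1`
#' parts, and search `j` matches part `j` exactly first, then extends
#' outward (right before left) allowing up to `k` cumulative errors in the
#' remaining parts. If an occurrence has at most `k` errors, at least one
#' part is error-free, so the scheme covers every error distribution.
#'
#' @param k Maximum number of errors, `0 <= k <= 13`.
#' @return A [search_scheme()].
#' @export
pigeonhole_scheme <- function(k) {
  if (k < 0 || k > 13) stop("k must be between 0 and 13")
  p <- k + 1L
  searches <- lapply(seq_len(p), function(j) {
    if (j == p) pi <- rev(seq_len(p))
    else if (j == 1) pi <- seq_len(p)
    else pi <- c(j, (j + 1L):p, (j - 1L):1L)
    ss_search(pi, rep(0L, p), c(0L, rep(as.integer(k), p - 1L)))
  })
  search_scheme(k, searches)
}

# ---- scheme files ---------------------------------------------------------

#' Read and write search-scheme files
#'
#' File dialect: `#` starts a comment; the first non-comment line is
#' `k <int>`; every following non-comment line is one search written as
#' three brace-delimited comma-separated integer lists, e.g.
#' `{1,2,3} {0,0,0} {0,1,2}` for `pi`, `L`, `U` (1-based part numbers).
#' A file holds one scheme; a collection is a directory of such files.
#' Every loaded scheme is validated and coverage-checked; invalid input is
#' rejected with a message naming the file and line.
#'
#' @param path For `parse_scheme_file`, one file; for
#'   `parse_scheme_collection`, a directory of `.txt` files (or a single
#'   file). For `write_scheme_file`, the output path.
#' @return `parse_scheme_file`: a [search_scheme()].
#'   `parse_scheme_collection`: a named list, keyed by `k`, of lists of
#'   schemes.
#' @export
parse_scheme_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) < 2)
    stop(sprintf("%s: expected a 'k <int>' header and at least one search", path))
  hdr <- lines[keep[1]]
  m <- regmatches(hdr, regexec("^\\s*k\\s+(\\d+)\\s*$", hdr))[[1]]
  if (length(m) == 0)
    stop(sprintf("%s:%d: malformed header '%s' (expected 'k <int>')", path, keep[1], hdr))
  k <- as.integer(m[2])
  searches <- lapply(keep[-1], function(ln) {
    txt <- lines[ln]
    mm <- regmatches(txt, regexec(
      "^\\s*\\{([0-9, ]+)\\}\\s+\\{([0-9, ]+)\\}\\s+\\{([0-9, ]+)\\}\\s*$", txt))[[1]]
    if (length(mm) == 0)
      stop(sprintf("%s:%d: malformed search line '%s'", path, ln, txt))
    parse_ints <- function(x) as.integer(strsplit(x, ",")[[1]])
    ss_search(parse_ints(mm[2]), parse_ints(mm[3]), parse_ints(mm[4]))
  })
  p <- length(searches[[1]]$pi)
  for (i in seq_along(searches)) {
    v <- validate_search(searches[[i]], p)
    if (!isTRUE(v))
      stop(sprintf("%s:%d: invalid search: %s", path, keep[1 + i], v))
  }
  sch <- search_scheme(k, searches)
  cv <- covers(sch, k)
  if (!isTRUE(cv))
    stop(sprintf("%s: scheme does not cover k = %d; uncovered error vector (%s)",
                 path, k, paste(attr(cv, "witness"), collapse = ",")))
  sch
}

#' @rdname parse_scheme_file
#' @export
parse_scheme_collection <- function(path) {
  files <- if (dir.exists(path))
    list.files(path, pattern = "\\.txt$", full.names = TRUE) else path
  if (length(files) == 0) stop(sprintf("no scheme files found under %s", path))
  out <- list()
  for (f in files) {
    sch <- parse_scheme_file(f)
    key <- as.character(sch$k)
    out[[key]] <- c(out[[key]], list(sch))
  }
  out[order(as.integer(names(out)))]
}

#' @rdname parse_scheme_file
#' @param scheme A [search_scheme()] to write.
#' @export
write_scheme_file <- function(scheme, path) {
  lines <- c(sprintf("# search scheme for k = %d, p = %d parts", scheme$k, scheme$p),
             sprintf("k %d", scheme$k),
             vapply(scheme$searches, format_search, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' The pigeonhole schemes bundled with the package
#'
#' @return Named list keyed by `k` (`"0".."13"`) of lists of schemes.
#' @export
bundled_schemes <- function() {
  dir <- system.file("extdata", "schemes", package = "ssaligner")
  parse_scheme_collection(dir)
}

# ---- partitioning ---------------------------------------------------------

#' Partition a pattern into p parts
#'
#' `uniform_partition` splits as evenly as possible (part lengths differ by
#' at most one, leftover distributed left to right). `dynamic_partition`
#' starts from the uniform cuts and greedily widens the part with the most
#' exact matches in the reference at the expense of a neighbour, balancing
#' the estimated workload of the searches; the set of reported occurrences
#' is unaffected by the partition (losslessness is partition-invariant),
#' only the search-tree size changes.
#'
#' @param pattern_length,p Pattern length and number of parts.
#' @return Integer vector of `p + 1` cut positions (0-based; first 0, last
#'   the pattern length).
#' @export
uniform_partition <- function(pattern_length, p) {
  if (p > pattern_length) stop("more parts than pattern characters")
  base <- pattern_length %/% p
  lens <- rep(base, p)
  extra <- pattern_length %% p
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  as.integer(cumsum(c(0L, lens)))
}

#' @rdname uniform_partition
#' @param pattern Character string to partition.
#' @param index An `fm_index` used for exact-match counts.
#' @param tolerance Stop once `max(count)/max(1, min(count))` is below this.
#' @param budget Maximum number of single-column boundary moves (default
#'   `2 * p`).
#' @export
dynamic_partition <- function(pattern, p, index, tolerance = 4, budget = 2L * p) {
  len <- nchar(pattern)
  if (p > len) stop("more parts than pattern characters")
  cuts <- uniform_partition(len, p)
  if (p == 1) return(cuts)
  part_count <- function(cuts, i)
    count_exact(index, substr(pattern, cuts[i] + 1L, cuts[i + 1L]))
  counts <- vapply(seq_len(p), function(i) part_count(cuts, i), numeric(1))
  for (mv in seq_len(budget)) {
    if (max(counts) <= tolerance * max(1, min(counts))) break
    i <- which.max(counts)
    # grow part i by one column from the neighbour with the smaller count
    nb <- c(if (i > 1) i - 1L, if (i < p) i + 1L)
    nb <- nb[which.min(counts[nb])]
    new_cuts <- cuts
    if (nb < i) new_cuts[i] <- cuts[i] - 1L else new_cuts[i + 1L] <- cuts[i + 1L] + 1L
    lens <- diff(new_cuts)
    if (any(lens < 1)) break
    new_i <- part_count(new_cuts, i)
    if (new_i >= counts[i]) break                 # no improvement possible
    cuts <- new_cuts
    counts[i] <- new_i
    counts[nb] <- part_count(cuts, nb)
  }
  cuts
}

#' Pick the scheme with the lowest estimated workload
#'
#' The workload of a search is estimated by the number of exact matches of
#' the part it matches first; a scheme's estimate is the sum over its
#' searches. Ties break by candidate order.
#'
#' @param candidates Non-empty list of [search_scheme()]s for the same `k`.
#' @param pattern Character string being matched.
#' @param partition Cut positions from [uniform_partition()] or
#'   [dynamic_partition()].
#' @param index An `fm_index`.
#' @return The selected scheme.
#' @export
select_scheme <- function(candidates, pattern, partition, index) {
  if (length(candidates) == 0) stop("empty candidate list")
  est <- vapply(candidates, function(sch) {
    sum(vapply(sch$searches, function(s) {
      j <- s$pi[1]
      count_exact(index, substr(pattern, partition[j] + 1L, partition[j + 1L]))
    }, numeric(1)))
  }, numeric(1))
  candidates[[which.min(est)]]
}
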