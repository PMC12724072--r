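# Naive reference implementations used as independent oracles, plus small
# fixture builders. All fixtures are generated in code under fixed seeds.

BASES <- c("A", "C", "G", "T")

rand_text <- function(n, prob = NULL) {
  paste(sample(BASES, n, replace = TRUE, prob = prob), collapse = "")
}

# BWT by explicitly sorting all rotations of text + sentinel
naive_bwt <- function(s) {
  s2 <- paste0(s, "$")
  n <- nchar(s2)
  rot <- vapply(0:(n - 1), function(i)
    paste0(substr(s2, i + 1, n), substr(s2, 1, i)), character(1))
  paste(substring(sort(rot), n, n), collapse = "")
}

# 0-based start positions of exact occurrences, by sliding window
naive_occ <- function(text, pat) {
  n <- nchar(text); m <- nchar(pat)
  if (m > n || m == 0) return(integer(0))
  hits <- which(vapply(1:(n - m + 1), function(i)
    substr(text, i, i + m - 1) == pat, logical(1)))
  hits - 1L
}

# does a search admit an error vector? (cumulative sums within [L, U])
admits <- function(search, avec) {
  cum <- cumsum(avec[search$pi])
  all(cum >= search$L & cum <= search$U)
}

# brute-force coverage: enumerate every error vector with sum <= k
brute_covers <- function(scheme, k) {
  p <- scheme$p
  grid <- expand.grid(rep(list(0:k), p))
  grid <- grid[rowSums(grid) <= k, , drop = FALSE]
  for (r in seq_len(nrow(grid))) {
    avec <- as.integer(grid[r, ])
    if (!any(vapply(scheme$searches, admits, logical(1), avec = avec)))
      return(structure(FALSE, witness = avec))
  }
  TRUE
}

# plant nmut random edits into a string (substitutions / indels)
mutate_seq <- function(s, nmut) {
  v <- strsplit(s, "")[[1]]
  for (z in seq_len(nmut)) {
    op <- sample(3, 1)
    i <- sample(length(v), 1)
    if (op == 1) v[i] <- sample(setdiff(BASES, v[i]), 1)
    else if (op == 2 && length(v) > 5) v <- v[-i]
    else v <- append(v, sample(BASES, 1), after = i)
  }
  paste(v, collapse = "")
}

# end positions (0-based, exclusive coords: substring ends) with minimal
# edit distance <= k, from the package's scalar scan oracle
oracle_ends <- function(text, pattern, k) {
  d <- sellers_scan(text, pattern)
  ends <- which(d <= k) - 1L
  ends[ends >= 1]
}

# leftmost minimal-distance start for a substring ending at `end`
# (independent R dynamic programme, used by the pair oracle)
r_best_start <- function(text, end, pattern, k) {
  tc <- strsplit(text, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  m <- length(pc)
  span <- min(end, m + k)
  prev <- 0:span
  for (i in 1:m) {
    cur <- numeric(span + 1)
    cur[1] <- i
    for (l in 1:span) {
      sub <- if (tc[end - l + 1] == pc[m - i + 1]) 0 else 1
      cur[l + 1] <- min(prev[l + 1] + 1, cur[l] + 1, prev[l] + sub)
    }
    prev <- cur
  }
  best <- min(prev)
  l <- max(which(prev == best)) - 1L
  c(start = end - l, d = best)
}

# trivial covering scheme: one search, full budget everywhere
trivial_scheme <- function(k) {
  search_scheme(k, list(ss_search(seq_len(k + 1L), rep(0L, k + 1L),
                                  rep(as.integer(k), k + 1L))))
}

cigar_read_len <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  sum(as.integer(sub("[A-Z=]", "", ops[grepl("[MI=X]$", ops)])))
}

cigar_ref_len <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  sum(as.integer(sub("[A-Z=]", "", ops[grepl("[MD=XN]$", ops)])))
}

nm_of <- function(tags) as.integer(sub(".*NM:i:(\\d+).*", "\\1", tags))
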