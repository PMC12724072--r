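---
title: "Lossless read alignment with search schemes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lossless read alignment with search schemes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssaligner)
```

## The problem

Most production read aligners are *lossy*: they seed on exact matches and
report one or a few high-scoring alignments. For applications where a read
must be attributed to *every* reference it could plausibly come from —
HLA typing, pan-genome strain attribution, metagenomic classification,
benchmarking of lossy tools — what is needed is *lossless* alignment:
report **all** occurrences of a read within edit distance $k$ of the
reference ("all" mode), or all occurrences at the minimal distance
("all-best" mode). ssaligner implements that guarantee for $k \le 13$,
which targets Illumina-style short reads; beyond that (e.g. spliced RNA
gaps) the search-tree approach is not appropriate.

## The method

**Search schemes.** A pattern $P$ is split into $p$ parts. A *search*
$S = (\pi, L, U)$ processes the parts in the order $\pi$ (each next part
adjacent to the processed block, so the partial match grows on one end
only) and requires the cumulative error count after the $i$-th processed
part to lie in $[L[i], U[i]]$. A *scheme* is a set of searches that
jointly admit every error vector $(a_1,\dots,a_p)$ with $\sum a_i \le k$;
then every occurrence is found by at least one search. `covers()` decides
this by exhaustive enumeration of error vectors, with a structural
shortcut for exact-first ("pigeonhole-shaped") schemes where coverage
follows from $p \ge k+1$; the enumeration path is cross-checked against a
second, independent brute-force implementation in the test suite for
$k \le 5$. The bundled scheme library holds the pigeonhole schemes for
$k = 0..13$; optimized schemes can be supplied as plain text files (one
search per line, `{pi} {L} {U}`; the *design* of optimal schemes is out
of scope here).

**Bidirectional FM-index.** Searches extend partial matches on either
side, which a single BWT cannot do; the index therefore keeps the BWT of
the text and of its reverse, with a synchronized pair of suffix-array
intervals as search state. Rank structures are plain per-character prefix
count arrays (block size 1 — constant-time rank with simple code; at the
desk scale this package targets, the extra memory over a blocked design
is irrelevant). The suffix array is built by prefix doubling — any
correct sorter would do — and subsampled 4× by default; `locate()`
LF-walks to the nearest sampled entry.

**Banded bit-parallel rows.** During a search, each consumed text
character advances one row of a banded edit-distance matrix (band
half-width fixed at $k$ for the whole alignment — the simplest sound
choice, since any cell with $|{\rm row}-{\rm col}|>k$ exceeds the
budget). Rows are maintained as Myers-style $\pm 1$ delta bit vectors and
updated for all band cells at once. Two properties define the contract,
and the scalar dynamic programme is kept alongside as the reference: all
cells whose true value is $\le k$ are exact, and cells beyond the budget
may saturate to $k+1$ (band-edge fills make them overestimates, which is
sound because such cells can never participate in a reported alignment).

**Direction switches.** The alignment of the processed region is split at
the pattern position where the first part starts: text grown rightward is
scored against the pattern right of the cut, text grown leftward against
the reversed pattern left of it, each with its own banded row. Any
alignment path crosses the cut column at some row, so completion of a
part is attempted at *every* row where the part's final column lies in
the band — this per-row branching is what keeps the search lossless
across direction switches, at the price of redundant path variants that
the clustering step later absorbs.

**Bounds enforcement.** Upper bounds prune: a branch dies when the
in-band row minimum (over the columns processed so far) plus the
other side's committed distance exceeds $U[i]$ or $k$. Lower bounds are
enforced as a final reporting filter ($d \ge L[p]$): a hit that one
search drops for being *too good* is, by coverage, found by another
search whose bounds admit its actual error vector, so losslessness is
unaffected. Intermediate reachability pruning on $L$ would only change
speed, not output, and is omitted.

**In-text verification.** When a branch's candidate count (range width)
drops below a threshold (default 4), index extension stops: candidates
are located, and the full pattern is verified against a reference window
by a multi-word bit-parallel scan. The window is padded so that every
occurrence compatible with the partial match is contained in it; the
verification therefore returns a superset of what further index-space
extension would have produced, and all of it is genuine (every reported
position is re-scored). This full-pattern window verification is simpler
than resuming the banded state against the slice and provably yields the
same final output.

**Canonicalization, dedupe, clustering.** Raw candidates from different
searches, partitions and verification paths describe the same alignments
with shifted boundaries (a leading/trailing gap exchanged for a
substitution). Every candidate end position is therefore re-scored by a
local scan and assigned its minimal distance and leftmost
minimal-distance start. Because (a) the index path is lossless and (b)
every verification hit is true, the canonical hit set equals the set of
*all* true hit positions regardless of partition, scheme, or threshold —
this is what makes the configuration-invariance guarantees exact rather
than approximate. Exact duplicates are collapsed; overlapping variants
are clustered, each group represented by its minimal-distance, leftmost,
longest member. Non-overlapping co-optimal occurrences are never merged.

## Read-level behaviour

Both strands are searched (the reverse complement of the read against the
forward text) and clustered per strand. All-best mode re-runs the search
at $k' = 0, 1, \dots$ until the first non-empty stratum; work is not
shared between strata — correct, and at these problem sizes the dominant
cost is the final stratum anyway. One record per read is primary
(smallest $d$, then leftmost position, then forward strand); co-optimal
occurrences are separate secondary records. MAPQ is a documented
convention (60 unique / 3 for 2–9 co-optimal / 0 beyond), not a
probability — a lossless aligner has no error model to calibrate one.
`NM` carries the edit distance; CIGARs come from a full-matrix traceback
against the located slice with tie preference match > substitution >
deletion > insertion, using `M` for both match and mismatch.

For pairs, "optimal proper pair" is interpreted as minimising
$d_1 + d_2$ (the natural reading of smallest total edit distance across
both mates; max-based optimality would be a one-line change). Proper
pairs must be convergent (leftmost mate forward) with outer fragment
length within six standard deviations of the inferred mean; both mates'
occurrence sets are expanded to the full budget $k$ before the
cross-product, because an optimal pair need not combine each mate's
individually optimal alignments. The fragment model is estimated from the
first 1000 pairs with unique concordant best alignments; with fewer than
50 usable pairs the model falls back to mean 400 bp, sd 100 bp (a
typical short-insert Illumina library) and says so.

Reference bases outside ACGT are replaced at indexing time by a reserved
fifth character that matches nothing — including `N` in reads — so any
alignment across such a position pays exactly one error. This keeps
"within edit distance $k$" well-defined on real references. Multi-record
FASTA references are concatenated with a single sentinel; occurrences
that would span a record boundary are discarded at location time, which
is simpler than per-record separators and directly testable.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` / `error_rate` | — | edit-distance budget; a rate converts as $\lfloor \text{rate} \times \text{length} \rfloor$, ceiling 13 (2% of 151 bp → 3; 8% of 150 bp → 12) |
| `sa_sampling` | 4 | suffix-array subsampling; memory vs `locate` speed |
| `in_text_threshold` | 4 | switch to in-text verification below this candidate count; changes speed only, never output |
| `partition` | dynamic | dynamic partitioning grows the part with the most exact matches (budget $2p$ moves, stop at max/min ratio ≤ 4) to balance search workload; output-invariant |
| fragment window | $\mu \pm 6\sigma$ | proper-pair acceptance window, inferred from data |

The dynamic-partition move budget and tolerance are heuristic knobs for a
pure performance optimisation: since partitioning cannot change the
output, any setting is safe, and the defaults keep the greedy loop short.

## What the synthetic generator does and does not emulate

`random_genome()` draws i.i.d. bases at a requested GC content;
`sample_reads()` plants reads uniformly (strand uniform) with independent
per-base substitution/insertion/deletion rates and records a truth table
whose distance is *re-verified by dynamic programming* against the origin
segment (adjacent planted operations can cancel, so the operation count
alone would overstate the truth). Paired mode plants convergent pairs at
normally distributed fragment lengths. This exercises every code path —
but an i.i.d. genome has no repeat structure, no homopolymer error bias,
no quality-correlated errors and no coverage bias. Passing the planted
recovery tests therefore demonstrates the *lossless-search guarantee*
(no occurrence within budget is missed, pairs are jointly optimal), not
calibrated performance on real genomes; conversely, since losslessness
is a combinatorial property of the algorithm, the i.i.d. setting is not
a weak test of it, and repeat-induced multi-mapping is covered by the
co-optimal record handling.

## Problem sizes used in the checks

The test-suite and acceptance-script sizes were chosen to be rich enough
to exercise every branch while staying desk-scale: 200 random instances
(texts to 3 kb, reads 30–100 bp, $k \le 5$) for the oracle comparisons,
$10^4$ random triples for bit-parallel/scalar row equivalence, and a
100 kb, 3-record genome with 1000 single reads plus 500 pairs (1%
substitutions, 0.2% indels, fragments 400 ± 40) for planted recovery.
The oracle is an $O(|P| \cdot n)$ scalar scan in a separate code path
from the search machinery, and the pair oracle is a brute-force
cross-product over both mates' oracle occurrence sets.

## Numerical / degenerate-input choices

- Tie-breaks are everywhere deterministic: scheme selection by candidate
  order, cluster representatives by (min $d$, leftmost, longest),
  primary record by ($d$, position, strand), CIGAR traceback by
  operation preference. The original tool's tie-breaks are not
  documented; ours are ours.
- Degenerate inputs: empty ranges are results, not errors; unmapped
  reads produce FLAG-4 records; `dynamic_partition` falls back to the
  uniform cuts whenever no move improves balance; patterns must be
  longer than $k$ (otherwise the empty string is within budget
  everywhere and the question is ill-posed).
- All internal coordinates are 0-based half-open; SAM emission converts
  to 1-based at the boundary, in exactly one place.

## Known limitations

Single-threaded by design. The FM-index is plain (no run-length
compression), so memory is $O(n)$ — desk-scale references, not
pan-genomes. All-best re-runs strata from scratch. PAF/BAM output,
spliced alignment and affine gap scores are out of scope. MAPQ is
conventional, not probabilistic.
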