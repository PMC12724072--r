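# ssaligner

Lossless approximate read alignment with search schemes over a
bidirectional FM-index, in R (with a C++ core).

Most short-read aligners are lossy: they seed on exact matches and report
one or a few good alignments. For tasks where a read must be attributed to
*every* reference sequence it could have come from — HLA typing,
pan-genome strain attribution, metagenomic read classification,
benchmarking lossy tools — you want *lossless* alignment: report **all**
occurrences of a read within edit distance *k* ("all" mode), or all
occurrences at the minimal distance ("all-best" mode, strata-based). This
package implements that guarantee for k ≤ 13 at desk scale, single- and
paired-end, FASTQ/FASTA in, SAM out.

## The method in brief

A pattern *P* is split into *p* parts. A **search scheme** is a set of
searches *S = (π, L, U)* — a part processing order (connected, so the
partial match always grows on one end) plus non-decreasing lower/upper
bounds on the cumulative error count — that jointly *cover* every
distribution of ≤ k errors over the parts, so every occurrence is found
by at least one search. Searches run over a **bidirectional FM-index**
(BWT of the text and of its reverse, with synchronized interval pairs),
extending partial matches character by character while a **banded
bit-parallel row** (Myers-style delta vectors, band half-width k) tracks
the edit distance. Sparse candidate sets switch to **in-text
verification** (threshold 4 by default). Patterns are partitioned
**dynamically** (balancing exact-match counts per part) and schemes can be
**dynamically selected** per read; redundant boundary variants of the same
alignment are **clustered** to representatives. Proper pairs minimise
d1 + d2 in convergent orientation with the fragment length within six
standard deviations of a mean **inferred from the data**.

## Worked example

```r
library(ssaligner)

g   <- random_genome(20000, n_records = 2, gc = 0.45, seed = 3)
idx <- build_index(g$sequences)          # 4x subsampled SA by default

read <- substr(g$sequences[1], 501, 600) # 100-mer from chr1:501-600
substr(read, 40, 40) <- "T"              # plant one substitution

all_best_match(idx, read, k_max = 4)
#> $occurrences
#>   start end d n_variants
#> 1   500 600 1          1
#> $stratum
#> [1] 1
```

The read's minimal edit distance (its *stratum*) is 1, and the single
occurrence covers 0-based reference interval [500, 600) — exactly the
planted origin. Mapping the same read yields a SAM record:

```r
rec <- map_single(list(name = "r1", seq = read), idx, k = 3)
rec[, c("qname", "flag", "rname", "pos", "mapq", "cigar", "tags")]
#>   qname flag rname pos mapq cigar            tags
#> 1    r1    0  chr1 501   60  100M NM:i:1\tAS:i:-1
```

`pos` is 1-based (internal coordinates are 0-based half-open), `NM` is
the edit distance, MAPQ 60 means the best occurrence is unique.

Command line (thin wrappers over the same functions):

```sh
ssaligner index --ref ref.fa --out idx/
ssaligner align --index idx/ --reads r1.fq --reads2 r2.fq \
    --error-rate 0.04 --mode all-best --out out.sam
```

## Layout

- `R/`, `src/` — package code (index, schemes, matching engine, mapping,
  io, synthetic data, CLI; C++ core via Rcpp)
- `inst/extdata/schemes/` — bundled pigeonhole search schemes, k = 0..13
- `vignettes/lossless-alignment.Rmd` — the model, its assumptions, and
  the design decisions
- `tests/testthat/` — unit, property and acceptance tests
- `exec/ssaligner` — command-line front end
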