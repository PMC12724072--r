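#' Read FASTA / FASTQ files
#'
#' Thin wrappers over Biostrings that return plain data frames. Sequences
#' are case-folded to upper case; gzip compression is detected from the
#' file content, and multi-line FASTA records are folded. Malformed input
#' is rejected by the underlying parser with a message naming the file.
#'
#' @param path Input file.
#' @return `read_fasta`: data frame with `name`, `seq`.
#'   `read_fastq`: data frame with `name`, `seq`, `qual`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) stop(sprintf("%s: malformed FASTA: %s",
                                                 path, conditionMessage(e))))
  data.frame(name = sub("\\s.*$", "", names(x)),
             seq = toupper(as.character(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  tryCatch({
    # Biostrings warns about dropping (empty) metadata columns on FASTQ input
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    qual <- as.character(Biostrings::quality(x))
    if (any(nchar(qual) != Biostrings::width(x)))
      stop(sprintf("quality length mismatch at record %d",
                   which(nchar(qual) != Biostrings::width(x))[1]))
    data.frame(name = sub("\\s.*$", "", names(x)),
               seq = toupper(as.character(x)),
               qual = qual,
               row.names = NULL, stringsAsFactors = FALSE)
  }, error = function(e) stop(sprintf("%s: malformed FASTQ: %s",
                                      path, conditionMessage(e))))
}

#' Write FASTA / FASTQ files
#'
#' @param records Data frame with `name`, `seq` (and `qual` for FASTQ).
#' @param path Output file.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::BStringSet(records$seq)
  names(x) <- records$name
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(records, path) {
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- records$name
  q <- Biostrings::BStringSet(records$qual)
  # QualityScaledDNAStringSet warns that it drops (empty) metadata columns
  qs <- suppressWarnings(
    Biostrings::QualityScaledDNAStringSet(x, Biostrings::PhredQuality(q)))
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Write alignment records as SAM
#'
#' Emits a valid SAM file: `@HD`, one `@SQ` line per reference record (from
#' the index's record table), `@PG`, then the alignment lines in standard
#' field order. Positions are converted from the package's internal 0-based
#' coordinates to SAM's 1-based `POS` upstream, in [map_single()] /
#' [map_pair()]; this writer emits records as given.
#'
#' @param records Data frame of SAM fields (`qname`, `flag`, `rname`,
#'   `pos`, `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`,
#'   `tags`).
#' @param header_info List with `records` (the index record table, for
#'   `@SQ`) and optionally `cl` (the command line for `@PG`).
#' @param path Output file.
#' @export
write_sam <- function(records, header_info, path) {
  rec <- header_info$records
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", rec$name, rec$length),
           sprintf("@PG\tID:ssaligner\tPN:ssaligner\tVN:%s%s",
                   as.character(utils::packageVersion("ssaligner")),
                   if (!is.null(header_info$cl))
                     sprintf("\tCL:%s", header_info$cl) else ""))
  lines <- hdr
  if (nrow(records) > 0) {
    known <- c(rec$name, "*")
    if (!all(records$rname %in% known))
      stop(sprintf("record references unknown RNAME: %s",
                   paste(setdiff(records$rname, known), collapse = ", ")))
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s%s",
                              records$qname, records$flag, records$rname,
                              records$pos, records$mapq, records$cigar,
                              records$rnext, records$pnext, records$tlen,
                              records$seq, records$qual,
                              ifelse(nzchar(records$tags),
                                     paste0("\t", records$tags), "")))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- index serialization --------------------------------------------------

.INDEX_FORMAT_VERSION <- 1L

#' Save / load an FM-index
#'
#' The on-disk layout is a directory holding the sanitized text, the record
#' table and a JSON manifest with a format version and a checksum of the
#' text; `load_index` validates both and rebuilds the index structures.
#'
#' @param index An `fm_index`.
#' @param directory Target / source directory.
#' @return `load_index` returns an `fm_index` answering queries identically
#'   to the one saved.
#' @export
save_index <- function(index, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  txt <- reference_slice(index, 0L, index$n - 1L)
  seq_path <- file.path(directory, "text.txt")
  writeLines(txt, seq_path)
  utils::write.table(index$records, file.path(directory, "records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(format = "ssaligner-index",
                   version = .INDEX_FORMAT_VERSION,
                   sa_sampling = index$sa_sampling,
                   n = index$n,
                   text_md5 = unname(tools::md5sum(seq_path)))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(directory)
}

#' @rdname save_index
#' @export
load_index <- function(directory) {
  man_path <- file.path(directory, "manifest.json")
  if (!file.exists(man_path))
    stop(sprintf("%s: not an index directory (no manifest.json)", directory))
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  if (!identical(man$format, "ssaligner-index") ||
      !identical(as.integer(man$version), .INDEX_FORMAT_VERSION))
    stop(sprintf("%s: index format version mismatch (found %s, need %d)",
                 directory, man$version, .INDEX_FORMAT_VERSION))
  seq_path <- file.path(directory, "text.txt")
  if (!identical(unname(tools::md5sum(seq_path)), man$text_md5))
    stop(sprintf("%s: checksum mismatch, index file corrupt", directory))
  txt <- readLines(seq_path, warn = FALSE)[1]
  records <- utils::read.table(file.path(directory, "records.tsv"),
                               sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  codes <- dna_codes(txt)
  ptr <- cpp_index_build(codes, as.integer(man$sa_sampling))
  structure(list(ptr = ptr, n = length(codes) + 1L,
                 sa_sampling = as.integer(man$sa_sampling), records = records),
            class = "fm_index")
}
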