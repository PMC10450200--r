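# File-format glue: FASTQ + SAM in, TSV tables out. Parsing is delegated to
# Biostrings / Rsamtools; nothing here re-implements a format.

#' Read FASTQ + SAM alignments into the caller's input table
#'
#' Joins a FASTQ file (Phred+33) with the alignments of the trimmed
#' templated portions of the same reads, producing the `reads` data.frame
#' consumed by [call_tails()]. Only primary aligned records are kept;
#' the aligned query length is taken from the CIGAR (M/=/X/I operations).
#'
#' @param fastq Path to a FASTQ file.
#' @param sam Path to a SAM (or BAM) file.
#' @param sample_id Optional sample label carried through.
#' @return data.frame with `read_id`, `seq`, `qual`, `chrom`, `strand`,
#'   `align_pos`, `align_len` (unaligned reads are dropped).
#' @export
read_alignments <- function(fastq, sam, sample_id = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    .stopf("read_alignments() requires the Rsamtools package")
  fq <- Biostrings::readDNAStringSet(fastq, format = "fastq",
                                     with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(fq))
  bam <- if (grepl("\\.sam$", sam, ignore.case = TRUE)) {
    Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else sam
  aln <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "strand", "pos", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)))[[1]]
  qlen <- vapply(aln$cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    sum(as.integer(sub("[A-Z=]", "", ops[grepl("[MI=X]$", ops)])))
  }, integer(1), USE.NAMES = FALSE)
  m <- match(aln$qname, ids)
  keep <- !is.na(m)
  out <- data.frame(
    read_id = aln$qname[keep],
    seq = as.character(fq)[m[keep]],
    qual = as.character(S4Vectors::mcols(fq)$qualities)[m[keep]],
    chrom = as.character(aln$rname)[keep],
    strand = as.character(aln$strand)[keep],
    align_pos = aln$pos[keep],
    align_len = qlen[keep],
    stringsAsFactors = FALSE)
  if (!is.null(sample_id)) out$sample_id <- sample_id
  out
}

#' Read a PAS annotation from BED6
#'
#' @param path BED file; the name field is expected as `gene:site`.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `score`, `strand`, `gene_id`, `site_id`.
#' @export
read_pas_bed <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(d)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  parts <- strsplit(d$name, ":", fixed = TRUE)
  d$gene_id <- vapply(parts, `[`, character(1), 1L)
  d$site_id <- vapply(parts, function(p)
    if (length(p) > 1) p[2] else NA_character_, character(1))
  d
}

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' First column = feature ids, remaining columns = samples.
#' @param path TSV path.
#' @return Integer matrix with feature rownames.
#' @export
read_count_matrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}
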