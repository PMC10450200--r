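# Per-read poly(A) tail calling.
#
# The tail rule: an A-run is extended base by base, where a non-A base with
# Phred <= min_quality is tolerated as a wildcard (it cannot veto the run),
# and a non-A base with Phred > min_quality consumes error budget. The run
# stops when cumulative errors would exceed max_error_fraction * current
# run length, and is then trimmed so both ends are literal A.
#
# In the full pipeline the per-read tail is anchored at the aligned 3' end
# of the (adapter- and tail-trimmed) templated portion: the A-run is read
# off the sequence beyond the alignment, and genomic A's immediately
# downstream of the cleavage point are subtracted as templated.

#' Tail-calling parameters
#'
#' @param adapter 3' adapter sequence.
#' @param max_error_fraction Error budget as a fraction of the current run
#'   length (default 1/5: one error in five bases allowed).
#' @param min_quality Phred score at or below which a non-A base is treated
#'   as a wildcard rather than an error (default 10).
#' @param min_nontemplated Minimum non-templated A's for a read to count as
#'   polyadenylated (default 4).
#' @return A list of class `tail_call_params`.
#' @export
tail_call_params <- function(adapter = .DEFAULT_ADAPTER,
                             max_error_fraction = 1 / 5,
                             min_quality = 10L, min_nontemplated = 4L) {
  if (!nzchar(adapter)) .stopf("'adapter' must be non-empty")
  if (max_error_fraction <= 0 || max_error_fraction >= 1)
    .stopf("'max_error_fraction' must be in (0, 1)")
  structure(list(adapter = toupper(adapter),
                 max_error_fraction = max_error_fraction,
                 min_quality = as.integer(min_quality),
                 min_nontemplated = as.integer(min_nontemplated)),
            class = "tail_call_params")
}

#' @noRd
.phred <- function(qual) utf8ToInt(qual) - 33L

# Best-scoring adapter match in one read. Score = overlap - 5 * mismatches
# over candidates with >= min_overlap 3' overlap and mismatches <= 10% of
# the overlap; ties go to the match closest to the 3' end.
#' @noRd
.find_adapter <- function(s, adapter, min_overlap = 5L,
                          mismatch_frac = 0.1) {
  n <- nchar(s); la <- nchar(adapter)
  if (n < min_overlap) return(NA_integer_)
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  av <- strsplit(adapter, "", fixed = TRUE)[[1]]
  best <- NA_integer_; best_score <- -Inf
  for (i in seq_len(n - min_overlap + 1L)) {
    ol <- min(la, n - i + 1L)
    mm <- sum(sv[i:(i + ol - 1L)] != av[seq_len(ol)])
    if (mm <= floor(mismatch_frac * ol)) {
      score <- ol - 5L * mm
      if (score > best_score || (score == best_score && !is.na(best))) {
        best_score <- score; best <- i
      }
    }
  }
  best
}

#' Trim the 3' adapter from a read
#'
#' Removes the best adapter match (allowing 10\% mismatches and partial 3'
#' overlap of at least `min_overlap` nt) and everything 3' of it; the
#' quality string is trimmed in lockstep. Reads without a match are
#' returned unchanged.
#'
#' @param seq,quals Character vectors of read sequences and Phred+33
#'   quality strings (same lengths).
#' @param adapter Adapter sequence.
#' @param min_overlap Minimum 3' overlap (default 5).
#' @return list with trimmed `seq` and `quals`.
#' @examples
#' trim_adapter("ACGTACGTAGATCGGAAGAGC", strrep("I", 21),
#'              adapter = "AGATCGGAAGAGC")
#' @export
trim_adapter <- function(seq, quals, adapter = .DEFAULT_ADAPTER,
                         min_overlap = 5L) {
  if (!nzchar(adapter)) .stopf("'adapter' must be non-empty")
  stopifnot(length(seq) == length(quals))
  adapter <- toupper(adapter)
  pos <- vapply(toupper(seq), .find_adapter, integer(1),
                adapter = adapter, min_overlap = min_overlap,
                USE.NAMES = FALSE)
  keep <- ifelse(is.na(pos), nchar(seq), pos - 1L)
  list(seq = substr(seq, 1L, keep), quals = substr(quals, 1L, keep))
}

# Quality-aware A-run length along index order 'idx' (a vector of positions
# walking away from the anchored end). Returns accepted positions.
#' @noRd
.a_run <- function(sv, qv, idx, max_error_fraction, min_quality) {
  L <- 0L; E <- 0L; taken <- integer(0)
  for (i in idx) {
    if (sv[i] == "A") {
      L <- L + 1L
    } else if (qv[i] <= min_quality) {
      L <- L + 1L                               # wildcard
    } else if (E + 1L <= max_error_fraction * (L + 1L)) {
      E <- E + 1L; L <- L + 1L                  # budgeted error
    } else break
    taken <- c(taken, i)
  }
  if (!length(taken)) return(integer(0))
  # trim both ends to literal A
  is_a <- sv[taken] == "A"
  if (!any(is_a)) return(integer(0))
  taken[seq(which(is_a)[1], tail(which(is_a), 1))]
}

#' Call the poly(A) run at the 3' end of a read
#'
#' Extends an A-run leftward from the 3' end of an adapter-trimmed read
#' under the wildcard/error-budget rule, then trims the run so both ends
#' are literal A.
#'
#' @param seq A single read sequence (adapter already trimmed).
#' @param quals Its Phred+33 quality string.
#' @param params A [tail_call_params()] object.
#' @return list with `tail_total` (run length, 0 if no terminal A-run) and
#'   `tail_start_offset` (0-based offset of the run's first base; `NA` when
#'   `tail_total` is 0).
#' @examples
#' call_tail("CCGTAAAAAAAAAA", strrep("I", 14))
#' @export
call_tail <- function(seq, quals, params = tail_call_params()) {
  stopifnot(length(seq) == 1L)
  n <- nchar(seq)
  if (n == 0L) return(list(tail_total = 0L, tail_start_offset = NA_integer_))
  sv <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  qv <- .phred(quals)
  run <- .a_run(sv, qv, n:1, params$max_error_fraction, params$min_quality)
  if (!length(run)) return(list(tail_total = 0L,
                                tail_start_offset = NA_integer_))
  list(tail_total = length(run), tail_start_offset = min(run) - 1L)
}

# Leading genomic A-run (strand-aware) just past an aligned 3' end.
# chrom_seq: plain character contig sequence; cleavage_pos: 0-based
# coordinate of the last aligned base on the read strand.
#' @noRd
.templated_run <- function(chrom_seq, cleavage_pos, strand, max_n) {
  L <- nchar(chrom_seq)
  if (cleavage_pos < 0 || cleavage_pos >= L)
    .stopf("alignment end %d outside contig (length %d)", cleavage_pos, L)
  k <- 0L
  if (strand == "+") {
    p <- cleavage_pos + 2L                       # 1-based next position
    while (k < max_n && p <= L &&
           substr(chrom_seq, p, p) == "A") { k <- k + 1L; p <- p + 1L }
  } else {
    p <- cleavage_pos                            # 1-based previous position
    while (k < max_n && p >= 1L &&
           substr(chrom_seq, p, p) == "T") { k <- k + 1L; p <- p - 1L }
  }
  k
}

#' Count non-templated adenosines in a called tail
#'
#' Walks the genome from the position just past the aligned 3' end
#' (strand-aware: A on the read strand) and subtracts the leading genomic-A
#' matches from the called run length, floored at zero.
#'
#' @param tail_total Called A-run length for the read.
#' @param chrom,cleavage_pos,strand Alignment 3' end: contig name, 0-based
#'   strand-aware coordinate of the last aligned base, and strand.
#' @param genome A [Biostrings::DNAStringSet] (or named character vector).
#' @return Integer non-templated tail length.
#' @export
count_nontemplated <- function(tail_total, chrom, cleavage_pos, strand,
                               genome) {
  cs <- if (is.character(genome)) genome[[chrom]] else
    as.character(genome[[chrom]])
  templated <- .templated_run(cs, cleavage_pos, strand, tail_total)
  max(tail_total - templated, 0L)
}

#' Assign cleavage positions to genes
#'
#' A cleavage position is assigned to the gene whose 3'UTR (CDS end to
#' distal cleavage point) or downstream extension window contains it; ties
#' are broken by the nearest annotated transcript end (distal PAS). Reads
#' matching no gene are returned unassigned (`NA`).
#'
#' @param calls data.frame with `chrom`, `strand`, `cleavage_pos` (0-based).
#' @param genes Gene annotation as in `sim_genome$genes` (columns
#'   `gene_id`, `chrom`, `strand`, `cds_end`, `pas_distal`).
#' @param extension Downstream extension window in nt (default 2000).
#' @return Character vector of gene ids (NA when unassigned).
#' @export
assign_to_gene <- function(calls, genes, extension = 2000L) {
  plus <- genes$strand == "+"
  win_start <- ifelse(plus, genes$cds_end + 1L,
                      genes$pas_distal - extension)
  win_end <- ifelse(plus, genes$pas_distal + extension, genes$cds_end - 1L)
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(win_start, 0L) + 1L, win_end + 1L),
    strand = genes$strand)
  gr_calls <- GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(calls$cleavage_pos + 1L, width = 1L),
    strand = calls$strand)
  hits <- GenomicRanges::findOverlaps(gr_calls, gr_genes)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  out <- rep(NA_character_, nrow(calls))
  if (length(qh)) {
    dist_to_end <- abs(calls$cleavage_pos[qh] - genes$pas_distal[sh])
    ord <- order(qh, dist_to_end)
    first <- !duplicated(qh[ord])
    out[qh[ord][first]] <- genes$gene_id[sh[ord][first]]
  }
  out
}

#' Call per-read poly(A) tails for a set of aligned reads
#'
#' The end-to-end caller: trims adapters, anchors the A-run at the aligned
#' 3' end of each read's templated portion, subtracts templated genomic
#' A's, flags polyadenylated reads (non-templated run >= `min_nontemplated`)
#' and assigns reads to genes.
#'
#' @param reads data.frame with `read_id`, `seq`, `qual` and alignment
#'   columns `chrom`, `strand`, `align_pos` (1-based leftmost), `align_len`
#'   (aligned query length); a `sample_id` column is carried through. The
#'   `reads` element of a [simulate_pat_reads()] result has this shape, and
#'   [read_alignments()] produces it from FASTQ + SAM.
#' @param genome [Biostrings::DNAStringSet] (or named character vector).
#' @param genes Optional gene annotation for [assign_to_gene()].
#' @param params [tail_call_params()].
#' @param extension Gene-assignment extension window (nt).
#' @return data.frame of per-read calls: `read_id`, `sample_id` (if
#'   present), `gene_id`, `chrom`, `strand`, `cleavage_pos`, `tail_total`,
#'   `tail_nontemplated`, `is_polyadenylated`.
#' @export
call_tails <- function(reads, genome, genes = NULL,
                       params = tail_call_params(), extension = 2000L) {
  req <- c("read_id", "seq", "qual", "chrom", "strand", "align_pos",
           "align_len")
  if (!all(req %in% names(reads)))
    .stopf("'reads' must have columns: %s", paste(req, collapse = ", "))
  if (is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }

  trimmed <- trim_adapter(reads$seq, reads$qual, params$adapter)
  n <- nrow(reads)
  tail_total <- integer(n)
  cleavage <- ifelse(reads$strand == "+",
                     reads$align_pos - 1L + reads$align_len - 1L,
                     reads$align_pos - 1L)
  for (i in seq_len(n)) {
    ts <- trimmed$seq[i]; tq <- trimmed$quals[i]
    al <- reads$align_len[i]
    if (nchar(ts) <= al) { tail_total[i] <- 0L; next }
    sv <- strsplit(toupper(ts), "", fixed = TRUE)[[1]]
    qv <- .phred(tq)
    run <- .a_run(sv, qv, (al + 1L):nchar(ts),
                  params$max_error_fraction, params$min_quality)
    tail_total[i] <- length(run)
  }

  nontemp <- integer(n)
  for (chr in unique(reads$chrom)) {
    idx <- which(reads$chrom == chr)
    cs <- genome[[chr]]
    nontemp[idx] <- vapply(idx, function(i) {
      if (tail_total[i] == 0L) return(0L)
      templ <- .templated_run(cs, cleavage[i], reads$strand[i],
                              tail_total[i])
      max(tail_total[i] - templ, 0L)
    }, integer(1))
  }

  out <- data.frame(read_id = reads$read_id, stringsAsFactors = FALSE)
  if ("sample_id" %in% names(reads)) out$sample_id <- reads$sample_id
  out$chrom <- reads$chrom
  out$strand <- reads$strand
  out$cleavage_pos <- cleavage
  out$tail_total <- tail_total
  out$tail_nontemplated <- nontemp
  out$is_polyadenylated <- nontemp >= params$min_nontemplated
  out$gene_id <- if (!is.null(genes))
    assign_to_gene(out, genes, extension) else NA_character_
  out
}
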