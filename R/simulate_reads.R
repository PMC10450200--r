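# Simulate 3'-anchored poly(A)-tail sequencing reads with ground truth.
#
# A read is built as
#   [genomic anchor ending at the trimmed cleavage point]
#   [A-run = templated genomic A's + non-templated tail]
#   [3' adapter][random fill]  -> truncated to read_len
# The "trimmed cleavage point" is the last non-A transcribed base: a real
# pipeline trims the entire terminal A-run before alignment, so truth
# alignments end there and the genomic A-run downstream is what the
# non-templated-A rule must subtract.

.DEFAULT_ADAPTER <- "AGATCGGAAGAGCACACGTCTG"

#' Simulate PAT-Seq reads with truth alignments
#'
#' Draws per-read non-templated tail lengths from a truncated normal
#' (rounded to integers, floored at 0), chooses the distal or proximal
#' cleavage site per `distal_usage`, and assembles reads as a genomic
#' anchor + A-run + adapter. Substitution errors are applied at
#' `error_rate` with the Phred score of erroneous bases dropped to
#' `qual_low` (two-level quality model). Each sample gets its own RNG
#' stream keyed by `(seed, sample_id)`.
#'
#' @param sim A `sim_genome` from [simulate_genome()].
#' @param samples data.frame with one row per sample: `sample_id`,
#'   `condition`, `tail_mean`, `tail_sd`, `distal_usage`, `depth`
#'   (polyadenylated reads per gene; deterministic, not Poisson, so
#'   per-gene totals are exactly reproducible).
#' @param read_len Read length in nt (default 150).
#' @param anchor_len Genomic anchor length in nt (default 50).
#' @param min_anchor Minimum templated anchor; `read_len` below this is an
#'   error (default 20).
#' @param error_rate Per-base substitution probability.
#' @param adapter 3' adapter sequence appended after the tail.
#' @param qual_high,qual_low Phred scores for correct / erroneous bases.
#' @param revcomp_reads If `TRUE`, FASTQ reads are written
#'   reverse-complemented (protocol orientation toggle).
#' @param seed Integer master seed.
#'
#' @return List of class `sim_reads`:
#' \describe{
#'   \item{reads}{data.frame per read: `read_id`, `sample_id`, `gene_id`,
#'     `site`, `true_tail` (non-templated), `templated_run`, `chrom`,
#'     `strand`, `align_pos` (1-based leftmost of the truth alignment),
#'     `align_len`, `cleavage_pos` (0-based genomic coordinate of the
#'     trimmed cleavage point, strand-aware), `seq`, `qual`.}
#'   \item{truth_gene}{per gene x sample: `n_reads`, `n_distal`,
#'     `n_proximal`, `true_mean_tail`, `true_distal_usage`.}
#'   \item{samples}{the input sample sheet.}
#' }
#' @seealso [write_pat_reads()] for FASTQ/SAM export, [call_tails()] for the
#'   calling pipeline.
#' @export
simulate_pat_reads <- function(sim, samples, read_len = 150L,
                               anchor_len = 50L, min_anchor = 20L,
                               error_rate = 0.001,
                               adapter = .DEFAULT_ADAPTER,
                               qual_high = 37L, qual_low = 8L,
                               revcomp_reads = FALSE, seed = 1L) {
  stopifnot(inherits(sim, "sim_genome"))
  req <- c("sample_id", "condition", "tail_mean", "tail_sd",
           "distal_usage", "depth")
  if (!all(req %in% names(samples)))
    .stopf("'samples' must have columns: %s", paste(req, collapse = ", "))
  if (read_len < min_anchor)
    .stopf("read_len (%d) shorter than minimum templated anchor (%d)",
           read_len, min_anchor)
  if (anchor_len < min_anchor || anchor_len >= read_len)
    .stopf("anchor_len must lie in [min_anchor, read_len)")
  .check_prob(error_rate, "error_rate")
  if (any(samples$tail_mean < 0) ||
      any(samples$distal_usage < 0 | samples$distal_usage > 1))
    .stopf("tail_mean must be >= 0 and distal_usage in [0, 1]")

  genes <- sim$genes
  contig_len <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  # transcription-direction contig sequences, precomputed per gene
  tx_seqs <- as.character(sim$genome)
  minus <- genes$strand == "-"
  tx_seqs[minus] <- .revcomp(tx_seqs[minus])
  names(tx_seqs) <- genes$gene_id

  alphabet <- c("A", "C", "G", "T")
  all_reads <- vector("list", nrow(samples))

  for (si in seq_len(nrow(samples))) {
    sm <- samples[si, ]
    set.seed(.derive_seed(seed, sm$sample_id))
    per_gene <- vector("list", nrow(genes))
    for (gi in seq_len(nrow(genes))) {
      g <- genes[gi, ]
      n <- as.integer(sm$depth)
      if (n <= 0L) next
      tails <- .rtail(n, sm$tail_mean, sm$tail_sd)
      is_distal <- runif(n) < sm$distal_usage
      L <- contig_len[[g$chrom]]
      cds_end_t <- .SIM_PAD5 + .SIM_CDS - 1L
      # transcription coords of the annotated cleavage points
      dist_t <- cds_end_t + g$utr_length
      prox_t <- dist_t - abs(g$pas_distal - g$pas_proximal)
      site_t <- ifelse(is_distal, dist_t, prox_t)
      r <- g$templated_a_run
      # The annotated cleavage base is forced non-A; the genomic A-run of
      # length r sits immediately downstream and is transcribed, so the
      # trimmed anchor ends exactly at the annotated cleavage point.
      trim_t <- site_t
      tx <- tx_seqs[[g$gene_id]]

      anchor <- substring(tx, trim_t - anchor_len + 2L, trim_t + 1L)
      a_run <- strrep("A", r + tails)
      # Read = anchor + A-run + adapter, truncated to read_len. Reads come
      # out length-variable, as after upstream quality/length trimming; an
      # adapter remnant shorter than the minimum match overlap (5 nt)
      # could never be trimmed, so it is dropped from the read instead.
      raw <- substr(paste0(anchor, a_run, adapter), 1L, read_len)
      body_len <- anchor_len + r + tails
      remnant <- pmax(nchar(raw) - body_len, 0L)
      drop <- remnant > 0L & remnant < 5L
      raw[drop] <- substr(raw[drop], 1L, body_len[drop])
      seqs <- raw

      quals <- strrep(rawToChar(as.raw(qual_high + 33L)), nchar(seqs))
      if (error_rate > 0) {
        len_i <- nchar(seqs)
        n_err <- rbinom(n, len_i, error_rate)
        for (ri in which(n_err > 0L)) {
          pos <- sample.int(len_i[ri], n_err[ri])
          s <- strsplit(seqs[ri], "", fixed = TRUE)[[1]]
          q <- strsplit(quals[ri], "", fixed = TRUE)[[1]]
          for (p in pos) {
            s[p] <- sample(setdiff(alphabet, s[p]), 1L)
            q[p] <- rawToChar(as.raw(qual_low + 33L))
          }
          seqs[ri] <- paste(s, collapse = "")
          quals[ri] <- paste(q, collapse = "")
        }
      }

      g2 <- function(t) .t2g(t, g$strand, L)
      cleav_g <- g2(trim_t)
      align_pos <- if (g$strand == "+") trim_t - anchor_len + 2L else
        g2(trim_t) + 1L
      per_gene[[gi]] <- data.frame(
        read_id = sprintf("%s:%s:%06d", sm$sample_id, g$gene_id, seq_len(n)),
        sample_id = sm$sample_id, gene_id = g$gene_id,
        site = ifelse(is_distal, "distal", "proximal"),
        true_tail = tails, templated_run = r,
        chrom = g$chrom, strand = g$strand,
        align_pos = align_pos, align_len = anchor_len,
        cleavage_pos = cleav_g, seq = seqs, qual = quals,
        stringsAsFactors = FALSE)
    }
    all_reads[[si]] <- do.call(rbind, per_gene)
  }
  reads <- do.call(rbind, all_reads)
  rownames(reads) <- NULL
  if (revcomp_reads) {
    reads$seq <- .revcomp(reads$seq)
    reads$qual <- vapply(strsplit(reads$qual, "", fixed = TRUE),
                         function(q) paste(rev(q), collapse = ""),
                         character(1))
  }

  tg <- do.call(rbind, lapply(split(reads, list(reads$gene_id,
                                                reads$sample_id),
                                    drop = TRUE), function(d) {
    data.frame(gene_id = d$gene_id[1], sample_id = d$sample_id[1],
               n_reads = nrow(d), n_distal = sum(d$site == "distal"),
               n_proximal = sum(d$site == "proximal"),
               true_mean_tail = mean(d$true_tail),
               true_distal_usage = mean(d$site == "distal"),
               stringsAsFactors = FALSE)
  }))
  rownames(tg) <- NULL

  out <- list(reads = reads, truth_gene = tg, samples = samples,
              params = list(read_len = read_len, anchor_len = anchor_len,
                            error_rate = error_rate, adapter = adapter,
                            revcomp_reads = revcomp_reads, seed = seed))
  class(out) <- c("sim_reads", "list")
  out
}

#' Export simulated reads as FASTQ (Phred+33) and truth SAM
#'
#' Writes `<sample>.fastq` and `<sample>.truth.sam` per sample. The SAM
#' records the error-free alignment of the templated anchor (flag 16 for
#' minus-strand genes; SEQ is reference-strand oriented).
#'
#' @param simreads A `sim_reads` object.
#' @param sim The `sim_genome` the reads were simulated from (for \code{@SQ}
#'   headers).
#' @param outdir Output directory.
#' @return Invisibly, a named list of written paths per sample.
#' @export
write_pat_reads <- function(simreads, sim, outdir) {
  stopifnot(inherits(simreads, "sim_reads"), inherits(sim, "sim_genome"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sim$genome),
                   Biostrings::width(sim$genome)))
  paths <- list()
  for (sm in unique(simreads$reads$sample_id)) {
    d <- simreads$reads[simreads$reads$sample_id == sm, ]
    fq <- file.path(outdir, paste0(sm, ".fastq"))
    writeLines(as.vector(rbind(paste0("@", d$read_id), d$seq, "+", d$qual)),
               fq)
    anchor <- substr(d$seq, 1L, d$align_len)
    flag <- ifelse(d$strand == "+", 0L, 16L)
    sam_seq <- ifelse(d$strand == "+", anchor, .revcomp(anchor))
    sam_q <- substr(d$qual, 1L, d$align_len)
    sam_q <- ifelse(d$strand == "+", sam_q,
                    vapply(strsplit(sam_q, "", fixed = TRUE),
                           function(q) paste(rev(q), collapse = ""),
                           character(1)))
    sam <- file.path(outdir, paste0(sm, ".truth.sam"))
    writeLines(c(hdr, sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                              d$read_id, flag, d$chrom, d$align_pos,
                              d$align_len, sam_seq, sam_q)), sam)
    paths[[sm]] <- c(fastq = fq, sam = sam)
  }
  invisible(paths)
}
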