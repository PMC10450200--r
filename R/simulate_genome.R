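# Synthetic genome / gene-model / PAS generator.
#
# Geometry per gene (transcription direction, 0-based):
#   [upstream pad][CDS][3'UTR ... proximal PAS ... distal PAS][downstream pad]
# Each gene lives on its own contig. A configurable fraction of genes carry
# a genomic A-run of length 4-12 immediately downstream of the cleavage
# point of BOTH PASs, to exercise the non-templated-A rule. The base at the
# cleavage point itself and the base just past the A-run are forced non-A so
# that templated-run lengths are exact by construction.

.SIM_PAD5 <- 100L   # upstream pad
.SIM_CDS  <- 300L   # nominal CDS length (only cds_end matters downstream)
.SIM_PAD3 <- 200L   # pad past the distal cleavage point
.SIM_PAS_WIDTH <- 5L  # width of emitted PAS annotation intervals

# transcription coordinate -> genomic 0-based coordinate
#' @noRd
.t2g <- function(t, strand, contig_len) {
  ifelse(strand == "+", t, contig_len - 1L - t)
}

#' Simulate a genome with two-PAS gene models
#'
#' Generates `n_genes` single-gene contigs, each with a CDS end, a proximal
#' and a distal polyadenylation site (PAS) in the 3'UTR, and (for a random
#' subset of genes) a templated genomic A-run of length 4-12 immediately
#' downstream of each cleavage point. Strands alternate between `+` and `-`.
#'
#' @param n_genes Number of genes (one per contig).
#' @param utr_len_range Length-2 integer vector; 3'UTR length (CDS end to
#'   distal cleavage point) is drawn uniformly from this range.
#' @param templated_a_prob Probability that a gene carries a templated A-run
#'   at its cleavage points.
#' @param seed Integer seed; output is deterministic given the seed.
#'
#' @return A list of class `sim_genome` with elements:
#' \describe{
#'   \item{genome}{Named [Biostrings::DNAStringSet] of contigs.}
#'   \item{genes}{data.frame: `gene_id`, `chrom`, `strand`, `cds_end`,
#'     `pas_proximal`, `pas_distal` (0-based genomic coordinates of the last
#'     transcribed base at each cleavage point), `templated_a_run`,
#'     `utr_length`, `utr_seq` (transcription-direction sequence from the
#'     base after `cds_end` to the distal cleavage point).}
#'   \item{pas}{BED-like data.frame of PAS intervals (0-based half-open):
#'     `chrom`, `start`, `end`, `name` (`gene:proximal` / `gene:distal`),
#'     `score`, `strand`, plus `gene_id`, `site_id`, `region`.}
#' }
#' @seealso [write_sim_genome()] to export FASTA/GFF3/BED.
#' @examples
#' sim <- simulate_genome(3, seed = 1)
#' sim$genes[, c("gene_id", "strand", "cds_end", "pas_proximal", "pas_distal")]
#' @export
simulate_genome <- function(n_genes, utr_len_range = c(300L, 1500L),
                            templated_a_prob = 0.3, seed = 1L) {
  n_genes <- .check_count(n_genes, "n_genes")
  .check_prob(templated_a_prob, "templated_a_prob")
  if (length(utr_len_range) != 2L || any(utr_len_range < 100) ||
      utr_len_range[1] > utr_len_range[2])
    .stopf("'utr_len_range' must be an increasing pair of lengths >= 100")
  seed <- .check_count(seed, "seed", min = 0L)
  set.seed(seed)

  ids <- sprintf("g%04d", seq_len(n_genes))
  strands <- rep(c("+", "-"), length.out = n_genes)
  utr_len <- as.integer(round(runif(n_genes, utr_len_range[1],
                                    utr_len_range[2])))
  # proximal cleavage 25-60% of the way through the UTR, clear of the distal
  prox_off <- pmin(pmax(as.integer(round(utr_len * runif(n_genes, .25, .6))),
                        30L), utr_len - 50L)
  has_run <- runif(n_genes) < templated_a_prob
  run_len <- ifelse(has_run, sample(4:12, n_genes, replace = TRUE), 0L)

  contig_len <- .SIM_PAD5 + .SIM_CDS + utr_len + .SIM_PAD3
  seqs <- character(n_genes)
  genes <- vector("list", n_genes)
  pas <- vector("list", n_genes)

  for (i in seq_len(n_genes)) {
    L <- contig_len[i]
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    cds_end_t <- .SIM_PAD5 + .SIM_CDS - 1L          # transcription coords
    prox_t <- cds_end_t + prox_off[i]
    dist_t <- cds_end_t + utr_len[i]
    r <- run_len[i]
    for (c_t in c(prox_t, dist_t)) {
      s[c_t + 1L] <- "C"                            # cleavage base non-A
      if (r > 0L) s[(c_t + 2L):(c_t + 1L + r)] <- "A"
      s[c_t + 2L + r] <- "G"                        # terminate templated run
    }
    tx_seq <- s
    if (strands[i] == "-") {
      # genomic sequence is the reverse complement of the transcript layout
      s <- rev(chartr("ACGT", "TGCA", s))
    }
    seqs[i] <- paste(s, collapse = "")

    g2 <- function(t) .t2g(t, strands[i], L)
    genes[[i]] <- data.frame(
      gene_id = ids[i], chrom = ids[i], strand = strands[i],
      cds_end = g2(cds_end_t),
      pas_proximal = g2(prox_t), pas_distal = g2(dist_t),
      templated_a_run = r, utr_length = utr_len[i],
      utr_seq = paste(tx_seq[(cds_end_t + 2L):(dist_t + 1L)], collapse = ""),
      stringsAsFactors = FALSE)

    # PAS interval [c-2, c+2] in transcription coords, half-open genomic
    mk_iv <- function(c_t, site) {
      lo_t <- c_t - 2L; hi_t <- c_t + 2L
      gs <- sort(c(g2(lo_t), g2(hi_t)))
      data.frame(chrom = ids[i], start = gs[1], end = gs[2] + 1L,
                 name = paste0(ids[i], ":", site), score = 0L,
                 strand = strands[i], gene_id = ids[i], site_id = site,
                 region = "3UTR", stringsAsFactors = FALSE)
    }
    pas[[i]] <- rbind(mk_iv(prox_t, "proximal"), mk_iv(dist_t, "distal"))
  }

  genome <- Biostrings::DNAStringSet(setNames(seqs, ids))
  out <- list(genome = genome,
              genes = do.call(rbind, genes),
              pas = do.call(rbind, pas),
              params = list(n_genes = n_genes, utr_len_range = utr_len_range,
                            templated_a_prob = templated_a_prob, seed = seed))
  class(out) <- c("sim_genome", "list")
  out
}

#' Export a simulated genome as FASTA + GFF3 + BED6
#'
#' Writes `genome.fa`, `genes.gff3` (1-based closed coordinates) and
#' `pas.bed` (0-based half-open) under `outdir`.
#'
#' @param sim A `sim_genome` from [simulate_genome()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim_genome <- function(sim, outdir) {
  stopifnot(inherits(sim, "sim_genome"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(outdir, "genome.fa")
  gff <- file.path(outdir, "genes.gff3")
  bed <- file.path(outdir, "pas.bed")
  Biostrings::writeXStringSet(sim$genome, fa)

  g <- sim$genes
  # gene span: upstream pad start through distal cleavage (+ run allowance)
  lo <- pmin(g$cds_end, g$pas_distal)
  hi <- pmax(g$cds_end, g$pas_distal)
  gff_lines <- c("##gff-version 3",
    sprintf("%s\tpatseq_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;cds_end=%d",
            g$chrom, lo + 1L, hi + 1L, g$strand, g$gene_id, g$cds_end))
  writeLines(gff_lines, gff)

  p <- sim$pas
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", p$chrom, p$start, p$end,
                     p$name, p$score, p$strand), bed)
  invisible(c(fasta = fa, gff = gff, bed = bed))
}
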