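# Alternative-polyadenylation analysis: PAS read counting, per-site usage
# testing (NB LRT with gene-total offsets), the RED statistic, event
# classification and 3'UTR length-change quantification.

#' Count polyadenylated reads at annotated PAS intervals
#'
#' A read is assigned to a site when its cleavage position falls within the
#' site interval extended by `flank` nt on the matching strand; a read
#' overlapping several sites goes to the site with the nearest midpoint.
#'
#' @param calls Per-read calls (polyadenylated reads are used): `chrom`,
#'   `strand`, `cleavage_pos`, `sample_id`, `is_polyadenylated`.
#' @param pas PAS table: `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `gene_id`, `site_id`.
#' @param flank Interval extension in nt (default 10).
#' @return The `pas` table with one count column per sample appended.
#' @export
count_pas_reads <- function(calls, pas, flank = 10L) {
  d <- calls[calls$is_polyadenylated, ]
  samples <- unique(calls$sample_id)
  gr_pas <- GenomicRanges::GRanges(
    pas$chrom,
    IRanges::IRanges(pmax(pas$start - flank, 0L) + 1L, pas$end + flank),
    strand = pas$strand)
  gr_reads <- GenomicRanges::GRanges(
    d$chrom, IRanges::IRanges(d$cleavage_pos + 1L, width = 1L),
    strand = d$strand)
  hits <- GenomicRanges::findOverlaps(gr_reads, gr_pas)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  mid <- (pas$start + pas$end) / 2
  dist_mid <- abs(d$cleavage_pos[qh] - mid[sh])
  ord <- order(qh, dist_mid)
  first <- !duplicated(qh[ord])
  ri <- qh[ord][first]; si <- sh[ord][first]

  counts <- matrix(0L, nrow(pas), length(samples),
                   dimnames = list(NULL, samples))
  smp <- match(d$sample_id[ri], samples)
  tab <- table(factor(si, levels = seq_len(nrow(pas))),
               factor(smp, levels = seq_along(samples)))
  counts[] <- as.integer(tab)
  cbind(pas, as.data.frame(counts, check.names = FALSE))
}

# Normalised counts: raw counts scaled so every sample has the mean
# effective library size.
#' @noRd
.normalized_counts <- function(counts, eff_lib) {
  t(t(counts) / eff_lib) * mean(eff_lib)
}

#' Filter PAS by normalised-count support
#'
#' Retains sites whose normalised count reaches `min_norm` in every sample
#' (`mode = "all"`, the strict reading) or on average (`mode = "mean"`).
#'
#' @param pas_counts PAS table with sample count columns (from
#'   [count_pas_reads()] or the `counts` element of
#'   [simulate_pas_usage_counts()]).
#' @param sample_ids Names of the count columns.
#' @param eff_lib Effective library sizes (defaults to the column sums of
#'   the site counts).
#' @param min_norm Normalised-count threshold (default 2).
#' @param mode `"all"` or `"mean"`.
#' @return Filtered PAS table.
#' @export
filter_sites <- function(pas_counts, sample_ids,
                         eff_lib = NULL, min_norm = 2,
                         mode = c("all", "mean")) {
  mode <- match.arg(mode)
  m <- as.matrix(pas_counts[, sample_ids, drop = FALSE])
  if (is.null(eff_lib)) eff_lib <- colSums(m)
  norm <- .normalized_counts(m, eff_lib)
  keep <- if (mode == "all") rowSums(norm >= min_norm) == ncol(norm)
          else rowMeans(norm) >= min_norm
  pas_counts[keep, , drop = FALSE]
}

#' Differential PAS usage (NB LRT with gene-total offsets)
#'
#' Per site, fits a fixed-dispersion NB model of the site count with offset
#' `log(gene total per sample)` and a condition term, and tests the
#' condition term by likelihood ratio. The log2FC is therefore a change in
#' within-gene usage, not in absolute expression. Samples where the gene
#' total is zero are dropped for that gene.
#'
#' @param pas_counts PAS table with count columns; needs `gene_id`,
#'   `site_id`.
#' @param design data.frame `sample_id`, `condition` (first level =
#'   reference).
#' @param dispersion Optional fixed NB dispersion; estimated by moments
#'   from the usage residuals when `NULL`.
#' @return The PAS table with `usage_lfc`, `p_value`, `fdr` appended
#'   (sites in genes with a single retained site get `NA`).
#' @export
diff_site_usage <- function(pas_counts, design, dispersion = NULL) {
  sample_ids <- design$sample_id
  lv <- unique(design$condition)
  if (length(lv) != 2L) .stopf("design must have exactly 2 conditions")
  cond <- factor(design$condition, levels = lv)
  m <- as.matrix(pas_counts[, sample_ids, drop = FALSE])
  gene <- pas_counts$gene_id
  gene_tot <- rowsum(m, gene)[gene, , drop = FALSE]

  multi <- gene %in% names(which(table(gene) >= 2L))
  if (is.null(dispersion)) {
    # moments on usage-scaled counts within condition, pooled across sites
    usage_resid <- c()
    for (cl in lv) {
      sel <- cond == cl
      u <- m[multi, sel, drop = FALSE] /
        pmax(gene_tot[multi, sel, drop = FALSE], 1)
      mu <- rowMeans(m[multi, sel, drop = FALSE])
      v <- apply(m[multi, sel, drop = FALSE], 1, var)
      ph <- (v - mu) / mu^2
      usage_resid <- c(usage_resid, ph[is.finite(ph)])
    }
    dispersion <- max(mean(usage_resid, na.rm = TRUE), 1e-6)
    if (!is.finite(dispersion)) dispersion <- 1e-6
  }

  lfc <- p <- rep(NA_real_, nrow(pas_counts))
  fam <- MASS::negative.binomial(theta = 1 / dispersion)
  for (i in which(multi)) {
    tot <- gene_tot[i, ]
    ok <- tot > 0
    if (sum(ok) < 4L || length(unique(cond[ok])) < 2L) next
    y <- m[i, ok]; offs <- log(tot[ok]); cc <- cond[ok]
    full <- try(glm(y ~ cc + offset(offs), family = fam,
                    control = glm.control(maxit = 50)), silent = TRUE)
    red <- try(glm(y ~ 1 + offset(offs), family = fam,
                   control = glm.control(maxit = 50)), silent = TRUE)
    if (inherits(full, "try-error") || inherits(red, "try-error")) next
    lfc[i] <- coef(full)[[2]] / log(2)
    p[i] <- pchisq(max(red$deviance - full$deviance, 0), df = 1,
                   lower.tail = FALSE)
  }
  pas_counts$usage_lfc <- lfc
  pas_counts$p_value <- p
  pas_counts$fdr <- NA_real_
  tested <- !is.na(p)
  pas_counts$fdr[tested] <- .bh(p[tested])
  pas_counts
}

#' Relative expression difference (RED)
#'
#' `RED = log2(dif_dist / ctrl_dist) - log2(dif_prox / ctrl_prox)` on
#' positive normalised means. RED > 1 flags 3'UTR-lengthening candidates,
#' RED < -1 shortening candidates.
#'
#' @param dif_dist,ctrl_dist,dif_prox,ctrl_prox Positive normalised mean
#'   counts of the distal and proximal isoforms in the two conditions
#'   (pseudocounts should already be applied; see [apa_event_analysis()]).
#' @return Numeric RED value(s).
#' @examples
#' red(8, 2, 2, 8)   # log2(4) - log2(1/4) = 4
#' @export
red <- function(dif_dist, ctrl_dist, dif_prox, ctrl_prox) {
  if (any(c(dif_dist, ctrl_dist, dif_prox, ctrl_prox) <= 0))
    .stopf("all four normalised means must be positive")
  log2(dif_dist / ctrl_dist) - log2(dif_prox / ctrl_prox)
}

#' Classify an APA event from RED and per-site tests
#'
#' Lengthening requires `RED > red_cut` coupled with a significant
#' (FDR < `fdr_cut`) increase of the distal isoform and/or decrease of the
#' proximal isoform; shortening mirrors this with `RED < -red_cut`.
#'
#' @param red_value RED statistic for the gene.
#' @param distal_lfc,distal_fdr,proximal_lfc,proximal_fdr Per-site usage
#'   test results.
#' @param fdr_cut,red_cut Cutoffs (defaults 0.1 and 1).
#' @return `"lengthening"`, `"shortening"` or `"none"`.
#' @export
classify_event <- function(red_value, distal_lfc, distal_fdr,
                           proximal_lfc, proximal_fdr,
                           fdr_cut = 0.1, red_cut = 1) {
  sig_up <- function(fdr, lfc) !is.na(fdr) && fdr < fdr_cut &&
    !is.na(lfc) && lfc > 0
  sig_dn <- function(fdr, lfc) !is.na(fdr) && fdr < fdr_cut &&
    !is.na(lfc) && lfc < 0
  if (!is.na(red_value) && red_value > red_cut &&
      (sig_up(distal_fdr, distal_lfc) || sig_dn(proximal_fdr, proximal_lfc)))
    return("lengthening")
  if (!is.na(red_value) && red_value < -red_cut &&
      (sig_dn(distal_fdr, distal_lfc) || sig_up(proximal_fdr, proximal_lfc)))
    return("shortening")
  "none"
}

#' Usage-weighted 3'UTR length change
#'
#' Per condition, the usage-weighted mean 3'UTR length over the top-2 sites
#' (length = transcription-direction distance from the CDS end to the site
#' midpoint); the change is treated minus reference.
#'
#' @param prox_len,dist_len 3'UTR lengths (nt) at the proximal and distal
#'   sites.
#' @param usage_ref,usage_trt Distal-usage fractions in the reference and
#'   treated conditions.
#' @return Signed length change in nt.
#' @examples
#' delta_utr_length(200, 1800, 0.1, 0.9)  # (0.9 - 0.1) * 1600 = 1280
#' @export
delta_utr_length <- function(prox_len, dist_len, usage_ref, usage_trt) {
  len <- function(u) (1 - u) * prox_len + u * dist_len
  len(usage_trt) - len(usage_ref)
}

#' Chi-squared test of PAS genomic-region composition between conditions
#'
#' @param region_table A region x condition contingency matrix of expressed
#'   PAS counts.
#' @param correct Continuity correction (default FALSE).
#' @return list with `chi2`, `df`, `p_value`.
#' @export
pas_region_chisq <- function(region_table, correct = FALSE) {
  region_table <- as.matrix(region_table)
  if (any(colSums(region_table) == 0) || any(rowSums(region_table) == 0))
    .stopf("degenerate contingency table (zero margin)")
  ct <- suppressWarnings(chisq.test(region_table, correct = correct))
  if (any(ct$expected < 1)) .warnf("expected cell count below 1")
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Full APA event analysis for two conditions
#'
#' Selects each gene's top two expressed PAS (by summed normalised counts;
#' ties broken in favour of the more distal site), ranks them
#' proximal/distal by transcription-direction order, runs the per-site
#' usage LRT, computes RED on pseudocounted normalised means, classifies
#' lengthening/shortening, and (when site coordinates and CDS ends are
#' available) quantifies the usage-weighted 3'UTR length change.
#'
#' @param pas_counts PAS table with sample count columns; needs `gene_id`,
#'   `site_id`, and (for length changes) `chrom`, `start`, `end`, `strand`
#'   plus `genes` with `cds_end`.
#' @param design data.frame `sample_id`, `condition` (first level =
#'   reference).
#' @param genes Optional gene annotation with `gene_id`, `cds_end`,
#'   `strand` for 3'UTR length change.
#' @param eff_lib Effective library sizes (default: column sums of the
#'   site counts).
#' @param min_norm Site-support filter threshold ([filter_sites()]).
#' @param filter_mode `"all"` or `"mean"` for the support filter.
#' @param pseudocount Added to raw condition means before RED (default 0.5).
#' @param fdr_cut,red_cut Classification cutoffs (defaults 0.1 and 1).
#' @return data.frame of class `apa_events`: one row per analysable gene
#'   with `red`, per-site lfc/fdr, `classification` and `delta_utr_len`.
#' @export
apa_event_analysis <- function(pas_counts, design, genes = NULL,
                               eff_lib = NULL, min_norm = 2,
                               filter_mode = "all", pseudocount = 0.5,
                               fdr_cut = 0.1, red_cut = 1) {
  sample_ids <- design$sample_id
  lv <- unique(design$condition)
  if (length(lv) != 2L) .stopf("design must have exactly 2 conditions")
  m_all <- as.matrix(pas_counts[, sample_ids, drop = FALSE])
  if (is.null(eff_lib)) eff_lib <- pmax(colSums(m_all), 1)

  kept <- filter_sites(pas_counts, sample_ids, eff_lib, min_norm,
                       filter_mode)
  if (!nrow(kept)) return(.empty_apa())

  # top-2 sites per gene by summed normalised counts; tie -> distal
  norm <- .normalized_counts(as.matrix(kept[, sample_ids, drop = FALSE]),
                             eff_lib)
  kept$.total <- rowSums(norm)
  kept$.order <- seq_len(nrow(kept))
  has_coords <- all(c("chrom", "start", "end", "strand") %in% names(kept))
  top2 <- do.call(rbind, lapply(split(kept, kept$gene_id), function(d) {
    if (nrow(d) < 2L) return(NULL)
    # transcription-direction position for distal preference on ties
    tx_pos <- if (has_coords) {
      ifelse(d$strand == "+", (d$start + d$end) / 2, -(d$start + d$end) / 2)
    } else seq_len(nrow(d))
    d[order(-d$.total, -tx_pos)[1:2], ]
  }))
  if (is.null(top2)) return(.empty_apa())

  tested <- diff_site_usage(top2, design)

  res <- lapply(split(tested, tested$gene_id), function(d) {
    tx_pos <- if (has_coords) {
      ifelse(d$strand == "+", (d$start + d$end) / 2, -(d$start + d$end) / 2)
    } else match(d$site_id, c("proximal", "distal"))
    d <- d[order(tx_pos), ]           # row 1 proximal, row 2 distal
    mm <- .normalized_counts(as.matrix(d[, sample_ids, drop = FALSE]),
                             eff_lib)
    cond <- design$condition
    means <- sapply(lv, function(cl)
      rowMeans(mm[, cond == cl, drop = FALSE])) + pseudocount
    rv <- red(means[2, 2], means[2, 1], means[1, 2], means[1, 1])
    cls <- classify_event(rv, d$usage_lfc[2], d$fdr[2],
                          d$usage_lfc[1], d$fdr[1], fdr_cut, red_cut)
    delta <- NA_real_
    prox_len <- dist_len <- NA_real_
    if (has_coords && !is.null(genes)) {
      g <- genes[genes$gene_id == d$gene_id[1], ]
      if (nrow(g) == 1L) {
        mid <- (d$start + d$end) / 2
        site_len <- abs(mid - g$cds_end)
        prox_len <- site_len[1]; dist_len <- site_len[2]
        usage <- mm[2, ] / pmax(colSums(mm), 1e-9)
        u_ref <- mean(usage[cond == lv[1]])
        u_trt <- mean(usage[cond == lv[2]])
        delta <- delta_utr_length(prox_len, dist_len, u_ref, u_trt)
      }
    }
    data.frame(gene_id = d$gene_id[1],
               proximal_site = d$site_id[1], distal_site = d$site_id[2],
               red = rv,
               proximal_lfc = d$usage_lfc[1], proximal_fdr = d$fdr[1],
               distal_lfc = d$usage_lfc[2], distal_fdr = d$fdr[2],
               classification = cls,
               prox_len = prox_len, dist_len = dist_len,
               delta_utr_len = delta,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("apa_events", "data.frame")
  out
}

#' @noRd
.empty_apa <- function() {
  out <- data.frame(gene_id = character(), proximal_site = character(),
                    distal_site = character(), red = numeric(),
                    proximal_lfc = numeric(), proximal_fdr = numeric(),
                    distal_lfc = numeric(), distal_fdr = numeric(),
                    classification = character(), prox_len = numeric(),
                    dist_len = numeric(), delta_utr_len = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("apa_events", "data.frame")
  out
}
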