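# Per-gene tail summaries and differential tail-length testing.
#
# The differential test is a depth-weighted moderated t: per gene, a
# weighted linear model of per-sample mean tail on condition with weights
# proportional to the number of poly(A) reads (the variance of a mean is
# inversely proportional to n), residual variances shrunk toward a common
# across-gene value with a fixed prior df. This mirrors the depth-aware
# voom-style analysis used for tail data without chasing numeric parity
# with limma; parity is asserted on simulated-data recovery instead.

#' Summarise poly(A) tails per gene and sample
#'
#' Arithmetic mean of per-read non-templated tail lengths among
#' polyadenylated reads. Genes with fewer than `min_reads` poly(A) reads in
#' a sample get `NA` for that sample's mean (the tail is not considered
#' quantifiable there).
#'
#' @param calls Per-read calls (from [call_tails()] or
#'   [simulate_gene_tails()]): needs `gene_id`, `sample_id`,
#'   `tail_nontemplated`, `is_polyadenylated`.
#' @param min_reads Minimum poly(A) reads per gene and sample (default 10).
#' @return list with matrices `mean_tail` and `n_reads`
#'   (genes x samples); class `gene_tail_summary`.
#' @export
summarize_gene_tails <- function(calls, min_reads = 10L) {
  d <- calls[calls$is_polyadenylated & !is.na(calls$gene_id), ]
  if (!nrow(d)) .stopf("no polyadenylated, gene-assigned reads")
  genes <- sort(unique(d$gene_id))
  samples <- unique(calls$sample_id)
  gi <- match(d$gene_id, genes)
  si <- match(d$sample_id, samples)
  idx <- (si - 1L) * length(genes) + gi
  n <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  tot <- matrix(0, length(genes), length(samples),
                dimnames = list(genes, samples))
  tabn <- tapply(rep(1L, nrow(d)), idx, sum)
  tabs <- tapply(d$tail_nontemplated, idx, sum)
  n[as.integer(names(tabn))] <- tabn
  tot[as.integer(names(tabs))] <- tabs
  mean_tail <- ifelse(n >= min_reads, tot / pmax(n, 1L), NA_real_)
  structure(list(mean_tail = mean_tail, n_reads = n,
                 min_reads = min_reads),
            class = c("gene_tail_summary", "list"))
}

# Moderated variance shrinkage: squeeze per-gene residual variances toward
# the across-gene mean with prior df d0.
#' @noRd
.squeeze_var <- function(s2, df, d0) {
  ok <- df > 0 & is.finite(s2)
  s0 <- if (any(ok)) mean(s2[ok]) else 1
  list(s2_post = (d0 * s0 + ifelse(ok, df, 0) * ifelse(ok, s2, 0)) /
         (d0 + ifelse(ok, df, 0)),
       s0 = s0)
}

#' Differential poly(A) tail length between two conditions
#'
#' Per gene, fits a weighted least-squares model of per-sample mean tail on
#' condition (weights = number of poly(A) reads), moderates the residual
#' variance with a fixed prior df, and reports a moderated-t p-value,
#' Benjamini-Hochberg FDR and the fitted tail-length difference. A gene
#' must have defined means in at least `min_samples` samples per group to
#' be tested.
#'
#' @param summaries A `gene_tail_summary` from [summarize_gene_tails()].
#' @param design data.frame `sample_id`, `condition` (2 levels; the first
#'   level in order of appearance is the reference/control).
#' @param prior_df Prior degrees of freedom for variance moderation
#'   (default 4).
#' @param fdr_cut,min_delta Significance gates: FDR < `fdr_cut` and
#'   |delta| > `min_delta` (defaults 0.1 and 10 A residues).
#' @param min_samples Minimum samples with defined means per group.
#' @return data.frame: `gene_id`, `delta_tail` (treated - reference),
#'   `p_value`, `fdr`, `significant`, `n_used`.
#' @export
diff_tail_length <- function(summaries, design, prior_df = 4,
                             fdr_cut = 0.1, min_delta = 10,
                             min_samples = 2L) {
  stopifnot(inherits(summaries, "gene_tail_summary"))
  mt <- summaries$mean_tail
  nr <- summaries$n_reads
  sidx <- match(colnames(mt), design$sample_id)
  if (anyNA(sidx)) .stopf("design is missing samples present in summaries")
  cond <- design$condition[sidx]
  lv <- unique(design$condition)
  if (length(lv) != 2L) .stopf("design must have exactly 2 conditions")
  x <- as.numeric(cond == lv[2])        # treated indicator

  ng <- nrow(mt)
  beta <- se2 <- s2 <- rep(NA_real_, ng)
  df <- rep(0, ng)
  testable <- logical(ng)
  for (g in seq_len(ng)) {
    ok <- !is.na(mt[g, ])
    if (sum(ok & x == 0) < min_samples || sum(ok & x == 1) < min_samples)
      next
    testable[g] <- TRUE
    w <- nr[g, ok]; y <- mt[g, ok]; xg <- x[ok]
    m0 <- weighted.mean(y[xg == 0], w[xg == 0])
    m1 <- weighted.mean(y[xg == 1], w[xg == 1])
    beta[g] <- m1 - m0
    fit <- ifelse(xg == 1, m1, m0)
    rdf <- sum(ok) - 2L
    # weighted residual variance (unit: per-read variance scale)
    s2[g] <- sum(w * (y - fit)^2) / rdf
    se2[g] <- 1 / sum(w[xg == 0]) + 1 / sum(w[xg == 1])
    df[g] <- rdf
  }

  idx <- which(testable)
  sq <- .squeeze_var(s2[idx], df[idx], prior_df)
  tstat <- beta[idx] / sqrt(sq$s2_post * se2[idx])
  tstat[!is.finite(tstat) & beta[idx] == 0] <- 0   # 0/0: no signal
  p <- 2 * pt(-abs(tstat), df = df[idx] + prior_df)
  fdr <- .bh(p)
  res <- data.frame(gene_id = rownames(mt)[idx],
                    delta_tail = beta[idx],
                    p_value = p, fdr = fdr,
                    significant = fdr < fdr_cut & abs(beta[idx]) > min_delta,
                    n_used = df[idx] + 2L,
                    stringsAsFactors = FALSE)
  skipped <- sum(!testable)
  if (skipped) attr(res, "n_excluded") <- skipped
  rownames(res) <- NULL
  res
}

#' Global tail-length comparison between conditions
#'
#' Two-sample Kolmogorov-Smirnov test on the distributions of per-gene mean
#' tail lengths, plus each group's grand mean (unweighted average of
#' per-gene means).
#'
#' @param summaries A `gene_tail_summary`.
#' @param design data.frame `sample_id`, `condition`.
#' @return list: `D`, `p_value`, `grand_mean` (named by condition),
#'   `n_genes` (named by condition).
#' @export
global_tail_ks <- function(summaries, design) {
  stopifnot(inherits(summaries, "gene_tail_summary"))
  mt <- summaries$mean_tail
  cond <- design$condition[match(colnames(mt), design$sample_id)]
  lv <- unique(design$condition)
  if (length(lv) != 2L) .stopf("design must have exactly 2 conditions")
  per_gene <- sapply(lv, function(cl)
    rowMeans(mt[, cond == cl, drop = FALSE], na.rm = TRUE))
  a <- per_gene[, 1][is.finite(per_gene[, 1])]
  b <- per_gene[, 2][is.finite(per_gene[, 2])]
  if (length(a) < 2L || length(b) < 2L)
    .stopf("need at least 2 genes with defined means per condition")
  kt <- suppressWarnings(ks.test(a, b))
  list(D = unname(kt$statistic), p_value = kt$p.value,
       grand_mean = setNames(c(mean(a), mean(b)), lv),
       n_genes = setNames(c(length(a), length(b)), lv))
}
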