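# miRNA-centred integrative analyses: target filtering, cumulative-shift
# (Kolmogorov-Smirnov) tests of target sets against background, count-
# stratified shift tests, negative-correlation screening of miRNA-mRNA
# pairs, and the nested linear-model ANOVA used to ask whether tail length
# adds explanatory power over mRNA change.

#' Filter predicted miRNA-target pairs
#'
#' Drops low-confidence pairs (cumulative weighted context++ score above
#' `threshold`; more negative = stronger predicted repression) and all
#' pairs of excluded miRNAs.
#'
#' @param pairs data.frame with `mirna_id`, `gene_id`, `context_score`.
#' @param threshold Score cutoff (default -0.2; pairs with score >
#'   threshold are removed).
#' @param exclude Character vector of miRNA ids to drop entirely.
#' @return Filtered pairs.
#' @export
filter_target_pairs <- function(pairs, threshold = -0.2,
                                exclude = character()) {
  pairs[pairs$context_score <= threshold &
          !(pairs$mirna_id %in% exclude), , drop = FALSE]
}

#' @noRd
.ks_shift <- function(target_vals, bg_vals) {
  kt <- suppressWarnings(ks.test(target_vals, bg_vals))
  list(D = unname(kt$statistic), p = kt$p.value,
       direction = sign(median(target_vals) - median(bg_vals)))
}

#' Target-set cumulative shift test
#'
#' Per miRNA (or pooled over all retained pairs), compares the distribution
#' of a per-gene statistic for target genes against non-targets with a
#' two-sample Kolmogorov-Smirnov test; p-values are Bonferroni-adjusted
#' across the miRNAs tested in the batch. miRNAs with fewer than
#' `min_targets` targets carrying the metric are skipped.
#'
#' @param pairs Filtered target pairs (`mirna_id`, `gene_id`).
#' @param metrics data.frame with `gene_id` and the metric column.
#' @param metric Name of the metric column (e.g. `"mrna_lfc"`,
#'   `"tail_delta"`, `"utr_delta"`).
#' @param per_mirna Test each miRNA separately (default) or pool all
#'   targets into one set.
#' @param min_targets Minimum targets with a defined metric (default 5).
#' @return data.frame: `set_label`, `metric`, `n_targets`, `n_background`,
#'   `D`, `p_raw`, `p_adjusted`, `direction`.
#' @export
target_shift_test <- function(pairs, metrics, metric, per_mirna = TRUE,
                              min_targets = 5L) {
  if (!metric %in% names(metrics))
    .stopf("metric '%s' not found in metrics table", metric)
  vals <- setNames(metrics[[metric]], metrics$gene_id)
  vals <- vals[is.finite(vals)]
  sets <- if (per_mirna) split(pairs$gene_id, pairs$mirna_id) else
    list(all_targets = unique(pairs$gene_id))

  rows <- lapply(names(sets), function(lab) {
    tg <- intersect(unique(sets[[lab]]), names(vals))
    bg <- setdiff(names(vals), tg)
    if (length(tg) < min_targets || length(bg) < min_targets) return(NULL)
    ks <- .ks_shift(vals[tg], vals[bg])
    data.frame(set_label = lab, metric = metric,
               n_targets = length(tg), n_background = length(bg),
               D = ks$D, p_raw = ks$p, direction = ks$direction,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.empty_shift())
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_raw * nrow(out))
  out[, c("set_label", "metric", "n_targets", "n_background", "D",
          "p_raw", "p_adjusted", "direction")]
}

#' @noRd
.empty_shift <- function() {
  data.frame(set_label = character(), metric = character(),
             n_targets = integer(), n_background = integer(),
             D = numeric(), p_raw = numeric(), p_adjusted = numeric(),
             direction = numeric(), stringsAsFactors = FALSE)
}

#' Count-stratified shift test
#'
#' Bins genes by an integer count (e.g. predicted miRNA recognition
#' elements, or CLIP peaks in the 3'UTR) and compares each stratum's metric
#' distribution against the whole-transcriptome background by KS test with
#' Bonferroni adjustment across strata. A monotone-trend summary (Spearman
#' correlation of stratum rank vs stratum median) is attached as an
#' attribute.
#'
#' @param gene_counts data.frame `gene_id`, `count`.
#' @param metrics data.frame with `gene_id` and the metric column.
#' @param metric Metric column name.
#' @param breaks Integer cut points: stratum k is `[breaks[k],
#'   breaks[k+1])`; default `c(0, 1, 3, 6, Inf)` gives strata
#'   0, 1-2, 3-5, >=6.
#' @return Shift-result data.frame (one row per non-empty stratum) with
#'   attribute `trend` (Spearman rho).
#' @export
stratified_shift_test <- function(gene_counts, metrics, metric,
                                  breaks = c(0, 1, 3, 6, Inf)) {
  vals <- setNames(metrics[[metric]], metrics$gene_id)
  vals <- vals[is.finite(vals)]
  cnt <- setNames(gene_counts$count, gene_counts$gene_id)
  cnt <- cnt[names(cnt) %in% names(vals)]
  stratum <- cut(cnt, breaks = breaks, right = FALSE,
                 include.lowest = TRUE)
  rows <- list(); medians <- c()
  for (k in levels(stratum)) {
    tg <- names(cnt)[!is.na(stratum) & stratum == k]
    bg <- setdiff(names(vals), tg)
    if (length(tg) < 2L || length(bg) < 2L) next
    ks <- .ks_shift(vals[tg], vals[bg])
    rows[[k]] <- data.frame(set_label = k, metric = metric,
                            n_targets = length(tg),
                            n_background = length(bg),
                            D = ks$D, p_raw = ks$p,
                            direction = ks$direction,
                            stringsAsFactors = FALSE)
    medians[k] <- median(vals[tg])
  }
  if (!length(rows)) return(.empty_shift())
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_raw * nrow(out))
  rownames(out) <- NULL
  out <- out[, c("set_label", "metric", "n_targets", "n_background", "D",
                 "p_raw", "p_adjusted", "direction")]
  attr(out, "trend") <- if (length(medians) > 2L)
    suppressWarnings(cor(seq_along(medians), medians,
                         method = "spearman")) else NA_real_
  out
}

#' Negative-correlation screen of miRNA-mRNA pairs
#'
#' For each candidate pair, computes the Pearson correlation between the
#' miRNA's expression (e.g. logCPM) and the gene's metric across shared
#' samples, with a one-sided p-value for negative correlation (the
#' miRComb-style convention) and Benjamini-Hochberg FDR over tested pairs.
#'
#' @param mirna_mat miRNAs x samples numeric matrix.
#' @param gene_mat Genes x samples numeric matrix (same sample columns).
#' @param candidate_pairs data.frame `mirna_id`, `gene_id`.
#' @param fdr_cut Edge-report cutoff (default 0.05).
#' @return list with `edges` (significant negative edges: `mirna_id`,
#'   `gene_id`, `pearson_r`, `p_one_sided_negative`, `fdr`), `all_pairs`
#'   (every tested pair) and `network` (node + edge tables for export).
#' @export
negative_correlation_screen <- function(mirna_mat, gene_mat,
                                        candidate_pairs, fdr_cut = 0.05) {
  shared <- intersect(colnames(mirna_mat), colnames(gene_mat))
  if (length(shared) < 4L) .stopf("need at least 4 shared samples")
  mm <- mirna_mat[, shared, drop = FALSE]
  gm <- gene_mat[, shared, drop = FALSE]
  n <- length(shared)

  keep <- candidate_pairs$mirna_id %in% rownames(mm) &
    candidate_pairs$gene_id %in% rownames(gm)
  cp <- candidate_pairs[keep, , drop = FALSE]
  res <- lapply(seq_len(nrow(cp)), function(i) {
    x <- mm[cp$mirna_id[i], ]; y <- gm[cp$gene_id[i], ]
    if (sd(x) == 0 || sd(y) == 0) return(NULL)   # zero-variance: skip
    r <- cor(x, y)
    tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-12))
    p <- pt(tt, df = n - 2)                      # one-sided, r < 0
    data.frame(mirna_id = cp$mirna_id[i], gene_id = cp$gene_id[i],
               pearson_r = r, p_one_sided_negative = p,
               stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(list(edges = NULL, all_pairs = NULL, network = NULL))
  all_pairs <- do.call(rbind, res)
  all_pairs$fdr <- .bh(all_pairs$p_one_sided_negative)
  edges <- all_pairs[all_pairs$pearson_r < 0 & all_pairs$fdr < fdr_cut, ,
                     drop = FALSE]
  rownames(edges) <- rownames(all_pairs) <- NULL
  nodes <- data.frame(
    id = c(unique(edges$mirna_id), unique(edges$gene_id)),
    type = rep(c("mirna", "gene"),
               c(length(unique(edges$mirna_id)),
                 length(unique(edges$gene_id)))),
    stringsAsFactors = FALSE)
  list(edges = edges, all_pairs = all_pairs,
       network = list(nodes = nodes,
                      edges = edges[, c("mirna_id", "gene_id",
                                        "pearson_r")]))
}

#' Nested linear-model ANOVA
#'
#' Extra-sum-of-squares F test of whether `added` improves a linear model
#' of `response` on `base` (e.g. does tail-length change improve the
#' mRNA-to-translation relationship).
#'
#' @param response,base,added Numeric vectors (complete cases are used;
#'   at least 10 required).
#' @return list: `F`, `p_value`, `df1`, `df2`, plus `collinear = TRUE`
#'   with undefined p when the covariates are collinear.
#' @export
nested_model_anova <- function(response, base, added) {
  cc <- complete.cases(response, base, added)
  if (sum(cc) < 10L) .stopf("need at least 10 complete cases")
  y <- response[cc]; b <- base[cc]; a <- added[cc]
  if (abs(suppressWarnings(cor(b, a))) > 1 - 1e-10 || sd(a) == 0)
    return(list(F = NA_real_, p_value = NA_real_, df1 = NA, df2 = NA,
                collinear = TRUE))
  m0 <- lm(y ~ b); m1 <- lm(y ~ b + a)
  av <- anova(m0, m1)
  list(F = av$F[2], p_value = av$`Pr(>F)`[2],
       df1 = av$Df[2], df2 = av$Res.Df[2], collinear = FALSE)
}
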