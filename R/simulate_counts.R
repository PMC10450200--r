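# Negative-binomial count simulation and light-weight generators used to
# test the statistical modules at count / tail level without read sequences.

#' Simulate negative-binomial count matrices with injected fold changes
#'
#' Counts are drawn as `NB(mean = lib_size * baseline * 2^(lfc * treated),
#' dispersion)`; `dispersion = 0` degrades to Poisson. Baseline relative
#' abundances are log-normal and sum to one. If `lfc` is a matrix, one
#' matrix per column (assay) is generated with the same per-feature
#' baselines, which is the layout used to test translational-efficiency
#' models (interaction = difference of assay log2FCs).
#'
#' @param n_features Number of features (genes or miRNAs).
#' @param design data.frame with columns `sample_id` and `condition`
#'   (2 levels; the first level in order of appearance is the reference).
#' @param dispersion NB dispersion (>= 0).
#' @param lfc Numeric vector of per-feature log2 fold changes
#'   (treated vs reference), or a features x assays matrix.
#' @param lib_sizes Library sizes, recycled across samples.
#' @param baseline_log_sd SD of the log-normal baseline abundances.
#' @param seed Integer seed.
#'
#' @return If `lfc` is a vector: list with `counts` (features x samples
#'   integer matrix), `design`, `truth` (data.frame `feature_id`, `lfc`,
#'   `baseline`). If a matrix: named list of such lists, one per assay.
#' @export
simulate_counts <- function(n_features, design, dispersion = 0.05,
                            lfc = numeric(n_features),
                            lib_sizes = 1e6, baseline_log_sd = 1.2,
                            seed = 1L) {
  n_features <- .check_count(n_features, "n_features")
  if (dispersion < 0) .stopf("'dispersion' must be >= 0")
  if (any(lib_sizes <= 0)) .stopf("'lib_sizes' must be positive")
  if (!all(c("sample_id", "condition") %in% names(design)))
    .stopf("'design' needs columns sample_id, condition")
  if (is.matrix(lfc)) {
    assays <- colnames(lfc)
    if (is.null(assays)) assays <- paste0("assay", seq_len(ncol(lfc)))
    out <- lapply(seq_along(assays), function(j)
      simulate_counts(n_features, design, dispersion, lfc[, j], lib_sizes,
                      baseline_log_sd, seed = .derive_seed(seed, assays[j])))
    names(out) <- assays
    return(out)
  }
  if (length(lfc) != n_features)
    .stopf("'lfc' must have one entry per feature")
  set.seed(.check_count(seed, "seed", min = 0L))

  ref <- design$condition[1]
  treated <- design$condition != ref
  ns <- nrow(design)
  libs <- rep_len(lib_sizes, ns)
  base <- exp(rnorm(n_features, 0, baseline_log_sd))
  base <- base / sum(base)

  counts <- matrix(0L, n_features, ns,
                   dimnames = list(sprintf("f%05d", seq_len(n_features)),
                                   design$sample_id))
  for (s in seq_len(ns)) {
    mu <- libs[s] * base * 2^(if (treated[s]) lfc else 0)
    counts[, s] <- if (dispersion == 0) rpois(n_features, mu) else
      rnbinom(n_features, mu = mu, size = 1 / dispersion)
  }
  list(counts = counts, design = design,
       truth = data.frame(feature_id = rownames(counts), lfc = lfc,
                          baseline = base, stringsAsFactors = FALSE))
}

#' Simulate proximal/distal PAS read counts with known usage
#'
#' Per gene and sample, the polyadenylated read total is fixed at `depth`
#' and the distal count is binomial with the condition's distal-usage
#' fraction. This exercises the APA usage test and RED classification at
#' count level, without generating read sequences.
#'
#' @param n_genes Number of genes.
#' @param design data.frame `sample_id`, `condition`.
#' @param depth Reads per gene per sample.
#' @param distal_usage Named vector of distal-usage fractions per condition,
#'   or a genes x conditions matrix for per-gene usage.
#' @param seed Integer seed.
#' @return list with `counts`: data.frame (`gene_id`, `site_id`, one column
#'   per sample) and `truth`: per-gene true usage by condition.
#' @export
simulate_pas_usage_counts <- function(n_genes, design, depth = 500L,
                                      distal_usage, seed = 1L) {
  n_genes <- .check_count(n_genes, "n_genes")
  conds <- unique(design$condition)
  if (is.null(dim(distal_usage))) {
    if (!all(conds %in% names(distal_usage)))
      .stopf("'distal_usage' must be named by condition")
    distal_usage <- matrix(rep(distal_usage[conds], each = n_genes),
                           n_genes, length(conds),
                           dimnames = list(NULL, conds))
  }
  set.seed(.check_count(seed, "seed", min = 0L))
  ids <- sprintf("g%04d", seq_len(n_genes))
  distal <- proximal <- matrix(0L, n_genes, nrow(design),
                               dimnames = list(ids, design$sample_id))
  for (s in seq_len(nrow(design))) {
    u <- distal_usage[, as.character(design$condition[s])]
    distal[, s] <- rbinom(n_genes, depth, u)
    proximal[, s] <- depth - distal[, s]
  }
  counts <- rbind(
    data.frame(gene_id = ids, site_id = "proximal", proximal,
               check.names = FALSE, stringsAsFactors = FALSE),
    data.frame(gene_id = ids, site_id = "distal", distal,
               check.names = FALSE, stringsAsFactors = FALSE))
  rownames(counts) <- NULL
  truth <- data.frame(gene_id = ids, distal_usage,
                      check.names = FALSE, stringsAsFactors = FALSE)
  list(counts = counts, truth = truth, design = design)
}

#' Simulate per-read tail calls with per-condition mean shifts
#'
#' Draws `depth` polyadenylated reads per gene and sample with
#' truncated-normal integer tails, returning a table shaped like the output
#' of [call_tails()] so tail summaries and differential tests can be
#' exercised directly.
#'
#' @param n_genes Number of genes.
#' @param design data.frame `sample_id`, `condition`.
#' @param depth Reads per gene per sample.
#' @param tail_mean Named vector of tail means per condition, or a genes x
#'   conditions matrix.
#' @param tail_sd Tail SD (single value).
#' @param seed Integer seed.
#' @return list with `calls` (read-level data.frame: `read_id`, `gene_id`,
#'   `sample_id`, `tail_nontemplated`, `is_polyadenylated`) and `truth`
#'   (per-gene true means by condition).
#' @export
simulate_gene_tails <- function(n_genes, design, depth = 100L,
                                tail_mean, tail_sd = 15, seed = 1L) {
  n_genes <- .check_count(n_genes, "n_genes")
  conds <- unique(design$condition)
  if (is.null(dim(tail_mean))) {
    if (!all(conds %in% names(tail_mean)))
      .stopf("'tail_mean' must be named by condition")
    tail_mean <- matrix(rep(tail_mean[conds], each = n_genes),
                        n_genes, length(conds),
                        dimnames = list(NULL, conds))
  }
  ids <- sprintf("g%04d", seq_len(n_genes))
  out <- vector("list", nrow(design))
  for (s in seq_len(nrow(design))) {
    sm <- design$sample_id[s]
    set.seed(.derive_seed(seed, sm))
    mu <- tail_mean[, as.character(design$condition[s])]
    tails <- .rtail(n_genes * depth, rep(mu, each = depth), tail_sd)
    out[[s]] <- data.frame(
      read_id = sprintf("%s:r%07d", sm, seq_len(n_genes * depth)),
      gene_id = rep(ids, each = depth), sample_id = sm,
      tail_nontemplated = tails, is_polyadenylated = TRUE,
      stringsAsFactors = FALSE)
  }
  list(calls = do.call(rbind, out),
       truth = data.frame(gene_id = ids, tail_mean,
                          check.names = FALSE, stringsAsFactors = FALSE),
       design = design)
}
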