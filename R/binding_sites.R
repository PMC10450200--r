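# Canonical miRNA seed-site scanning (TargetScan-style site classes) and
# the gained-vs-common site census for APA lengthening events.
#
# Site classes, written 5'->3' on the mRNA:
#   6mer     : perfect match to the reverse complement of miRNA bases 2-7
#   7mer-m8  : 6mer plus a match opposite miRNA base 8 (one base 5' of the
#              6mer core on the mRNA)
#   7mer-A1  : 6mer plus an adenosine opposite miRNA base 1 (one base 3'
#              of the core), an A regardless of the miRNA base
#   8mer     : both the m8 match and the A1 adenosine
# At one core locus only the strongest class is reported
# (8mer > 7mer-m8 > 7mer-A1 > 6mer), so class counts partition loci.

.SITE_LEVELS <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Find canonical miRNA seed-match sites in a 3'UTR sequence
#'
#' Scans the sense-strand UTR sequence for reverse-complement matches to
#' the miRNA seed (bases 2-7), then classifies each core locus as 8mer,
#' 7mer-m8, 7mer-A1 or 6mer. U and T are equivalent; windows containing
#' other characters are skipped with a warning.
#'
#' @param region_seq UTR (sub)sequence, sense strand, 5'->3'.
#' @param mirna_seq Mature miRNA sequence 5'->3' (length >= 8).
#' @param site_types Site classes to report (default all four).
#' @return data.frame: `site_type`, `position` (0-based start of the full
#'   site on the UTR), `length`, `core_position` (0-based start of the
#'   6mer core).
#' @export
find_seed_sites <- function(region_seq, mirna_seq,
                            site_types = .SITE_LEVELS) {
  if (nchar(mirna_seq) < 8L) .stopf("'mirna_seq' must be >= 8 nt")
  site_types <- match.arg(site_types, .SITE_LEVELS, several.ok = TRUE)
  utr <- chartr("Uu", "Tt", toupper(region_seq))
  mir <- chartr("Uu", "Tt", toupper(mirna_seq))
  n <- nchar(utr)
  empty <- data.frame(site_type = character(), position = integer(),
                      length = integer(), core_position = integer(),
                      stringsAsFactors = FALSE)
  if (n < 6L) return(empty)
  if (grepl("[^ACGT]", utr)) {
    .warnf("non-ACGTU characters in UTR sequence; affected windows skipped")
  }

  # core = reverse complement of miRNA bases 2-7 (6 nt on the mRNA)
  core <- .revcomp(substr(mir, 2L, 7L))
  m8 <- .complement(substr(mir, 8L, 8L))  # base opposite miRNA position 8
  starts <- integer(0)
  hit <- gregexpr(core, utr, fixed = TRUE)[[1]]
  if (hit[1] != -1L) starts <- as.integer(hit)
  if (!length(starts)) return(empty)

  rows <- lapply(starts, function(s) {         # s: 1-based core start
    has_m8 <- s > 1L && substr(utr, s - 1L, s - 1L) == m8
    has_a1 <- s + 6L <= n && substr(utr, s + 6L, s + 6L) == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
            else if (has_a1) "7mer-A1" else "6mer"
    pos <- if (has_m8) s - 2L else s - 1L      # 0-based site start
    len <- 6L + has_m8 + has_a1
    data.frame(site_type = type, position = pos, length = len,
               core_position = s - 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[out$site_type %in% site_types, , drop = FALSE]
}

#' Census of miRNA sites gained by 3'UTR lengthening vs common sites
#'
#' For each lengthening event, the common region is the annotated UTR up to
#' the proximal cleavage point and the gained region is the sequence
#' between the proximal and distal cleavage points. Sites are counted per
#' gene and per miRNA in each region. 6mer sites are excluded by default
#' (canonical 7-8mer classes only), configurable via `site_types`.
#'
#' @param events `apa_events` table (only rows with
#'   `classification == "lengthening"` are used) or any data.frame with
#'   `gene_id` and `prox_len` / `dist_len` columns.
#' @param utr_seqs Named character vector (or `DNAStringSet`) of full
#'   transcription-direction 3'UTR sequences per gene (CDS end to distal
#'   cleavage point).
#' @param mirnas data.frame `mirna_id`, `sequence` (mature, 5'->3').
#' @param conservation Optional data.frame `mirna_id`, `conserved_mirna`
#'   (logical) plus optionally `site_conserved_prob` is NOT supported;
#'   site-level conservation comes via `site_flags`.
#' @param site_flags Optional data.frame `gene_id`, `mirna_id`,
#'   `site_type`, `position`, `conserved_site` to annotate individual
#'   sites; unmatched sites get `FALSE`.
#' @param site_types Site classes to count (default 7-8mers).
#' @return list with `sites` (one row per site: gene, miRNA, type, region,
#'   conservation flags), `per_gene` (gained/common counts + medians as
#'   attributes), `per_mirna` (gained/common counts per miRNA).
#' @export
gained_site_census <- function(events, utr_seqs, mirnas,
                               conservation = NULL, site_flags = NULL,
                               site_types = c("8mer", "7mer-m8",
                                              "7mer-A1")) {
  ev <- if ("classification" %in% names(events)) {
    events[events$classification == "lengthening", , drop = FALSE]
  } else events
  if (is(utr_seqs, "XStringSet"))
    utr_seqs <- setNames(as.character(utr_seqs), names(utr_seqs))

  all_sites <- list()
  for (i in seq_len(nrow(ev))) {
    g <- ev$gene_id[i]
    if (!g %in% names(utr_seqs)) {
      message("gene ", g, ": missing UTR sequence; skipped")
      next
    }
    seq_full <- utr_seqs[[g]]
    pl <- as.integer(round(ev$prox_len[i]))
    dl <- as.integer(round(ev$dist_len[i]))
    if (is.na(pl) || is.na(dl) || dl <= pl) next
    common_seq <- substr(seq_full, 1L, pl)
    gained_seq <- substr(seq_full, pl + 1L, min(dl, nchar(seq_full)))
    for (m in seq_len(nrow(mirnas))) {
      for (reg in c("common", "gained")) {
        rs <- if (reg == "common") common_seq else gained_seq
        hits <- find_seed_sites(rs, mirnas$sequence[m], site_types)
        if (!nrow(hits)) next
        hits$gene_id <- g
        hits$mirna_id <- mirnas$mirna_id[m]
        hits$region <- reg
        all_sites[[length(all_sites) + 1L]] <- hits
      }
    }
  }
  if (!length(all_sites))
    return(list(sites = NULL, per_gene = NULL, per_mirna = NULL))
  sites <- do.call(rbind, all_sites)

  sites$conserved_mirna <- FALSE
  if (!is.null(conservation)) {
    m <- match(sites$mirna_id, conservation$mirna_id)
    sites$conserved_mirna <- !is.na(m) &
      as.logical(conservation$conserved_mirna[m])
  }
  sites$conserved_site <- FALSE
  if (!is.null(site_flags)) {
    key <- function(d) paste(d$gene_id, d$mirna_id, d$site_type,
                             d$position)
    sites$conserved_site <- key(sites) %in%
      key(site_flags[as.logical(site_flags$conserved_site), , drop = FALSE])
  }

  per_gene <- as.data.frame.matrix(
    table(sites$gene_id, factor(sites$region,
                                levels = c("common", "gained"))))
  per_gene <- data.frame(gene_id = rownames(per_gene),
                         common = per_gene$common,
                         gained = per_gene$gained,
                         stringsAsFactors = FALSE)
  attr(per_gene, "median_gained") <- median(per_gene$gained)
  attr(per_gene, "median_common") <- median(per_gene$common)
  per_mirna <- as.data.frame.matrix(
    table(sites$mirna_id, factor(sites$region,
                                 levels = c("common", "gained"))))
  per_mirna <- data.frame(mirna_id = rownames(per_mirna),
                          common = per_mirna$common,
                          gained = per_mirna$gained,
                          stringsAsFactors = FALSE)
  list(sites = sites, per_gene = per_gene, per_mirna = per_mirna)
}

#' Chi-squared tests of site-conservation composition
#'
#' Tests (i) conserved vs non-conserved composition within the gained
#' sites and (ii) whether the conservation composition differs between
#' gained and common sites. Pearson chi-squared without continuity
#' correction by default.
#'
#' @param site_table data.frame with `region` (`gained`/`common`) and a
#'   logical conservation column.
#' @param flag Name of the conservation column (default
#'   `"conserved_site"`).
#' @param correct Continuity correction (default FALSE).
#' @return list with `within_gained` (chi-squared of conserved vs
#'   non-conserved counts against a uniform split) and `gained_vs_common`
#'   (2x2 test), each `(chi2, df, p_value)`.
#' @export
conservation_chisq <- function(site_table, flag = "conserved_site",
                               correct = FALSE) {
  tab <- table(factor(site_table$region, levels = c("common", "gained")),
               factor(site_table[[flag]], levels = c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0)) .stopf("zero margin in site table")
  gained <- tab["gained", ]
  within <- suppressWarnings(chisq.test(gained, correct = correct))
  if (any(colSums(tab) == 0)) {
    between <- list(statistic = NA_real_, parameter = NA_real_,
                    p.value = NA_real_)
  } else {
    between <- suppressWarnings(chisq.test(tab, correct = correct))
  }
  list(within_gained = list(chi2 = unname(within$statistic),
                            df = unname(within$parameter),
                            p_value = within$p.value),
       gained_vs_common = list(chi2 = unname(between$statistic),
                               df = unname(between$parameter),
                               p_value = between$p.value))
}

#' Shift test of 3'UTR length change for miRNA target sets
#'
#' Delegates to [target_shift_test()] with the per-gene 3'UTR length
#' change as the metric.
#'
#' @param pairs Filtered target pairs.
#' @param delta_utr data.frame `gene_id`, `utr_delta`.
#' @param ... Passed to [target_shift_test()].
#' @return Shift-result data.frame.
#' @export
utr_delta_shift_by_targets <- function(pairs, delta_utr, ...) {
  target_shift_test(pairs, delta_utr, metric = "utr_delta", ...)
}
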