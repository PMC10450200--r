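# Summary reports over result tables. Percentage fields follow the
# conventions of published summaries: tail-length reports use one decimal
# place, APA and conservation composition reports use whole percentages.

#' Summarise a differential tail-length result table
#'
#' @param res Result of [diff_tail_length()] (needs `delta_tail`,
#'   `significant`).
#' @return list: `n_tested`, `n_significant`, `n_lengthening`,
#'   `n_shortening`, `pct_lengthening` (share of significant genes with
#'   increased tails, one decimal), `mean_delta_significant`,
#'   `mean_delta_nonsignificant`.
#' @export
summarize_tail_diff <- function(res) {
  sig <- res[res$significant, , drop = FALSE]
  n_len <- sum(sig$delta_tail > 0)
  list(n_tested = nrow(res),
       n_significant = nrow(sig),
       n_lengthening = n_len,
       n_shortening = sum(sig$delta_tail < 0),
       pct_lengthening = if (nrow(sig)) round(100 * n_len / nrow(sig), 1)
                         else NA_real_,
       mean_delta_significant = if (nrow(sig)) mean(sig$delta_tail)
                                else NA_real_,
       mean_delta_nonsignificant =
         mean(res$delta_tail[!res$significant]))
}

#' Summarise an APA event table
#'
#' @param events `apa_events` table from [apa_event_analysis()] (or any
#'   data.frame with `classification` and optionally `delta_utr_len`).
#' @return list: `n_genes`, `n_events` (lengthening + shortening),
#'   `n_lengthening`, `n_shortening`, `pct_lengthening` (share of events
#'   that are lengthening, whole percent), and median 3'UTR length changes
#'   per class when available.
#' @export
summarize_apa_events <- function(events) {
  cls <- events$classification
  n_len <- sum(cls == "lengthening")
  n_sho <- sum(cls == "shortening")
  n_ev <- n_len + n_sho
  med <- function(sel) {
    if ("delta_utr_len" %in% names(events) && any(sel))
      median(events$delta_utr_len[sel], na.rm = TRUE) else NA_real_
  }
  list(n_genes = nrow(events), n_events = n_ev,
       n_lengthening = n_len, n_shortening = n_sho,
       pct_lengthening = if (n_ev) round(100 * n_len / n_ev) else NA_real_,
       median_delta_lengthening = med(cls == "lengthening"),
       median_delta_shortening = med(cls == "shortening"),
       median_delta_other = med(cls == "none"))
}

#' Summarise conservation composition of a site census
#'
#' @param sites Site table from [gained_site_census()] (`region`,
#'   `conserved_site`, `conserved_mirna`).
#' @return list with per-region counts and whole-percent shares of
#'   non-conserved sites and non-conserved miRNAs among gained sites
#'   (`pct_nonconserved_site`, `pct_nonconserved_mirna`), plus the same
#'   for common sites.
#' @export
summarize_site_conservation <- function(sites) {
  per_region <- function(reg) {
    d <- sites[sites$region == reg, , drop = FALSE]
    n <- nrow(d)
    n_ncs <- sum(!d$conserved_site)
    n_ncm <- sum(!d$conserved_mirna)
    list(n_sites = n,
         n_nonconserved_site = n_ncs,
         n_nonconserved_mirna = n_ncm,
         pct_nonconserved_site = if (n) round(100 * n_ncs / n) else
           NA_real_,
         pct_nonconserved_mirna = if (n) round(100 * n_ncm / n) else
           NA_real_)
  }
  list(gained = per_region("gained"), common = per_region("common"))
}
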