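# PAS counting, site filtering, the usage LRT, RED, event classification
# and 3'UTR length-change quantification.

test_that("count_pas_reads respects intervals, flanks and nearest midpoint", {
  pas <- data.frame(chrom = "chr1", start = c(100L, 200L, 300L, 312L),
                    end = c(105L, 205L, 305L, 317L), strand = "+",
                    gene_id = "g",
                    site_id = c("s1", "s2", "s3", "s4"),
                    stringsAsFactors = FALSE)
  calls <- data.frame(
    chrom = "chr1", strand = "+", sample_id = "a",
    cleavage_pos = c(100L,   # exactly at site start (half-open: inside)
                     114L,   # within the 10 nt flank of site 1
                     116L,   # 11 nt past the interval: outside the flank
                     204L,   # inside site 2
                     215L,   # just past site 2's flank (ends at 214)
                     308L),  # overlaps sites 3 and 4; nearer midpoint 302.5
    is_polyadenylated = TRUE, stringsAsFactors = FALSE)
  out <- count_pas_reads(calls, pas, flank = 10L)
  expect_equal(out$a, c(2L, 1L, 1L, 0L))
  # strand mismatch never counts
  calls$strand <- "-"
  out2 <- count_pas_reads(calls, pas, flank = 10L)
  expect_equal(out2$a, c(0L, 0L, 0L, 0L))
})

test_that("filter_sites: strict per-sample vs mean-mode reading", {
  sc <- data.frame(gene_id = "g", site_id = c("a", "b"),
                   s1 = c(2, 5), s2 = c(2, 5), s3 = c(2, 5),
                   s4 = c(2, 1.9), s5 = c(2, 5), s6 = c(2, 5),
                   stringsAsFactors = FALSE)
  ids <- paste0("s", 1:6)
  eff <- rep(1, 6) # unit libraries: normalised = raw
  strict <- filter_sites(sc, ids, eff * mean(eff), min_norm = 2)
  expect_equal(strict$site_id, "a")        # boundary 2 kept, 1.9 removed
  mean_mode <- filter_sites(sc, ids, eff * mean(eff), min_norm = 2,
                            mode = "mean")
  expect_setequal(mean_mode$site_id, c("a", "b"))  # mean 4.48 >= 2
})

test_that("red matches hand arithmetic and its symmetries", {
  expect_equal(red(4, 4, 7, 7), 0)
  expect_equal(red(8, 2, 2, 8), 4)
  expect_equal(red(2, 8, 8, 2), -4)
  expect_error(red(0, 1, 1, 1), "positive")
  # antisymmetry under condition swap and under proximal/distal exchange
  set.seed(99)
  q <- matrix(runif(4000, 0.5, 100), ncol = 4)
  for (i in 1:1000) {
    r0 <- red(q[i, 1], q[i, 2], q[i, 3], q[i, 4])
    expect_equal(red(q[i, 2], q[i, 1], q[i, 4], q[i, 3]), -r0)
    expect_equal(red(q[i, 3], q[i, 4], q[i, 1], q[i, 2]), -r0)
  }
})

test_that("classify_event follows the coupled RED + per-site criteria", {
  expect_equal(classify_event(1.5, 1.2, 0.04, NA, NA), "lengthening")
  expect_equal(classify_event(1.5, 0.5, 0.5, -0.2, 0.9), "none")
  expect_equal(classify_event(-1.2, NA, NA, 0.9, 0.01), "shortening")
  # red alone is never sufficient
  expect_equal(classify_event(3, 1.2, 0.2, -1, 0.2), "none")
  # mutual exclusivity via the invariance under swap + relabel
  cls <- classify_event(2, 1, 0.01, -1, 0.01)
  swapped <- classify_event(-2, -1, 0.01, 1, 0.01)
  expect_equal(cls, "lengthening")
  expect_equal(swapped, "shortening")
})

test_that("delta_utr_length is the usage-weighted change", {
  expect_equal(delta_utr_length(200, 1800, 0.5, 0.5), 0)
  expect_equal(delta_utr_length(200, 1800, 0.1, 0.9), 1280)
  expect_equal(delta_utr_length(200, 1800, 0, 1), 1600)  # full switch
})

test_that("pas_region_chisq matches the hand formula and flags degeneracy", {
  tab <- matrix(c(10, 20, 20, 10), 2,
                dimnames = list(c("3UTR", "intron"), c("ctl", "dif")))
  out <- pas_region_chisq(tab)
  # hand Pearson chi-squared: all expected cells are 15
  expect_equal(out$chi2, sum((tab - 15)^2 / 15))
  same <- matrix(c(30, 30, 10, 10), 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("ctl", "dif")))
  expect_gt(pas_region_chisq(same)$p_value, 0.99)
  degen <- matrix(c(5, 0, 7, 0), 2)
  expect_error(pas_region_chisq(degen), "degenerate")
})

test_that("diff_site_usage: null lfc ~ 0 and label-swap antisymmetry", {
  design <- design_3v3()
  u <- matrix(0.4, 40, 2,
              dimnames = list(NULL, c("control", "differentiated")))
  pc <- simulate_pas_usage_counts(40, design, depth = 400,
                                  distal_usage = u, seed = 8)
  res <- diff_site_usage(pc$counts, design)
  expect_lt(mean(abs(res$usage_lfc), na.rm = TRUE), 0.15)
  # exchanging the conditions (reference level becomes the treated one)
  # negates the usage log-fold-change
  res_sw <- diff_site_usage(pc$counts, design[6:1, ], dispersion = 1e-6)
  res_fx <- diff_site_usage(pc$counts, design, dispersion = 1e-6)
  expect_equal(res_sw$usage_lfc, -res_fx$usage_lfc, tolerance = 1e-6)
})

test_that("apa_event_analysis recovers injected usage switches", {
  design <- design_3v3()
  u <- matrix(0.2, 80, 2,
              dimnames = list(NULL, c("control", "differentiated")))
  u[1:8, "differentiated"] <- 0.8
  pc <- simulate_pas_usage_counts(80, design, depth = 500,
                                  distal_usage = u, seed = 4)
  ev <- apa_event_analysis(pc$counts, design)
  inj <- ev$gene_id %in% sprintf("g%04d", 1:8)
  expect_gte(mean(ev$classification[inj] == "lengthening"), 0.8)
  expect_lte(mean(ev$classification[!inj] == "lengthening"), 0.1)
  # site-count conservation: per-gene site counts sum to the gene total
  m <- as.matrix(pc$counts[, design$sample_id])
  expect_true(all(rowsum(m, pc$counts$gene_id) == 500L))
})

test_that("apa_event_analysis computes usage-weighted UTR length change", {
  design <- design_3v3()
  # one gene with coordinates: proximal at +200, distal at +1800
  counts <- data.frame(
    gene_id = "g1", site_id = c("proximal", "distal"),
    chrom = "chr1", start = c(1198L, 2798L), end = c(1203L, 2803L),
    strand = "+", stringsAsFactors = FALSE)
  usage <- c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1)   # distal usage per sample
  depth <- 1000
  for (i in seq_len(6)) {
    counts[[design$sample_id[i]]] <-
      c(round((1 - usage[i]) * depth), round(usage[i] * depth))
  }
  genes <- data.frame(gene_id = "g1", cds_end = 1000L, strand = "+",
                      stringsAsFactors = FALSE)
  ev <- apa_event_analysis(counts, design, genes = genes)
  expect_equal(ev$prox_len, 200.5)           # midpoint convention
  expect_equal(ev$dist_len, 1800.5)
  expect_equal(ev$delta_utr_len,
               delta_utr_length(200.5, 1800.5, 0.9, 0.1),
               tolerance = 0.05)
  expect_equal(ev$classification, "shortening")
  expect_lt(ev$red, -1)
})
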