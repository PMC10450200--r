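# miRNA integration: target filtering, KS shift tests, stratified tests,
# the negative-correlation screen and the nested-model ANOVA.

test_that("filter_target_pairs applies score and exclusion rules", {
  pairs <- data.frame(
    mirna_id = c("m1", "m1", "m2", "m3"),
    gene_id = c("gA", "gB", "gC", "gD"),
    context_score = c(-0.5, -0.1, -0.3, -0.9),
    stringsAsFactors = FALSE)
  f <- filter_target_pairs(pairs)
  expect_setequal(f$gene_id, c("gA", "gC", "gD"))     # -0.1 dropped
  f2 <- filter_target_pairs(pairs, exclude = "m3")
  expect_false("m3" %in% f2$mirna_id)
  # boundary: exactly -0.2 is retained (scores above -0.2 are dropped)
  expect_equal(nrow(filter_target_pairs(
    data.frame(mirna_id = "m", gene_id = "g", context_score = -0.2))), 1L)
})

test_that("target_shift_test: null targets, simulated repression, oracle D", {
  set.seed(21)
  genes <- sprintf("G%04d", 1:2000)
  metrics <- data.frame(gene_id = genes, rfp_lfc = rnorm(2000, 0, 0.6),
                        stringsAsFactors = FALSE)
  # random subset: adjusted p near 1
  null_pairs <- data.frame(mirna_id = "mirX",
                           gene_id = sample(genes, 300))
  r0 <- target_shift_test(null_pairs, metrics, "rfp_lfc")
  expect_gt(r0$p_raw, 0.01)
  # simulated repression: targets shifted by -0.5
  tg <- sample(genes, 300)
  metrics2 <- metrics
  metrics2$rfp_lfc[metrics2$gene_id %in% tg] <-
    metrics2$rfp_lfc[metrics2$gene_id %in% tg] - 0.5
  r1 <- target_shift_test(data.frame(mirna_id = "mirY", gene_id = tg),
                          metrics2, "rfp_lfc")
  expect_lt(r1$p_adjusted, 0.001)
  expect_equal(r1$direction, -1)
  expect_equal(r1$n_targets, 300L)
  expect_equal(r1$n_background, 1700L)
  # Bonferroni bounds
  expect_gte(r1$p_adjusted, r1$p_raw)
  # background is a set: permuting metric row order changes nothing
  perm <- metrics2[sample(nrow(metrics2)), ]
  r2 <- target_shift_test(data.frame(mirna_id = "mirY", gene_id = tg),
                          perm, "rfp_lfc")
  expect_equal(r2$D, r1$D)
  # toy oracle
  x <- c(0.1, 0.5, 0.9, 1.4, 2.2, 3.3)
  y <- c(0.2, 0.6, 1.0, 1.1)
  expect_equal(suppressWarnings(ks.test(x, y)$statistic[[1]]),
               brute_ks_D(x, y))
})

test_that("stratified_shift_test partitions genes and finds dose effects", {
  set.seed(5)
  genes <- sprintf("G%04d", 1:1500)
  cnt <- rpois(1500, 2)
  metrics <- data.frame(gene_id = genes,
                        lfc = rnorm(1500, 0.2 * cnt, 0.5),
                        stringsAsFactors = FALSE)
  gc <- data.frame(gene_id = genes, count = cnt)
  res <- stratified_shift_test(gc, metrics, "lfc")
  # default breaks partition exhaustively and disjointly
  expect_equal(sum(res$n_targets), 1500L)
  expect_gt(attr(res, "trend"), 0.9)     # monotone medians
  expect_true(any(res$p_adjusted < 0.01))
  # single stratum vs itself is skipped
  gc1 <- data.frame(gene_id = genes, count = 0L)
  res1 <- stratified_shift_test(gc1, metrics, "lfc")
  expect_equal(nrow(res1), 0L)
})

test_that("negative_correlation_screen: perfect, null, and hand-checked r", {
  set.seed(3)
  samples <- paste0("s", 1:6)
  mirna <- matrix(rnorm(6), 1, 6, dimnames = list("mir1", samples))
  gene <- -mirna
  rownames(gene) <- "gene1"
  out <- negative_correlation_screen(mirna, gene,
                                     data.frame(mirna_id = "mir1",
                                                gene_id = "gene1"))
  expect_equal(out$all_pairs$pearson_r, -1, tolerance = 1e-12)
  expect_lt(out$all_pairs$p_one_sided_negative, 1e-8)
  expect_equal(nrow(out$edges), 1L)

  # independent series: ~5% raw p < 0.05, none after FDR
  nm <- 40; ng <- 25
  mm <- matrix(rnorm(nm * 6), nm, 6,
               dimnames = list(paste0("m", 1:nm), samples))
  gm <- matrix(rnorm(ng * 6), ng, 6,
               dimnames = list(paste0("g", 1:ng), samples))
  cand <- expand.grid(mirna_id = paste0("m", 1:nm),
                      gene_id = paste0("g", 1:ng),
                      stringsAsFactors = FALSE)
  nul <- negative_correlation_screen(mm, gm, cand)
  expect_lt(mean(nul$all_pairs$p_one_sided_negative < 0.05), 0.10)
  expect_lte(nrow(nul$edges), 2L)

  # r against the hand covariance formula on a 5-point series
  x <- c(1, 2, 4, 6, 9); y <- c(3, 1, 4, 2, 0)
  mm5 <- matrix(x, 1, 5, dimnames = list("mx", paste0("t", 1:5)))
  gm5 <- matrix(y, 1, 5, dimnames = list("gy", paste0("t", 1:5)))
  out5 <- negative_correlation_screen(
    mm5, gm5, data.frame(mirna_id = "mx", gene_id = "gy"))
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out5$all_pairs$pearson_r, r_hand, tolerance = 1e-12)

  # zero-variance series is skipped
  gm0 <- matrix(5, 1, 6, dimnames = list("flat", samples))
  out0 <- negative_correlation_screen(
    mirna, gm0, data.frame(mirna_id = "mir1", gene_id = "flat"))
  expect_null(out0$all_pairs)
})

test_that("nested_model_anova matches hand RSS arithmetic on a 12-row toy", {
  set.seed(13)
  b <- rnorm(12); a <- rnorm(12)
  y <- 1 + 2 * b + 0.8 * a + rnorm(12, 0, 0.3)
  out <- nested_model_anova(y, b, a)
  rss0 <- sum(resid(lm(y ~ b))^2)
  rss1 <- sum(resid(lm(y ~ b + a))^2)
  f_hand <- (rss0 - rss1) / (rss1 / (12 - 3))
  expect_equal(out$F, f_hand, tolerance = 1e-10)
  expect_equal(out$p_value, pf(f_hand, 1, 9, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_lt(out$p_value, 0.05)          # generating covariate detected
  # pure-noise covariate is not significant in a clear case
  y2 <- 1 + 2 * b + rnorm(12, 0, 0.1)
  out2 <- nested_model_anova(y2, b, rep(c(0.5, -0.5), 6))
  expect_gt(out2$p_value, 1e-4)
  # collinear covariates are flagged
  outc <- nested_model_anova(y, b, 2 * b)
  expect_true(outc$collinear)
  expect_true(is.na(outc$p_value))
  expect_error(nested_model_anova(y[1:5], b[1:5], a[1:5]), "complete cases")
})
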