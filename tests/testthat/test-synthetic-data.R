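# Synthetic-data generators: determinism, stated invariants, and clean
# parsing of the emitted standard formats.

test_that("simulate_genome honours probability-zero and binomial templated runs", {
  one <- simulate_genome(1, templated_a_prob = 0, seed = 3)
  expect_equal(nrow(one$genes), 1L)
  expect_equal(one$genes$templated_a_run, 0L)
  expect_equal(nrow(one$pas), 2L)            # exactly two PAS per gene

  sim <- simulate_genome(200, templated_a_prob = 0.5, seed = 7)
  # regenerate the generator's own RNG stream to predict which genes carry
  # a run (the draw happens right after utr lengths and proximal offsets)
  set.seed(7)
  runif(200); runif(200)                      # utr_len, prox fraction
  expected_has_run <- runif(200) < 0.5
  expect_equal(sim$genes$templated_a_run > 0, expected_has_run)
  expect_true(all(sim$genes$templated_a_run %in% c(0L, 4:12)))
})

test_that("simulate_genome is byte-identical across runs and exports parse", {
  sim1 <- simulate_genome(30, seed = 1)
  sim2 <- simulate_genome(30, seed = 1)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  write_sim_genome(sim1, d1); write_sim_genome(sim2, d2)
  for (f in c("genome.fa", "genes.gff3", "pas.bed")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # standard parsers accept the output
  fa <- Biostrings::readDNAStringSet(file.path(d1, "genome.fa"))
  expect_equal(length(fa), 30L)
  skip_if_not_installed("rtracklayer")
  gff <- rtracklayer::import(file.path(d1, "genes.gff3"))
  expect_equal(length(gff), 30L)
  bed <- rtracklayer::import(file.path(d1, "pas.bed"))
  expect_equal(length(bed), 60L)
  # BED is 0-based half-open on disk; rtracklayer re-bases to 1-based
  expect_equal(GenomicRanges::start(bed),
               sim1$pas$start + 1L)
})

test_that("gene geometry invariants hold on both strands", {
  sim <- simulate_genome(40, templated_a_prob = 0.4, seed = 11)
  g <- sim$genes
  # proximal strictly between cds_end and distal in transcription direction
  plus <- g$strand == "+"
  expect_true(all(g$pas_proximal[plus] > g$cds_end[plus] &
                    g$pas_proximal[plus] < g$pas_distal[plus]))
  expect_true(all(g$pas_proximal[!plus] < g$cds_end[!plus] &
                    g$pas_proximal[!plus] > g$pas_distal[!plus]))
  expect_true(all(nchar(g$utr_seq) == g$utr_length))
  # templated run really is in the genome right after each cleavage point
  for (i in which(g$templated_a_run > 0)[1:5]) {
    utr <- g$utr_seq[i]
    prox_off <- g$utr_length[i] - abs(g$pas_distal[i] - g$pas_proximal[i])
    run <- g$templated_a_run[i]
    expect_equal(substr(utr, prox_off + 1, prox_off + run),
                 strrep("A", run))
    expect_false(substr(utr, prox_off, prox_off) == "A")
  }
})

test_that("simulate_pat_reads: degenerate distributions and conservation", {
  sim <- simulate_genome(5, templated_a_prob = 0, seed = 2)
  sheet <- sample_sheet(tail_mean = c(30, 30), tail_sd = 0,
                        distal_usage = c(1, 1), depth = 10)
  rd <- simulate_pat_reads(sim, sheet, error_rate = 0, seed = 5)
  expect_true(all(rd$reads$true_tail == 30L))         # sd = 0
  expect_true(all(rd$reads$site == "distal"))         # usage = 1
  # conservation: per-gene truth counts = proximal + distal = reads
  tg <- rd$truth_gene
  expect_true(all(tg$n_reads == tg$n_distal + tg$n_proximal))
  expect_true(all(tg$n_reads == 10L))
  # parameter errors
  expect_error(simulate_pat_reads(sim, sheet, read_len = 10),
               "anchor")
})

test_that("simulated tail means match the target within sampling error", {
  sim <- simulate_genome(10, seed = 4)
  sheet <- sample_sheet(tail_mean = c(44, 44), tail_sd = 15, depth = 100)
  sheet <- sheet[1:2, ]                                # 2 x 1000 reads
  rd <- simulate_pat_reads(sim, sheet, error_rate = 0, seed = 3)
  n <- nrow(rd$reads)
  # truncation at 0 is negligible at mean 44 sd 15; 3 SE bound
  expect_lt(abs(mean(rd$reads$true_tail) - 44), 3 * 15 / sqrt(n))
})

test_that("per-sample RNG streams are stable when samples are added", {
  sim <- simulate_genome(5, seed = 2)
  s2 <- sample_sheet(depth = 20)[1:2, ]
  s4 <- sample_sheet(depth = 20)[1:4, ]
  r2 <- simulate_pat_reads(sim, s2, seed = 9)
  r4 <- simulate_pat_reads(sim, s4, seed = 9)
  expect_identical(r2$reads,
                   r4$reads[r4$reads$sample_id %in% s2$sample_id, ])
})

test_that("FASTQ and SAM exports are read back by standard parsers", {
  sim <- simulate_genome(4, templated_a_prob = 0.5, seed = 6)
  sheet <- sample_sheet(depth = 5)[c(1, 4), ]
  rd <- simulate_pat_reads(sim, sheet, error_rate = 0.01, seed = 8)
  outdir <- file.path(tempdir(), "sim_reads")
  write_pat_reads(rd, sim, outdir)
  fq <- Biostrings::readDNAStringSet(file.path(outdir, "ctl1.fastq"),
                                     format = "fastq")
  expect_equal(length(fq), sum(rd$reads$sample_id == "ctl1"))
  skip_if_not_installed("Rsamtools")
  aln <- read_alignments(file.path(outdir, "ctl1.fastq"),
                         file.path(outdir, "ctl1.truth.sam"),
                         sample_id = "ctl1")
  ref <- rd$reads[rd$reads$sample_id == "ctl1", ]
  m <- match(ref$read_id, aln$read_id)
  expect_false(anyNA(m))
  expect_equal(aln$align_pos[m], ref$align_pos)
  expect_equal(aln$seq[m], ref$seq)
  # calling from files equals calling from the in-memory table
  calls_file <- call_tails(aln, sim$genome, sim$genes)
  calls_mem <- call_tails(ref, sim$genome, sim$genes)
  m2 <- match(calls_mem$read_id, calls_file$read_id)
  expect_equal(calls_file$tail_nontemplated[m2], calls_mem$tail_nontemplated)
})

test_that("simulate_counts: determinism, Poisson limit, and lfc recovery", {
  design <- design_3v3()
  a <- simulate_counts(100, design, dispersion = 0.05, seed = 5)
  b <- simulate_counts(100, design, dispersion = 0.05, seed = 5)
  expect_identical(a$counts, b$counts)

  lfc <- c(rep(1.5, 20), rep(0, 80))
  big <- simulate_counts(100, design, dispersion = 0, lfc = lfc,
                         lib_sizes = 5e6, seed = 2)
  cond <- big$design$condition
  m1 <- rowMeans(big$counts[, cond == "control"])
  m2 <- rowMeans(big$counts[, cond == "differentiated"])
  obs_lfc <- log2(m2 / m1)
  # dispersion 0 + high depth: observed ratios converge on injected lfc
  expect_lt(median(abs(obs_lfc[1:20] - 1.5)), 0.1)
  expect_lt(median(abs(obs_lfc[21:100])), 0.1)
  expect_error(simulate_counts(10, design, lib_sizes = -1), "positive")
})
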