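# patseq

Poly(A) tail length and alternative polyadenylation (APA) analysis from
3'-anchored sequencing, in R.

## What problem this solves

3'-anchored poly(A)-tail sequencing protocols (PAT-Seq and relatives)
capture the last stretch of a transcript's 3'UTR together with its poly(A)
tail. From those reads — plus alignments of their templated portions, a
genome, and a polyadenylation-site (PAS) annotation — one can quantify, per
gene and condition:

* **poly(A) tail length** (with the non-templated adenosine rule separating
  true tail from genomic A-runs at the cleavage site),
* **PAS usage and APA events** (proximal/distal isoform switching, hence
  3'UTR length change), and
* the interplay of both with **mRNA abundance, translation (ribosome
  footprints), translational efficiency and miRNA expression**.

The package is aimed at transcriptomics researchers analysing 3'-end
sequencing of differentiation or perturbation experiments (bulk, two
conditions with replicates), and at methodologists who need a fully
simulatable test bed: a synthetic-data module generates genomes, gene
models, reads and count matrices with known ground truth, so every stage of
the pipeline is testable without external data.

## The statistics at the core

* **Tail calling.** An A-run is extended from the read's 3' end; a non-A
  base with Phred <= 10 is a wildcard, a higher-quality non-A consumes an
  error budget of 1 error per 5 bases of run; the run is trimmed to literal
  A at both ends. Genomic adenosines immediately downstream of the aligned
  3' end are subtracted as templated; a read is polyadenylated when >= 4
  non-templated A's remain. Genes need >= 10 poly(A) reads per sample for a
  mean tail estimate.
* **Differential tail length.** Depth-weighted moderated t per gene
  (weights = poly(A) read counts, variance shrinkage with prior df 4);
  significant at Benjamini-Hochberg FDR < 0.1 and |Δtail| > 10 A.
* **RED (relative expression difference)** for the top-2 PAS of a gene:

      RED = log2(dif_dist / ctrl_dist) - log2(dif_prox / ctrl_prox)

  A lengthening event needs RED > 1 *coupled with* a significant
  (FDR < 0.1) gain of the distal isoform and/or loss of the proximal one
  (per-site negative-binomial LRT with gene-total offsets); shortening
  mirrors this at RED < -1. 3'UTR length change is the usage-weighted mean
  over the two sites.
* **Expression testing.** CPM filtering (features must exceed the CPM
  equivalent of 5 raw counts in the smallest library), TMM normalisation,
  NB exact-style tests (FDR < 0.05, |log2FC| > 1), and a translational
  efficiency test as the assay x condition interaction of an NB GLM over
  matched mRNA/ribosome-footprint counts.
* **miRNA integration.** TargetScan-style target filtering (context++
  score <= -0.2), two-sample Kolmogorov-Smirnov shift tests of target sets
  vs background with Bonferroni correction, count-stratified shift tests,
  one-sided negative-correlation screening (BH FDR < 0.05), nested
  linear-model ANOVA, and a canonical seed-site scanner
  (8mer > 7mer-m8 > 7mer-A1 > 6mer) for sites gained by 3'UTR lengthening.

## Worked example

End to end on synthetic data — 20 genes, 3 vs 3 samples, a +18 A tail
shift and a 0.25 -> 0.75 distal-usage switch injected in the
"differentiated" condition:

```r
library(patseq)

sim <- simulate_genome(20, utr_len_range = c(400, 1200),
                       templated_a_prob = 0.3, seed = 7)
samples <- data.frame(
  sample_id    = c("ctl1","ctl2","ctl3","dif1","dif2","dif3"),
  condition    = rep(c("control","differentiated"), each = 3),
  tail_mean    = rep(c(44, 62), each = 3),
  tail_sd      = 15,
  distal_usage = rep(c(0.25, 0.75), each = 3),
  depth        = 40)
reads <- simulate_pat_reads(sim, samples, read_len = 250,
                            error_rate = 0.001, seed = 11)

calls  <- call_tails(reads$reads, sim$genome, sim$genes)
summ   <- summarize_gene_tails(calls)
design <- samples[, c("sample_id", "condition")]

global_tail_ks(summ, design)
tails <- diff_tail_length(summ, design)
summarize_tail_diff(tails)

pas_counts <- count_pas_reads(calls, sim$pas)
events <- apa_event_analysis(pas_counts, design, genes = sim$genes)
summarize_apa_events(events)
```

Output (abridged):

```
4800 reads, 99.9% polyadenylated
grand mean tails: control 44.13, differentiated 62.10 (KS D = 1.00, p = 1.5e-11)
differential tails: 20/20 genes significant, 100% lengthening, mean gain 18.0 A
APA: 10/10 analysed genes with events, 100% lengthening, median delta-3'UTR +182 nt
```

Reading this: the per-gene grand means recover the simulated tail means
(44 vs 62), every gene passes the FDR < 0.1 & |Δ| > 10 gate with the mean
fitted gain equal to the injected +18 residues, and every gene whose two
PAS survive the >= 2 normalised-counts filter (10 of 20 at this shallow
depth) is classified as a 3'UTR lengthening event, with the usage-weighted
3'UTR extension reported in nt.

A command-line interface wraps the same steps
(`inst/exec/patseq`; subcommands `simulate`, `call-tails`, `tail-diff`,
`de`, `apa`, `sites`).

## Documentation

See the methods vignette (`vignettes/patseq-methods.Rmd`) for the models,
parameter choices, simulator scope and known limitations.
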