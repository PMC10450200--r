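---
title: "patseq: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{patseq: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patseq)
```

# Scope

`patseq` analyses 3'-anchored poly(A)-tail sequencing of a two-condition,
replicated experiment: per-read tail calling, per-gene tail summaries and
differential tests, polyadenylation-site (PAS) counting and alternative
polyadenylation (APA) event classification via the relative expression
difference (RED) statistic, 3'UTR length-change quantification,
count-matrix differential expression / translational efficiency testing,
and miRNA-centred integrative analyses (target-set shifts, negative
correlations, seed-site census). A synthetic-data module generates every
input with known ground truth. This vignette records the models, the
parameters that matter, and the design decisions taken where reasonable
alternatives existed.

# Tail calling

## The A-run rule

Tails are called as an A-run anchored at the read's 3' end (for adapter
trimming, `call_tail()`) or at the aligned 3' end of the templated portion
(the pipeline path in `call_tails()`). Extension treats each base as:

* `A` — extends the run;
* non-A with Phred $\le$ `min_quality` (default 10) — a *wildcard*: a base
  too unreliable to veto the run, it extends without penalty;
* non-A with Phred $>$ `min_quality` — a budgeted error; the run stops
  when accepted errors would exceed `max_error_fraction` (default 1/5) of
  the current run length.

The run is finally trimmed so both ends are literal `A`. The wildcard
reading (low quality *permits*, rather than being *required for*,
extension) is a convention: the alternative reading — only high-quality
bases may extend — would make quality scores gatekeepers of A's rather
than of mismatches, which does not match how base-calling uncertainty
works. A consequence worth stating: raising `min_quality` converts errors
into wildcards and can only lengthen calls, so the monotonicity property
tested in the suite is non-decreasing in `min_quality`.

## Why the pipeline anchors the run at the alignment

The cumulative error budget is generous on long tails (a 50-A run buys 10
errors), so a leftward scan from the 3' end can absorb genomic bases
*before* the cleavage site and then re-extend over genomic adenosines,
overcounting the tail. In the pipeline the aligned 3' end of the trimmed
read bounds the run: the A-run is read off the sequence beyond the
alignment. With error-free input this makes tail recovery exact — which is
precisely what the acceptance suite demands — while the unanchored rule
remains available as the trimming operation used before alignment.

## Non-templated adenosines

Genomic A's immediately downstream of the aligned 3' end (strand-aware)
are subtracted from the called run; a read is *polyadenylated* when at
least `min_nontemplated` (default 4) non-templated A's remain. This is the
standard defence against internal priming / templated A-runs at cleavage
sites.

## Adapter trimming

`trim_adapter()` accepts matches with up to 10% mismatches and a 3'
overlap of at least 5 nt, and picks the *best-scoring* match
(score = overlap − 5 × mismatches; ties resolved toward the 3' end)
rather than the rightmost acceptable match. A pure rightmost rule lets a
spurious 5-nt suffix coincidence pre-empt a true full-length adapter hit,
which corrupts the downstream tail call; scoring is the convention used by
mainstream trimmers.

# Per-gene tail statistics

Genes need `min_reads` (default 10) polyadenylated reads in a sample for a
mean tail; fewer reads leave that cell missing. The differential test is a
weighted moderated t: per gene, weighted least squares of per-sample mean
tail on condition with weights proportional to read counts (the variance
of a mean scales as $1/n$), residual variances shrunk toward the
across-gene mean with a fixed prior df (default 4; small because per-gene
residual df in a 3 vs 3 design is 4 at most), and t-tests on the shrunken
variances. Genes must have defined means in at least 2 samples per group.
Significance requires FDR < 0.1 *and* |Δtail| > 10 A residues; the
effect-size gate dominates in practice and drives the false-positive rate
near zero under the null. This is a transparent reimplementation of the
depth-aware voom-style idea; numeric parity with limma is not claimed —
instead the suite asserts parameter recovery (power ≥ 0.8 and median
bias < 2 residues on injected +18 shifts at depth 100).

The global comparison (`global_tail_ks()`) is a two-sample KS test on
per-gene mean tails, reporting each condition's unweighted grand mean;
weighting genes by read count is a defensible alternative the package does
not take, because depth then leaks into a quantity meant to describe genes.

# Expression statistics

* `filter_low_counts()` keeps features whose CPM in *every* sample reaches
  the CPM equivalent of 5 raw counts in the smallest library.
* `tmm_normalize()` is the classic trimmed mean of M-values: reference =
  sample with upper quartile closest to the mean, 30%/5% two-sided trims
  on M/A, inverse-variance weights, factors rescaled to multiply to 1.
* `exact_de_test()` estimates a common dispersion by method of moments on
  within-group residuals, shrinks per-feature moment estimates toward it
  (prior weight 10), and tests depth-equalised group pseudo-sums with the
  NB conditional double-tail probability; totals above `exact_max_total`
  (default 10⁴) fall back to a fixed-dispersion likelihood-ratio test.
  Significance: FDR < 0.05 and |log2FC| > 1.
* `te_test()` fits, per feature, an NB log-linear model of combined
  mRNA + ribosome-footprint counts with assay, condition and their
  interaction plus log effective-library offsets; ΔTE is the interaction
  (log2) with an LRT p-value. In the dispersion→0, depth→∞ limit the
  interaction equals the footprint log2FC minus the mRNA log2FC, which the
  suite checks. Note that TMM's compositional assumption (most features
  unchanged) applies within each assay.

These reimplement the standard count-based toolchain *in spirit*;
correctness rests on calibration tests (null FDR within binomial error,
power > 0.9 on injected log2FC = 2), not on bit-parity with any package.
Dispersions are floored at 10⁻⁶ to avoid degenerate NB likelihoods.

# APA analysis

Reads are assigned to annotated PAS intervals extended by ±10 nt
(nearest-midpoint tie-break); sites need ≥ 2 normalised counts in every
sample (the strict reading of the support filter — a mean-based mode is
available because the aggregate reading is also defensible). Per gene the
top two sites by summed normalised counts are kept (ties prefer the distal
site, since lengthening is the biologically expected direction), ranked
proximal/distal along transcription, and tested with an NB LRT on site
counts offset by the per-sample gene total — so the tested quantity is
within-gene usage, not absolute expression. RED is computed on normalised
condition means with a 0.5 pseudocount guard. Classification couples
RED > 1 (< −1) with a significant per-site usage change in the consistent
direction; RED alone is never sufficient.

3'UTR length change is the usage-weighted mean length over the two sites
(length = transcription-direction distance from CDS end to site midpoint),
treated minus reference. The site-to-site distance is an alternative
definition; the usage-weighted form was chosen because it degrades
gracefully for partial switches and reduces to the inter-site distance for
a complete switch.

# miRNA integration and seed sites

Target pairs are filtered at context++ score ≤ −0.2 with an optional
miRNA exclusion list. Shift tests are two-sample KS of targets vs
non-targets per miRNA, Bonferroni-corrected within the batch of miRNAs
tested per metric (the family could also span metrics jointly; per-metric
batches are the default because each metric answers a separate question).
The correlation screen is Pearson with a one-sided p for negative
correlation — the direction canonical miRNA repression predicts — and BH
FDR across tested pairs. The nested-model ANOVA is the textbook
extra-sum-of-squares F test.

The seed scanner matches the reverse complement of miRNA bases 2–7 and
classifies each core locus by its flanks (m8 match one base 5', A
opposite position 1 one base 3'), with the strongest class winning
(8mer > 7mer-m8 > 7mer-A1 > 6mer) so counts partition loci. U and T are
equivalent. The gained-site census scans the sequence between proximal and
distal cleavage points of lengthening events against the UTR up to the
proximal site; 6mers are excluded from the default census because
prediction-based catalogues weight canonical 7–8mers. Conservation is an
input annotation (site- and miRNA-family-level flags), not computed from
alignments.

# The synthetic-data module

What it emulates:

* two-PAS gene models (proximal + distal in the 3'UTR) on alternating
  strands, one gene per contig;
* templated genomic A-runs of 4–12 nt immediately downstream of cleavage
  points in a configurable fraction of genes (default 0.3), with the
  cleavage base and the base past the run forced non-A so planted run
  lengths are exact;
* per-read integer tails from a truncated normal (the field reports means
  and SDs; the true distribution shape of tail data is unknown, so the
  truncated normal is a stand-in, not a claim);
* proximal/distal choice per read from the condition's distal-usage
  fraction;
* reads as genomic anchor (default 50 nt) + A-run + adapter, truncated to
  `read_len`; adapter remnants shorter than the 5-nt minimum match overlap
  are dropped, as upstream quality/length trimming would do;
* a two-level Phred model (high for correct bases, low for substitution
  errors at `error_rate`) — the simplest model that exercises the quality
  rule;
* negative-binomial count matrices with log-normal baselines and injected
  log2 fold changes (`dispersion = 0` degrades to Poisson).

Deliberate simplifications: per-gene read depth is deterministic (exactly
`depth` reads), not Poisson — stated scales like "2000 reads" are then
exact and conservation invariants byte-stable; no intron structure, PCR
duplicates, or realistic sequencer error profiles; coordinates are 0-based
half-open internally, with GFF3 emitted 1-based closed and BED 0-based
half-open. Each sample draws from its own RNG stream keyed by
`(seed, sample_id)`, so adding samples never perturbs existing ones.

A green test on this simulator therefore establishes that the
implementation recovers what it injects under the stated noise model — it
does not establish performance on real libraries, where tail-length
distributions are skewed, cleavage is heterogeneous around annotated
sites, and error profiles are structured.

# Numerical and testing notes

* KS calibration is checked with *exact* two-sample p-values on co-prime
  group sizes (71 vs 89): with equal sizes or the asymptotic
  approximation, the discreteness/bias of the two-sample KS p-value makes
  a uniformity meta-test reject for reasons unrelated to this package.
* The NB exact test enumerates the conditional distribution only for
  pseudo-totals ≤ 10⁴; beyond that the LRT is used.
* RED throws on non-positive inputs; callers apply the 0.5 pseudocount.
* Degenerate contingency tables (zero margins) are errors, not silent
  zeros; expected cells < 1 raise a warning.
* Zero-variance series in the correlation screen and collinear covariates
  in the nested ANOVA are skipped/flagged, not forced.

# Known limitations

* Isoform-level (per-PAS) tail testing is out of scope; tails are
  summarised at gene level by the mean only.
* The caller consumes alignments; it does not align reads itself.
* The DE/TE machinery targets the simple two-group replicated design; no
  batch covariates or quasi-likelihood tests.
* Published headline counts from real libraries depend on external
  annotations and deposited data; the package reproduces their
  *bookkeeping* (ratio reports) and the method's behaviour on simulated
  truth, which is what the acceptance suite checks.
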