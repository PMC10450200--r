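Package: patseq
Title: Poly(A) Tail Length and Alternative Polyadenylation Analysis from
    3'-Anchored Sequencing
Version: 0.2.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying mRNA poly(A) tail length and alternative
    polyadenylation (APA) from 3'-anchored poly(A)-tail sequencing reads.
    Calls per-read tail lengths with a quality-aware A-run rule and a
    non-templated adenosine test against the genome, summarises tails per
    gene, tests differential tail length with depth-weighted moderated
    statistics, counts reads at annotated polyadenylation sites, scores APA
    events with the relative expression difference (RED) statistic and
    classifies 3'UTR lengthening and shortening, quantifies 3'UTR length
    change, and integrates miRNA expression with target-set shift tests,
    negative-correlation screening and seed-site (6mer/7mer/8mer) scanning
    of gained 3'UTR sequence. A synthetic-data module generates genomes,
    gene models, reads with known tails, and negative-binomial count
    matrices with injected effects so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    MASS
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    Rsamtools,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
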