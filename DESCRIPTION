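Package: strainpan
Title: Pangenome Novelty Scoring and Annotation Reconciliation for
    Yeast Strain Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing gene content across panels of
    Saccharomyces genome assemblies. Implements a translated-homology
    Novelty Metric that scores, for each query gene, how much stronger
    its best six-frame hit is in a given strain than in the reference
    genome, normalized by the best hit across the panel; reconciles two
    gene-annotation tracks into a single coding/pseudogene call set with
    automatic open-reading-frame correction; validates predicted genes
    against transcriptome alignments, FPKM expression levels, and
    peptide identifications, including a log-space Fisher exact test for
    association between annotation status and validation; and locates
    genes relative to chromosome ends, detects missing genes,
    nonsyntenic homologs and gene clusters, computes N50, and orders and
    orients contigs along a related reference genome. A synthetic-data
    generator plants strain panels with known gene content so every
    stage can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
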