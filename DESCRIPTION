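Package: hgtscreen
Title: Detection and Evolutionary Validation of Host-to-Parasite
    Horizontal Gene Transfer from Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a transcriptome screen for horizontally
    transferred genes in parasitic plants and the downstream
    evolutionary validation of candidates. The screen combines read
    quality trimming, host-contamination removal via life-stage read
    evidence, ORF prediction and length gates, and a taxon-partitioned
    homology score ratio (alien index) with a sister-taxon exclusion
    filter. Validation tools cover pairwise and multiple-alignment
    diagnostics (group-specific residues and indels), spliced
    alignment of cDNA onto genomic sequence for intron-position
    comparison, neighbor-joining trees with bootstrap clade support,
    type-I functional divergence (theta1) between duplicate clades,
    GY94 codon substitution models (M0, M3, M1a/M2a, M7/M8 and
    branch-site model A) with likelihood-ratio tests and empirical
    Bayes site posteriors, and expression analysis (FPKM, qPCR
    reference-gene stability and the comparative Ct method). A
    simulation module generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Phylogenetics, Transcriptomics, Alignment, GeneExpression
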