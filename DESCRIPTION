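Package: introscan
Title: Congenic Locus Mapping and Candidate Gene Nomination from
    Strain-Specific Coding SNPs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps introgressed donor chromosomal segments in congenic
    rodent strains from RNA-Seq-derived coding SNPs and nominates
    candidate genes. Classifies variant sites by strain of origin via
    set comparison of quality-filtered per-strain variant calls, bins
    informative sites along chromosomes, delimits donor-origin
    segments, and compares segment sizes with the 100/N centimorgan
    flanking expectation for N marker-selected backcrosses. A minimal
    negative-binomial differential-expression stage (median-of-ratios
    normalization, exact conditional test, Benjamini-Hochberg
    correction), a coding-consequence annotator (CDS position, codon
    and amino-acid change, SIFT-score classification), and a
    cross-referencing step assemble the candidate-gene report. A
    synthetic-data module simulates parental genomes, marker-assisted
    backcross breeding, RNA-Seq variant observation, and
    negative-binomial count matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
biocViews: Genetics, SNP, Transcriptomics, DifferentialExpression,
    Sequencing, Annotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
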