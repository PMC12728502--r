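Package: supergeneR
Title: Supergene Genotyping and Candidate-Gene Inference from Multi-Sample VCFs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies ant samples into supergene genotype classes (M/M, M/P,
    P/P and haploid M or P) from a multi-sample VCF using per-sample inbreeding
    coefficients and trans-species haplotype-specific SNPs, delimits the
    non-recombining supergene region by windowed heterozygosity, scores genes
    for haplotype-specific alleles retained in obligately polygynous species,
    detects collapsed duplications from normalized read depth and haploid
    pseudo-heterozygosity, classifies coding variant effects, and contrasts
    mutation load between supergene genotype groups. Includes a synthetic
    cohort generator with planted ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
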