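Package: seaselect
Title: Seascape Genomics of Putative Local Adaptation from SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consensus detection of putatively adaptive single nucleotide
    polymorphisms (SNPs) from genotype and environmental data, in the style of
    seascape genomic studies of marine invertebrates. Implements collinearity
    pruning of environmental predictors, redundancy-analysis loading outliers,
    a latent-factor genotype-environment association scan with genomic
    inflation correction, a permutation FST-outlier scan, and their two-of-three
    consensus; population diversity and structure statistics (observed and
    unbiased expected heterozygosity, nucleotide diversity over SNP loci, FIS,
    Weir-Cockerham theta, hierarchical AMOVA with Phi statistics); open reading
    frame (ORF) based classification of transcript SNPs into synonymous,
    non-synonymous, nonsense and outside-CDS classes with kN/kS count ratios;
    and an iterative one-tailed Wilcoxon enrichment test asking whether
    non-synonymous SNPs dominate the top of per-axis ordination contribution
    ranks. A synthetic-data module simulates Balding-Nichols population
    structure, environmental gradients, and annotated transcriptomes with
    planted ground truth so the whole pipeline is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
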