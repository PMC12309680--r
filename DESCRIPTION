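Package: tempogen
Title: Temporal Population Genomics of Two Interbreeding Ecotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for century-scale temporal
    population genomics of a pair of partially diverged, interbreeding
    ecotypes (a migratory and a coastal population). Provides a forward
    Wright-Fisher simulator of two ecotypes with inversion supergenes,
    time-varying gene flow and karyotype-dependent selection; VCF input
    and output with genotype-level site filters, LD pruning, and
    inversion-region exclusion; genotype PCA and three-cluster inversion
    karyotype calling validated by heterozygosity; temporal
    allele-frequency-shift estimation (Fs, Fs') with jackknife
    confidence intervals and effective-population-size inference;
    windowed Weir-Cockerham FST and allele-frequency-difference scans
    with permutation p-values and per-chromosome FDR; windowed Tajima's
    D and nucleotide diversity with inside-versus-outside-inversion
    contrasts; genotype-frequency trajectory tests (Hardy-Weinberg
    chi-square, Fisher exact with compact letter display,
    Kruskal-Wallis/Dunn); and supervised per-individual ancestry
    estimation aggregated by birth-year cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
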