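Package: rumentype
Title: Rumen Enterotype Discovery, Microbiome Association and Host-Genetic
    Analysis for Livestock Cohorts
Version: 0.1.0
Authors@R:
    person("rumentype", "developers", email = "rumentype@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for enterotype analysis of rumen (and other
    gut) microbiome cohorts. Discovers enterotypes from genus-level abundance
    tables (Jensen-Shannon / Bray-Curtis distances, partitioning around
    medoids, Calinski-Harabasz model selection, random-forest driver-genus
    ranking), associates enterotypes with performance phenotypes and rearing
    covariates, screens genera with two-part Beta / zero-inflated Beta
    regression, contrasts enterotype-stratified partial-correlation
    co-occurrence networks, and layers on host genetics: SNP QC, LD pruning,
    the genomic relationship matrix, REML heritability with the
    observed-to-liability transform, Haseman-Elston genetic correlation,
    binary-trait GWAS, and Bayesian colocalization via approximate Bayes
    factors. A synthetic-data module generates Dirichlet-multinomial
    communities, HWE genotypes with LD blocks, liability-threshold binary
    phenotypes and enterotype-shifted performance traits so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    igraph,
    jsonlite,
    MASS,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    SummarizedExperiment,
    utils,
    VariantAnnotation
LinkingTo: Rcpp
Suggests:
    ape,
    cluster,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
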