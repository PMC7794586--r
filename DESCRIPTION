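Package: crediblemap
Title: Trans-Ancestral GWAS Fine-Mapping with Approximate Bayes Factors and Credible Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for nominating causal variants at a disease-associated
    locus across ancestrally diverse case-control cohorts. Implements genotype and
    sample quality control (per-group minor allele frequency, call rate, imputation
    info score, method-of-moments pi-hat relatedness), additive-model logistic
    association scans with admixture covariates, stepwise conditional analysis,
    Wakefield approximate Bayes factors with posterior probabilities and minimal
    95 percent credible sets, cross-ancestry credible-set intersection,
    sample-size-weighted Z-score meta-analysis with allele alignment, cis/trans
    eQTL linear-model scans, and defined bench statistics (interferon signature
    scores, T7 endonuclease I editing efficiency, qPCR fold enrichment, allelic
    read imbalance). A seeded synthetic-data generator produces every input the
    pipeline consumes: haplotype panels with tunable linkage disequilibrium,
    case-control cohorts with a planted causal variant, genotype-additive
    expression, and negative-control/treated expression panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
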