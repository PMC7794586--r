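# crediblemap

Trans-ancestral GWAS fine-mapping to Bayesian credible sets, with the full
statistical chain around it: quality control, covariate-adjusted logistic
association scans, stepwise conditional analysis, sample-size-weighted
meta-analysis, cis/trans eQTL scans, and the bench statistics used to follow
up a nominated variant (interferon signature scores, T7 endonuclease I
editing efficiency, qPCR fold enrichment, allelic read imbalance). A seeded
synthetic-data generator produces every input the pipeline consumes, so the
whole chain is exercisable — and testable — without access to cohort data.

The package is written for statistical geneticists who want a compact,
auditable reimplementation of the classic "GWAS locus to causal variant"
workflow: the kind of analysis that nominates a single regulatory variant at
an autoimmune risk locus by intersecting 95% credible sets across ancestral
cohorts.

## The model at the core

For each variant in a region, association evidence from an additive logistic
model (log-odds `β̂`, standard error `se`) is converted to a Wakefield
approximate Bayes factor against the null, with a Gaussian effect prior
`N(0, W)`:

```
log BF = ½ log( V / (V + W) ) + (z²/2) · W / (V + W),   V = se², z = β̂/se
```

Under the assumptions that any variant in the region could be causal and
exactly one is, the posterior probability of variant *i* is its Bayes-factor
share of the region:

```
PP_i = BF_i / Σ_j BF_j
```

and the 95% credible set is the minimum number of variants, ranked by PP,
whose cumulative posterior probability reaches 0.95. A variant common to
every ancestry's credible set is the natural trans-ancestral causal
candidate. When only p-values are available (e.g. after meta-analysis), `z`
is recovered from the p-value and `V` approximated as `1/(2·N·f·(1−f))` for
allele frequency `f`.

Per-study evidence is combined with the sample-size weighting scheme
(`Z = Σ wᵢzᵢ / √Σ wᵢ²`, `wᵢ = √Nᵢ`) after aligning each study's effect
allele to a common reference.

## Worked example

Simulate one ancestral cohort with a planted causal variant (per-allele
OR 1.35, the middle of the odds-ratio range typical of common autoimmune
risk alleles), run QC and the admixture-adjusted scan, and fine-map:

```r
library(crediblemap)

spec   <- ancestry_spec("EU", n_variants = 30, alt_freqs = 0.3, ld_rho = 0.6,
                        n_cases = 1500, n_controls = 1500)
panel  <- simulate_haplotype_panel(spec, n_hap = 4000, seed = 42)
cohort <- simulate_case_control(panel, causal_index = 15,
                                or_per_allele = 1.35, seed = 43)

qc   <- filter_variants(cohort$genotypes)
scan <- logistic_scan(qc$genotypes, cohort$status, cohort$admixture)
scan
#> assoc_scan: 30 variants, 3 covariates
#>   top hit: v15000  beta=0.2911 se=0.0561 p=2.07e-07 (n=2945)

finemap(scan, prior_w = 0.04, level = 0.95)
#> finemap: 30 variants, prior W=0.04
#> 95% credible set: 1 variant(s), cumulative PP 0.9997
#>   v15000  PP=0.9997
```

The scan's top hit is the planted variant (`β̂ = 0.29 ≈ ln 1.35`), and with
this much signal the 95% credible set collapses to the causal variant alone.

The full four-ancestry replay — simulate, QC, scan, fine-map per ancestry,
intersect credible sets, meta-analyse, fine-map the meta-analysis — is one
call:

```r
report <- run_pipeline(run_config(seed = 11))
report
#> run_report (seed 11 )
#>   EU: credible set of 20 variant(s), cum PP 0.954
#>   AA: credible set of 28 variant(s), cum PP 0.957
#>   AS: credible set of 26 variant(s), cum PP 0.960
#>   AI: credible set of 28 variant(s), cum PP 0.962
#>   shared credible variants: v15000, v08000, ...
#>   meta top hit: v15000 Z=4.63 p=3.62e-06
```

At the default desk-scale cohort sizes (500 cases / 500 controls per
ancestry) each single-ancestry credible set is wide, but the causal variant
`v15000` leads the shared set and the trans-ancestral meta-analysis — the
behaviour the method is designed to expose.

Bench statistics work on plain tables:

```r
panel <- simulate_ifn_panel(n_nc = 20, n_treated = 20,
                            treated_shift = c(-2, -2, -1, -1), seed = 7)
ifn_score(panel)           # per-sample IFN scores; NC group mean is 0
t7_efficiency(1, 1, 1)     # 42.26% editing at equal band intensities
fold_enrichment(25, 28, mode = "ct")  # 2^3 = 8-fold
allelic_imbalance(10, 0)   # exact binomial p = 0.00195
```

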