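---
title: "Methods: trans-ancestral fine-mapping with approximate Bayes factors"
author: "crediblemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trans-ancestral fine-mapping with approximate Bayes factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crediblemap)
```

This vignette documents the statistical models the package implements, the
assumptions behind them, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the field leaves them open.

## 1. The association model

Case-control status is modelled per variant by additive-model logistic
regression,

$$\mathrm{logit}\,P(\mathrm{case}) = \alpha + \beta g + \gamma' c,$$

where $g \in \{0,1,2\}$ counts alternate alleles and $c$ holds covariates —
in the intended application, three admixture proportions that absorb
population stratification within each ancestral cohort. $\beta$ is the
per-allele log odds ratio for the alternate allele as coded in the VCF; the
sign convention is fixed by that coding and carried through every downstream
table via explicit A1/A2 columns.

Fitting is maximum likelihood via binomial IRLS (`stats::glm.fit`, deviance
tolerance $10^{-10}$, 50 iterations). Each variant is fit on the samples
with a non-missing genotype at that variant (complete-case per variant, no
mean imputation, matching standard GWAS-toolkit behaviour). Wald $z =
\hat\beta/\widehat{se}$ and two-sided normal p-values are reported; no
genomic control is applied. Three failure modes are flagged rather than
reported as numbers: non-convergence, separation (detected as
$|\hat\beta| > 15$ or a non-converged IRLS path; no Firth correction is
applied, keeping the estimand identical to the standard scan), and aliasing
against conditioning covariates. Flagged records carry `CONVERGED = FALSE`
and `P = NA`.

**Conditional analysis.** `conditional_stepwise()` counts independent
signals: the top variant (lowest p; ties broken by lowest genomic position —
a choice this package makes, since equally significant ties have no
canonical order) is added as a covariate and the region re-scanned, repeating
while any variant stays below `p_stop` ($10^{-4}$ by default). Variants in
the residual window $10^{-4} < p < 10^{-2}$ are recorded at each step, the
window conventionally reported as residual evidence. Conditioning genotypes
are mean-filled at their few missing entries so that the per-variant
complete-case sample is preserved; the focal genotype is never imputed.

**eQTL scans.** `eqtl_scan()` fits the same additive model by OLS with
expression as the response, on the samples shared between the genotype and
expression matrices, reporting slope, Student-t statistic and two-sided
p-value, with optional conditioning genotypes. The default reporting
threshold $10^{-4}$ is the conventional genome-wide screen for a focal
variant against all transcripts.

## 2. Bayesian fine-mapping

Evidence per variant is the Wakefield approximate Bayes factor. With
sampling variance $V = se^2$ and a Gaussian effect prior $N(0, W)$,

$$\log \mathrm{BF} = \tfrac12 \log\frac{V}{V+W} +
  \frac{z^2}{2}\cdot\frac{W}{V+W}.$$

The prior variance defaults to $W = 0.04$ (prior SD 0.2 on the log-odds
scale), the de facto standard for binary traits: it says a priori that
per-allele odds ratios beyond $e^{\pm 0.4} \approx 1.5$ are unusual.
Published analyses of this design computed Bayes factors with genotype-level
software whose priors are not printed; the Wakefield form with a documented,
configurable $W$ is this package's choice, and posterior probabilities are
only approximately invariant to $W$ — sensitivity can be checked by passing
other values.

Under the single-causal-variant assumption (made explicit: any variant could
be causal, exactly one is), posterior probabilities are Bayes-factor shares,
$PP_i = BF_i / \sum_j BF_j$, computed by log-sum-exp so that regions of
thousands of variants with very large BFs normalise to 1 within $10^{-12}$.
The 95% credible set accumulates variants by descending PP until the sum
reaches the level; it is minimal by construction, and PP ties are taken in
input order (any choice among tied variants yields the same size and
cumulative PP). `shared_credible_variants()` intersects per-ancestry sets
and orders the survivors by mean PP.

When only p-values are available — the meta-analysis route — $z$ is
recovered via the normal quantile (evaluated from $\log p$ so that
$p < 10^{-300}$ never yields an infinite $z$) and $V$ approximated by
$1/(2 N f (1-f))$; the trans-ancestral credible set is built from the
meta-analysis p-values this way, mirroring how replication-cohort credible
sets are computed from summary statistics.

## 3. Meta-analysis

`weighted_z_meta()` implements the sample-size weighting scheme only:
$z_i = \Phi^{-1}(1-p_i/2)\,\mathrm{sign}(\beta_i)$ per study after allele
alignment, combined as $Z = \sum_i \sqrt{N_i}\, z_i / \sqrt{\sum_i N_i}$.
No heterogeneity statistics and no inverse-variance scheme are provided.
Alleles are aligned by testing identity, swap, strand complement, and
strand-complemented swap; palindromic A/T and C/G variants cannot be
strand-resolved without frequency information and are excluded by default
(`keep_ambiguous = TRUE` assumes same-strand reporting). A study supplying
p-values with no direction column is rejected: the signed scheme is
undefined without directions.

## 4. Quality control

The filters and their defaults follow standard case-control practice:

| filter | rule | default |
|---|---|---|
| variant MAF | remove if MAF < threshold in **any** ancestral group | 0.01 |
| variant call rate | remove if overall call rate < threshold | 0.90 |
| sample call rate | remove if sample call rate < threshold | 0.95 |
| relatedness | remove lower-call-rate member of pairs with $\hat\pi$ > threshold | 0.40 |
| imputation info | remove imputed variants with $r^2$ < threshold | 0.80 |

All comparisons are strict (`<`), so values sitting exactly at a threshold
survive. Order matters and is fixed: variant filters, then sample call rate,
then relatedness, because the sample filters are defined over variants that
pass the variant filters. One direction deserves a note: descriptions of the
sample filter are sometimes printed as excluding samples with genotyping
rates *above* 95%, which would discard the best-genotyped samples; the
conventional direction (exclude below) is implemented and the threshold is
configurable.

$\hat\pi$ is the method-of-moments IBD estimate
$P(\mathrm{IBD}{=}1)/2 + P(\mathrm{IBD}{=}2)$ from observed IBS class
counts. The expected class probabilities use unbiased factorial-moment
estimators of the allele-frequency monomials (e.g. $\widehat{p^2q^2} =
a(a{-}1)b(b{-}1)/x^{(4)}$ for $a$ alternate and $b$ reference alleles among
$x$), the small-sample correction standard toolkits apply — without it the
estimator is visibly biased upward for unrelated pairs when frequencies come
from small cohorts. The three moment components are solved unclipped and
only then clamped to the simplex and renormalised; clamping mid-solution
breaks the anticorrelation between components and biases $\hat\pi$ upward at
the zero boundary. Estimates from fewer than 50 overlapping variants are
flagged unreliable, and reference frequencies can be supplied when the
cohort itself is too small to estimate them. Relatedness pruning is greedy
over pairs by descending $\hat\pi$, removing the lower-call-rate member, so
a trio of mutual duplicates loses exactly two members. Note that $\hat\pi$
is a genome-wide quantity: the pipeline's default configuration disables
relatedness pruning because a single fine-mapping region (tens of variants)
cannot estimate IBD, and enabling it there would prune on noise.

## 5. The synthetic-data generator

The generator produces inputs with exactly the statistical structure the
estimators assume, which is what makes parameter-recovery testing
meaningful — and bounds what the tests show.

**Haplotypes.** Each haplotype is a thresholded latent AR(1) Gaussian:
$z_j = \rho z_{j-1} + \sqrt{1-\rho^2}\,\epsilon_j$, with the alternate
allele called where $z_j > \Phi^{-1}(1-f_j)$. Marginal allele frequencies
hit the spec exactly (in expectation) and adjacent-site allelic correlation
rises with `ld_rho`, producing the multi-variant shadow associations that
fine-mapping must resolve. This is deliberately not a coalescent model: no
recombination hotspots, no allele-frequency/LD coupling, no demographic
history. Passing tests therefore demonstrate correctness of the estimators
under a clean LD structure, not robustness to the full complexity of real
haplotypes.

**Disease.** Individuals are random haplotype pairs; status is drawn from
the logistic model $\mathrm{logit}\,P = \mathrm{logit}(p_0) +
\ln(\mathrm{OR})\,g_{\mathrm{causal}} + \gamma'a$, and sampling continues
until the case and control quotas are met. Because the generative model is
logistic (not liability-threshold), the simulated per-allele OR is exactly
the logistic-regression estimand — recovery tests are testing the estimator,
not a model approximation. Admixture proportions are Dirichlet(1,1,1,1) with
the first three components retained, mirroring the convention of using three
of four admixture estimates as covariates. The default planted effect is
OR 1.35, the midpoint of the 1.18–1.51 range typical of replicated common
autoimmune risk alleles; baseline prevalence defaults to 0.1 and genotypes
are masked missing completely at random at rate 0.02 (typical array-QC
scale). Control:case ratios per cohort are 1:1 by default — an assumption,
since real cohort compositions vary; both quotas are configurable.

**Expression.** The eQTL generator adds $\beta g$ to Gaussian noise for one
target gene and leaves the remaining genes pure noise; the IFN panel draws
negative-control samples $N(\mu_g, \sigma_g^2)$ per signature gene and
shifts treated samples by a specified vector. Real normalised expression has
heavier tails and gene-gene correlation; none of that is emulated.

**Determinism.** Every generator takes one integer seed and draws all its
randomness from a single generator stream per call; identical configuration
and seed give bit-identical output, and the pipeline derives per-ancestry
seeds from the master seed by fixed offsets.

## 6. Bench statistics

**IFN score.** For each signature gene (IFI27, IFIT3, OAS1, LY6E by
default), expression is standardised against the negative-control group —
subtract the NC mean, divide by the NC SD — and the four standardised values
are summed per sample. The NC group's mean score is 0 by construction, which
the acceptance checks verify to $10^{-9}$. The SD uses the sample ($n-1$)
convention by default; the population convention is available
(`sd_type = "population"`) since published descriptions rarely state it, and
all four genes are standardised identically (descriptions sometimes walk
through only three; the gene list is configurable).

**T7EI editing efficiency.** From substrate band $a$ and cleavage products
$b, c$, the cleaved fraction is $f = (b+c)/(a+b+c)$ and efficiency is
$(1-\sqrt{1-f}) \times 100$ — the square root accounts for re-annealed
homoduplexes escaping cleavage. Printed renderings of this formula sometimes
drop the inner parentheses, a literal reading of which leaves $f$ outside
$[0,1]$; the cleaved-fraction reading is the standard one and is the
implementation here, with the boundary checks ($f \in [0,1]$, efficiency in
$[0,100]$) that the literal reading violates. Samples above 40% efficiency
are flagged usable, the conventional cutoff before downstream expression
analysis.

**Fold enrichment** is the target/control signal ratio (ChIP target antibody
vs IgG; FAIRE vs input), or $E^{\Delta Ct}$ in Ct mode with amplification
efficiency $E = 2$ by default; the two modes agree on signals $E^{-Ct}$.
**Allelic imbalance** is the exact two-sided binomial test at null 0.5,
two-sided by the minimum-likelihood rule (the p-value sums the probabilities
of all outcomes no more likely than the observed one) — this quantifies
ref/alt read skew at a heterozygous site without any alignment-bias
modelling.

## 7. Numerical choices and problem sizes

- All Bayes-factor arithmetic is in natural-log space; normalisation uses
  log-sum-exp; p-to-z conversion accepts log p-values.
- IRLS separation flag at $|\hat\beta| > 15$ (odds ratios beyond $e^{15}$
  have no finite-sample meaning here).
- Degenerate inputs fail loudly: monomorphic variants, all-missing samples,
  zero NC SDs (named gene), empty regions, irreconcilable alleles.
- The test suite's Monte-Carlo sizes — 50 replicates for odds-ratio
  recovery at 2000/2000, 200 single-causal regions at 1000/1000 for
  credible-set coverage, 100 replicates for scan ranking, 20 simulated
  pairs at 25{,}000 markers for the $\hat\pi$ oracle — were chosen as the
  smallest sizes at which the checked properties are statistically stable;
  the pipeline default of four cohorts of 500/500 over 30 variants keeps
  the end-to-end replay at desk scale.

## 8. Known limitations

- Single-causal fine-mapping only: no stochastic search over causal
  configurations, no LD-matrix-based multi-causal methods, no
  colocalisation.
- The sample-size meta-analysis scheme only; no inverse-variance weights,
  no random effects, no heterogeneity statistics.
- No HWE tests, sex checks, or heterozygosity outlier detection in QC.
- The generator's LD model is a single AR(1) parameter per region; it
  cannot represent block boundaries or long-range LD.
- Admixture and principal components are treated as supplied covariates;
  their estimation is out of scope.
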