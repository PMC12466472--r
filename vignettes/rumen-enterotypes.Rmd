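---
title: "Enterotype discovery and host-genetic analysis with rumentype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enterotype discovery and host-genetic analysis with rumentype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumentype)
```

# Scope and model

`rumentype` implements the full analysis chain used in large livestock
rumen-microbiome cohorts: unsupervised discovery of *enterotypes*
(community types) from a genus-level abundance table, association of the
enterotype with performance phenotypes and rearing covariates, genus-level
differential-abundance screening with a two-part Beta model,
enterotype-stratified co-occurrence network comparison, and a host-genetics
layer (genomic relationship matrix, heritability of the binary enterotype on
the liability scale, genetic correlations, GWAS, colocalization). A
synthetic-data module generates cohorts with the exact statistical structure
each stage assumes, so the whole chain is testable offline.

## Enterotype discovery

Samples are compared with the square root of the Jensen–Shannon divergence
(natural logarithms), the metric used by the canonical enterotyping
literature; Bray–Curtis is available via `distance_kind = "bray"`.
Partitioning around medoids (BUILD + SWAP, fully deterministic with ties
broken toward the lowest sample index) is run for each candidate $k$, and
the Calinski–Harabasz index
$$\mathrm{CH}(k) = \frac{B/(k-1)}{W/(n-k)}$$
is evaluated on a classical-scaling (PCoA) embedding restricted to
positive-eigenvalue axes, because CH is a Euclidean statistic and sqrt-JSD
matrices are near- but not exactly Euclidean. `k_opt` is the CH argmax;
clusters are relabelled by decreasing size so "enterotype 1" is always the
larger group.

*Parameters that matter.* `pseudocount` (default `1e-9` of each profile's
mass) keeps the KL terms finite; its value is irrelevant at double precision
as long as it is far below the smallest observed relative abundance.
`k_range` defaults to 2–10. Driver genera are ranked with a random-forest
classifier (enterotype ~ genus relative abundances) under repeated 10-fold
cross-validation; importance is the Breiman permutation importance
(per-tree accuracy drop on held-out data). Whole-forest permutation
importance is *not* used: with compositional predictors most genera carry
redundant signal and forest-level accuracy never drops when one column is
permuted, which collapses all importances to zero. Cross-validation repeats
default to 99: importance means stabilize well below the 999 sometimes
used, and the full 999 is a flag away.

## Community analysis

Alpha diversity (observed, Shannon, Simpson, inverse Simpson, Pielou,
bias-corrected Chao1 $S + F_1(F_1-1)/(2(F_2+1))$, ACE with rare cutoff 10,
Fisher's $\alpha$ solved by Newton with bisection fallback, tolerance
1e-10), Bray–Curtis distances, classical PCoA and a marginal PERMANOVA
(single factor per model, 999 permutations by default,
$p = (1 + \#\{F_\pi \ge F\})/(1 + n_\pi)$) are computed from first
principles and are cross-checked in the test suite against vegan and ape.
The bias-corrected Chao1 form avoids division by zero when no doubletons
exist. Rarefaction to a common depth (`rarefy_counts`, minimum library size
by default) is an explicit pipeline step rather than a hidden default
inside the diversity functions: the caller decides whether diversity is
computed on rarefied or raw counts, and the recommended workflow rarefies
first.

## Enterotype–phenotype association

Each trait is fit by OLS as
$$y_i = \beta_0 + \beta_1\,\mathrm{Enterotype}_i +
\beta_2\,\mathrm{Birthplace}_i + \varepsilon_i,$$
with a t-test on $\beta_1$ and Benjamini–Hochberg adjustment across traits
(never pooled across test families). Birthplace is the only default
covariate — mirroring the phenotype model of the cohort design this package
targets — and further covariates can be supplied. Derived traits follow the
standard feedlot formulas (ADG, ADFI, FCR, MBW $=[0.5(BW_{80}+BW_{180})]
^{0.75}$, BMI, dressing percentage, relative fat weights on both carcass
and live-weight denominators); residual feed intake is the residual of ADFI
on MBW and ADG. Covariate diagnostics include Pearson chi-square tests
(without Yates correction by default; both variants agree to the printed
precision on the worked contingency example in the test suite), pairwise
level comparisons with BH adjustment, per-covariate logistic models, a
Spearman correlation matrix of integer-coded covariates, and the condition
index of the column-scaled dummy design (annotated at the conventional 10 /
30 thresholds, filtering nothing).

## Two-part genus screening

Genus relative abundances are zero-inflated; the package routes each genus
by prevalence (fraction of samples with nonzero abundance, threshold 0.60,
equality to the Beta branch since the routing rule is stated as strict
inequalities on both sides):

* **Beta branch** (prevalence ≥ 0.60): maximum likelihood under
  $y \sim \mathrm{Beta}(\mu\phi, (1-\mu)\phi)$ with
  $\mathrm{logit}(\mu) = \beta_0 + \beta_1\mathrm{Enterotype} +
  \beta_2\mathrm{Birthplace}$, after the Smithson–Verkuilen shrinkage
  $y' = (y(n-1)+0.5)/n$.
* **ZIBR branch** (prevalence < 0.60): a point mass at zero with
  $\mathrm{logit}(\nu) = \gamma_0 + \gamma_1\mathrm{Enterotype} +
  \gamma_2\mathrm{Birthplace}$ plus the same Beta density for positives.
  The mixture likelihood factorizes over the zero indicator and the
  positive part, so the joint MLE is computed exactly as a logistic fit
  plus a Beta fit; the reported log-likelihood is the mixture
  log-likelihood and is verified against a hand-written evaluation in the
  tests.

Optimization is BFGS with analytic gradients on the unconstrained scale
($\log\phi$), moment-based starts and up to 5 jittered restarts; SEs come
from the numerically observed information. Both the zero-model and
mean-model enterotype tests enter one BH family; a genus is called at the
minimum of its adjusted p-values — whether the original analysis tested
$\gamma_1$, $\beta_1$ or both is not stated, so both are reported and the
combined call is documented here. Significance is reported at both raw
p < 0.05 and FDR ≤ 0.05, since cohort analyses of this design report both.

## Co-occurrence networks

Within each enterotype stratum, genera present in ≥ 50% of samples with
mean relative abundance > 0.001 are retained; Spearman partial correlations
(conditioning on *all* other retained genera, via inversion of the
rank-correlation matrix, Moore–Penrose pseudo-inverse on singular input)
are tested with the t approximation at $df = n - g$ and BH-filtered at
q ≤ 0.05. Topology (transitivity, mean shortest path on the largest
connected component — the input may be disconnected and the convention is
documented rather than implicit — normalized betweenness, degrees) uses
igraph. Edges significant in exactly one stratum are *specialists*; edges
in both are *generalists* partitioned into `direction_change` (sign flip,
taking precedence), `strength_change` (same sign,
$|r_{E1} - r_{E2}| > 0.2$ on signed values; the
$||r_{E1}|-|r_{E2}||$ reading is available by flag) and `stable`. The three
classes provably partition the generalist set, a structural identity the
acceptance tests exercise on random networks.

## Host genetics

SNP QC keeps biallelic sites with MAF ≥ 0.05 and missingness < 0.3
(mean depth > 3 when a depth matrix exists); LD pruning is the
indep-pairwise 50/10/0.1 sliding-window rule. The GRM is
$$g_{jk} = \frac1m \sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}
{2p_i(1-p_i)},$$
identically $ZZ^{\mathsf T}/m$ for standardized dosages (the denominator is
the standard HWE variance; the tests verify the identity by brute force).
Heritability of the binary enterotype uses single-component REML: after
rotation by the GRM eigenvectors the restricted likelihood is profiled over
$h^2 \in [0, 0.999]$ by bounded 1-D optimization; the SE is from the
numerical observed information and the LRT against $h^2 = 0$ uses the
boundary ½χ²(1) mixture. The liability transform is
$$h^2_l = h^2_{obs}\,\frac{K(1-K)}{z^2}\,\frac{K(1-K)}{P(1-P)},$$
with $K$ the population prevalence, $P$ the sample case fraction
(defaulting to $K$ when no external prevalence is known) and $z$ the normal
density at the threshold; at $K=P=1/2$ the multiplier is exactly $\pi/2$,
and the tests also confirm the multiplier against a direct Monte-Carlo
liability simulation. Genetic correlations use Haseman–Elston regression
(cross-products of standardized traits on GRM off-diagonals) with a
20-block jackknife SE — a desk-scale, moment-based stand-in for bivariate
REML that is unbiased under the model. GWAS of the binary trait is logistic
regression with covariates (birthplace, season, first five GRM
eigenvectors in the full design): the score test is primary because it is
well defined under separation, per-SNP Wald log-odds are optional, genomic
inflation is $\lambda = \mathrm{median}(\chi^2)/0.4549$, and Bonferroni
thresholds are $0.05/N$ and $1/N$ for $N$ independent (pruned) SNPs. SNP
effects on the microbiota route genera at the same 0.60 prevalence cut:
clr-transformed abundance in a linear model above it, presence/absence
logistic below it, with a 1.5% prevalence floor for testability.

## Colocalization

For two sets of summary statistics over a shared SNP panel, per-SNP
Wakefield log approximate Bayes factors
$\tfrac12[\log(1-s) + s z^2]$, $s = W/(V+W)$, are combined under the
single-causal-variant enumeration into posterior probabilities of H0–H4
with priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ (the canonical
defaults; the source analysis does not state its priors). Prior effect SDs
default to 0.15 on the log-odds scale for the binary enterotype trait and
0.2 for quantitative clr traits. A shared variant is called when
PP.H4 > 0.50. Overlap (upper-tail hypergeometric) and cross-signal LD
(pairwise $r^2$ of dosages) accompany the Bayesian analysis.

# The synthetic cohort: what it does and does not emulate

`sim_config()` states the world once; generators are deterministic given
the seed.

* **Community**: a geometric rank-abundance baseline over genera; each
  cluster multiplies its driver genera by `driver_fold` (default 10) and
  renormalizes; per-sample compositions are Dirichlet with concentration 50
  (moderate overdispersion) and counts multinomial at a log-uniform library
  size in 5,000–20,000, exercising rarefaction.
* **Genotypes**: HWE dosages at per-block allele frequencies uniform in
  `maf_range`; LD blocks are copula-style (SNPs copy a shared latent
  haplotype with a per-SNP flip probability) — sufficient for pruning and
  LD statistics, orders of magnitude faster than coalescent simulation, but
  *not* a realistic recombination landscape.
* **Enterotype phenotype**: a liability-threshold trait; the genetic score
  from designated causal SNPs is rescaled to variance $h^2$ exactly and the
  residual has variance $1-h^2$, making the observed-to-liability transform
  checkable against the generating truth. Default prevalence 553/1150 and
  $h^2_l = 0.43$ match the cohort scale the package models.
* **Performance traits**: mean + enterotype shift + birthplace effect +
  Gaussian noise, with birthplace sampling probabilities tilted by cluster
  so the covariate is genuinely confounded. Default shifts are the printed
  group contrasts of the modelled cohort (e.g. BW180 45.64 → 46.90 kg);
  residual SDs (2.5 / 3.5 kg, 12 kg intake, 4 cm) are realistic feedlot
  magnitudes chosen once, since dispersions are not printed.

A green test on this world establishes *statistical correctness of the
machinery* (calibration, recovery, invariances) — not that any particular
real cohort will reproduce specific published point estimates: real data
carry batch structure, phylogenetic correlation, family relatedness and
sequencing artifacts the generator deliberately omits.

# Numerical choices

* PAM requires a strictly positive objective improvement (relative
  tolerance 1e-10) per SWAP; without it, tie-heavy distance matrices cause
  cycling.
* `optimize()` never probes the boundary exactly, so REML reports
  $h^2 = 0$ whenever the profiled likelihood at 0 is at least the interior
  optimum.
* Beta likelihood evaluation uses `log1p` for the $1-y$ terms; fits flag
  non-convergence (non-finite SEs) and non-converged genera are excluded
  from the FDR family rather than contributing unstable p-values.
* The CH embedding drops negative-eigenvalue axes; CH is invariant to
  a global rescaling of the distance matrix, which the tests assert.
* BH adjustment is applied within families only (traits; genus tests;
  network pairs; genus × SNP tests).

# Known limitations

* The GWAS is plain logistic regression with PC covariates, not a mixed
  model: with strong cryptic relatedness it will inflate, and `lambda` is
  reported precisely so users can see this.
* Haseman–Elston genetic correlations have larger sampling variance than
  bivariate REML at the same n.
* The ZIBR branch has no random effects (no longitudinal support).
* Partial correlations condition on all retained genera; when the retained
  set approaches the sample count the pseudo-inverse path is a warning, not
  a remedy — interpret such networks cautiously.
* NMDS, UniFrac distances, LEfSe, model-based (Dirichlet-multinomial
  mixture) clustering and fine-mapping-based colocalization are out of
  scope by design.
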