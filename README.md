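# rumentype

Enterotype analysis for livestock gut/rumen microbiome cohorts, with the
host-genetics layer needed to ask whether community types are heritable and
which variants drive them.

Large rumen 16S cohorts cluster into a small number of *enterotypes* —
community types such as a *Prevotella*-dominated type versus a mixed type —
that track economically important traits (growth, feed efficiency, fat
deposition). Analysing such a cohort takes a long chain of methods that are
usually scattered across half a dozen tools. `rumentype` packages the whole
chain as tested R functions:

* **Enterotype discovery** — square-root Jensen–Shannon distance,
  partitioning around medoids (PAM), Calinski–Harabasz selection of the
  cluster number `k_opt = argmax_k [B/(k−1)]/[W/(n−k)]`, and driver-genus
  ranking by cross-validated random-forest permutation importance
  (compiled in Rcpp).
* **Community ecology** — rarefaction, alpha diversity (Shannon, Simpson,
  InvSimpson, Pielou, Chao1, ACE, Fisher's α), Bray–Curtis, PCoA, marginal
  PERMANOVA with permutation p-values.
* **Phenotype association** — derived feedlot traits (ADG, ADFI, FCR,
  MBW = [0.5(BW80+BW180)]^0.75, BMI, RFI), per-trait OLS
  `y = β0 + β1·Enterotype + β2·Birthplace + ε` with BH-FDR, chi-square /
  logistic / collinearity covariate diagnostics.
* **Two-part genus screening** — Beta regression with logit mean link for
  prevalent genera (≥ 60%), zero-inflated Beta regression (ZIBR) below
  that, maximum likelihood with analytic gradients.
* **Co-occurrence networks** — Spearman partial correlations per
  enterotype, BH edge filtering, igraph topology, and the
  specialist/generalist + direction/strength/stable edge taxonomy.
* **Host genetics** — SNP QC, indep-pairwise LD pruning, the GRM
  `g_jk = (1/m) Σ (x_ij−2p_i)(x_ik−2p_i)/(2p_i(1−p_i))`, REML heritability
  of the binary enterotype with the liability transform
  `h²_l = h²_obs · K(1−K)/z² · K(1−K)/(P(1−P))`, Haseman–Elston genetic
  correlations, logistic-score GWAS with genomic inflation λ and Bonferroni
  thresholds, and SNP→microbiota effect models (clr / presence-absence).
* **Colocalization** — hypergeometric overlap, cross-signal LD, and
  Wakefield approximate-Bayes-factor colocalization (PP.H0–PP.H4).
* **Synthetic cohorts** — a generator for Dirichlet-multinomial
  communities with planted driver genera, HWE genotypes with LD blocks,
  liability-threshold binary enterotypes and enterotype-shifted performance
  traits, so every stage is testable without any external data.

See `vignettes/rumen-enterotypes.Rmd` for the models, assumptions and
numerical choices.

## Worked example

Simulate a 300-animal cohort in which a heritable liability decides the
enterotype, the community composition follows the enterotype, and
performance traits are shifted by it — then run the pipeline:

```r
library(rumentype)

cfg <- sim_config(n_samples = 300, n_genera = 60, n_snps = 1000,
                  h2_liability = 0.4, seed = 2024,
                  causal_snps = setNames(rep(1, 20),
                                         paste0("snp", seq(25, 1000, 50))))
G   <- gen_genotypes(cfg)
lia <- gen_enterotype_liability(G, cfg)
ab  <- gen_abundance_table(cfg, assignments = lia$phenotype + 1L)
ph  <- gen_performance_phenotypes(lia$phenotype + 1L, cfg)

model <- fit_enterotypes(ab$table)
model
#> enterotype_model (jsd distance): k_opt = 2, sizes = 152/148
#> CH curve:
#>      2      3      4      5      6      7      8      9     10
#> 545.69 280.33 191.56 145.72 118.22 100.52  86.99  77.37  70.10
```

The CH curve peaks sharply at k = 2: the planted two-community structure is
recovered (152/148 animals per enterotype).

```r
enterotype_trait_assoc(ph[c("BW80", "BW180", "feed_intake")],
                       model$assignments[ph$sample_id], ph$birthplace)
#>         trait        term estimate    se statistic        p        q
#> 1        BW80 enterotype2     1.07 0.285      3.75 2.11e-04 0.000254
#> 2       BW180 enterotype2     1.84 0.411      4.47 1.13e-05 0.000034
#> 3 feed_intake enterotype2     5.54 1.496      3.70 2.54e-04 0.000254
```

All three generated shifts (1.31 / 1.26 kg body weight, 5 kg feed intake)
are detected after BH adjustment, with estimates near the planted values.

```r
grm <- compute_grm(qc_filter_variants(G))
h2  <- reml_h2_observed(lia$phenotype, grm)
lb  <- observed_to_liability(h2$h2_observed, K = mean(lia$phenotype),
                             se_obs = h2$se_observed)
#> h2 observed = 0.20 (SE 0.16); liability scale = 0.31 (SE 0.25); LRT p = 0.1
```

At n = 300 the heritability estimate is noisy (the generating liability
h² is 0.40, inside one SE) — binary-trait GREML needs the cohort sizes the
acceptance suite uses (n = 800+) for tight estimates.

A command-line front end for the main stages ships in
`inst/cli/rumentype-cli.R`
(`Rscript rumentype-cli.R enterotype fit --input abundance.tsv --out run1`).

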