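test_that("variant QC applies MAF / missingness / biallelic rules", {
  dos <- cbind(ok = c(0, 1, 2, 1, 0, 1, 2, 1, 0, 1),
               lowmaf = c(rep(0, 9), 1),              # MAF 0.05 -> retained
               rarer = c(rep(0, 10)),                 # monomorphic
               holey = c(rep(NA, 4), 1, 0, 1, 2, 0, 1)) # 40% missing
  G <- genotype_matrix(dos)
  q <- qc_filter_variants(G)
  expect_setequal(q$snp_ids, c("ok", "lowmaf"))
  expect_error(qc_filter_variants(genotype_matrix(dos[, "rarer", drop = FALSE])),
               "all SNPs removed")

  # multiallelic VCF records are dropped by the reader
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S1", "S2"), collapse = "\t"),
               paste(c("1", "100", "bi", "A", "G", ".", "PASS", ".", "GT",
                       "0/1", "1/1"), collapse = "\t"),
               paste(c("1", "200", "multi", "A", "G,T", ".", "PASS", ".", "GT",
                       "0/1", "1/2"), collapse = "\t")), vcf)
  G2 <- read_genotype_vcf(vcf)
  expect_equal(G2$snp_ids, "bi")
})

test_that("LD pruning removes duplicates, keeps independent SNPs", {
  set.seed(50)
  n <- 300
  base <- matrix(rbinom(n * 20, 2, 0.3), n, 20)
  dos <- cbind(base, dup = base[, 3])
  colnames(dos) <- c(paste0("s", 1:20), "dup")
  G <- genotype_matrix(dos)
  kept <- ld_prune(G)
  expect_equal(length(setdiff(c("s3", "dup"), kept)), 1) # one of the pair pruned
  # near-independent SNPs survive almost entirely
  G2 <- genotype_matrix(base)
  expect_gt(length(ld_prune(G2)) / 20, 0.8)
  # sample order does not matter
  ord <- sample(n)
  G3 <- genotype_matrix(dos[ord, ])
  expect_setequal(ld_prune(G3), kept)
})

test_that("GRM matches the standardized-dosage identity and worked value", {
  # p = 0.5, individual with x = 2: diagonal (2-1)^2 / (2*0.5*0.5) = 2
  G1 <- genotype_matrix(matrix(c(2, 0), 2, 1,
                               dimnames = list(c("a", "b"), "s")))
  g <- compute_grm(G1)
  expect_equal(unname(diag(g$matrix)), c(2, 2))
  expect_equal(g$matrix["a", "b"], -2)

  # brute-force double loop on a small instance
  set.seed(51)
  dos <- matrix(rbinom(8 * 5, 2, 0.4), 8, 5)
  dos[dos == 2][1] <- 2 # keep polymorphic as drawn
  G2 <- genotype_matrix(dos)
  grm <- compute_grm(G2)$matrix
  p <- colMeans(dos) / 2
  brute <- matrix(0, 8, 8)
  for (j in 1:8) for (k in 1:8) {
    s <- 0
    for (i in 1:5) s <- s + (dos[j, i] - 2 * p[i]) * (dos[k, i] - 2 * p[i]) /
        (2 * p[i] * (1 - p[i]))
    brute[j, k] <- s / 5
  }
  expect_equal(unname(grm), brute, tolerance = 1e-12)

  # HWE simulation: mean diagonal ~ 1, mean off-diagonal ~ 0
  cfg <- sim_config(n_samples = 500, n_snps = 5000, seed = 52)
  Gs <- gen_genotypes(cfg)
  A <- compute_grm(Gs)$matrix
  expect_lt(abs(mean(diag(A)) - 1), 0.05)
  expect_lt(abs(mean(A[upper.tri(A)])), 0.01)
})

test_that("REML heritability: null behaviour, shift invariance, monotone LRT", {
  cfg <- sim_config(n_samples = 300, n_snps = 800, h2_liability = 0, seed = 53)
  G <- gen_genotypes(cfg)
  grm <- compute_grm(G)
  y <- rnorm(300)
  fit0 <- reml_h2_observed(y, grm)
  expect_lt(fit0$h2_observed, 0.25)
  expect_gte(fit0$loglik, fit0$loglik0)
  # invariance to adding a constant to the phenotype
  fit1 <- reml_h2_observed(y + 100, grm)
  expect_equal(fit1$h2_observed, fit0$h2_observed, tolerance = 1e-6)

  # quantitative recovery: y = g + e with h2 = 0.5 at n = 500
  set.seed(54)
  cfg2 <- sim_config(n_samples = 500, n_snps = 2000, seed = 55)
  G2 <- gen_genotypes(cfg2)
  Z <- scale(G2$dosage)
  gval <- drop(Z %*% rnorm(2000)) ; gval <- gval / sd(gval) * sqrt(0.5)
  y2 <- gval + rnorm(500, 0, sqrt(0.5))
  fit2 <- reml_h2_observed(y2, compute_grm(G2))
  expect_lt(abs(fit2$h2_observed - 0.5), 2 * fit2$se_observed)
  expect_lt(fit2$lrt_p, 0.05)
})

test_that("liability transform matches closed forms", {
  expect_equal(observed_to_liability(0.3, 0.5)$multiplier, pi / 2,
               tolerance = 1e-12)
  res <- observed_to_liability(0.27, 553 / 1150)
  expect_equal(res$h2_liability, 0.4244698, tolerance = 1e-6)
  expect_equal(observed_to_liability(0, 0.3)$h2_liability, 0)
  # linear in h2_obs
  expect_equal(observed_to_liability(0.54, 553 / 1150)$h2_liability,
               2 * res$h2_liability, tolerance = 1e-12)
  expect_error(observed_to_liability(0.3, 0), "0, 1")

  # multiplier agrees with a Monte-Carlo liability simulation within 1%
  set.seed(56)
  K <- 0.3; h2l <- 0.4; n <- 4e5
  g <- rnorm(n, 0, sqrt(h2l))
  lia <- g + rnorm(n, 0, sqrt(1 - h2l))
  yb <- as.numeric(lia > qnorm(1 - K))
  h2_obs_mc <- (cov(g, yb) / var(g))^2 * var(g) / var(yb)
  mult_mc <- h2l / h2_obs_mc
  expect_equal(observed_to_liability(1, K)$multiplier, mult_mc,
               tolerance = 0.015)
})

test_that("Haseman-Elston genetic correlation hits the trivial poles", {
  cfg <- sim_config(n_samples = 400, n_snps = 1000, seed = 57)
  G <- gen_genotypes(cfg)
  grm <- compute_grm(G)
  Z <- scale(G$dosage)
  set.seed(58)
  gval <- drop(Z %*% rnorm(1000)); gval <- gval / sd(gval) * sqrt(0.6)
  y <- gval + rnorm(400, 0, sqrt(0.4))
  same <- genetic_correlation(y, y, grm)
  expect_equal(same$rG, 1, tolerance = 1e-10)
  neg <- genetic_correlation(y, -y, grm)
  expect_equal(neg$rG, -1, tolerance = 1e-10)
  # genetically independent traits: |rG| small relative to its SE
  g2 <- drop(Z %*% rnorm(1000)); g2 <- g2 / sd(g2) * sqrt(0.6)
  y2 <- g2 + rnorm(400, 0, sqrt(0.4))
  indep <- genetic_correlation(y, y2, grm)
  expect_lt(abs(indep$rG), 3 * indep$se)
})

test_that("binary GWAS: calibration, power at a causal SNP, permutation null", {
  cfg <- sim_config(n_samples = 800, n_snps = 2000, h2_liability = 0.6,
                    seed = 59,
                    causal_snps = stats::setNames(1, "snp1000"))
  G <- gen_genotypes(cfg)
  lia <- gen_enterotype_liability(G, cfg)
  gw <- gwas_binary_trait(lia$phenotype, G, wald = FALSE)
  expect_lt(abs(gw$lambda - 1), 0.2)   # single causal SNP barely inflates
  expect_lt(gw$table$p[gw$table$snp == "snp1000"],
            gw$thresholds$suggestive)
  # permuting the phenotype destroys the association signal
  set.seed(60)
  gwp <- gwas_binary_trait(sample(lia$phenotype), G, wald = FALSE)
  expect_gt(min(gwp$table$p, na.rm = TRUE), 0.05 / (20 * 2000))
  # Wald betas agree with glm at a spot-checked SNP
  gww <- gwas_binary_trait(lia$phenotype,
                           genotype_matrix(G$dosage[, 990:1010]), wald = TRUE)
  ref <- glm(lia$phenotype ~ G$dosage[, "snp1000"], family = binomial())
  i <- which(gww$table$snp == "snp1000")
  expect_equal(gww$table$beta[i], unname(coef(ref)[2]), tolerance = 1e-6)
})

test_that("significance thresholds reproduce printed and identity values", {
  th <- significance_thresholds(1608328)
  expect_equal(th$genome_wide_2sf, 3.1e-8)
  expect_equal(th$suggestive_2sf, 6.2e-7)
  th20 <- significance_thresholds(20)
  expect_equal(th20$genome_wide, 2.5e-3)
  expect_equal(th20$suggestive, 5.0e-2)
  expect_equal(th$genome_wide, th$suggestive * 0.05)
  expect_error(significance_thresholds(0), "> 0")
})

test_that("clr transform satisfies its algebraic identities", {
  set.seed(61)
  m <- matrix(rpois(6 * 10, 20) + 1, 6, 10)
  tab <- abundance_table(m)
  clr <- clr_transform(tab)
  expect_true(all(abs(rowSums(clr)) < 1e-10))
  # uniform composition -> all zeros
  u <- clr_transform(abundance_table(matrix(5, 2, 4)))
  expect_true(all(abs(u) < 1e-12))
  # scale invariance per sample
  m2 <- m; m2[1, ] <- m2[1, ] * 7
  expect_equal(clr_transform(abundance_table(m2))[1, ], clr[1, ],
               tolerance = 1e-12)
  expect_error(clr_transform(abundance_table(rbind(m, 0))), "all-zero")
})

test_that("snp-microbiota effects route by prevalence and find planted hits", {
  set.seed(62)
  n <- 500
  g <- rbinom(n, 2, 0.4)
  rel <- matrix(rgamma(n * 6, 5), n, 6)
  colnames(rel) <- paste0("g", 1:6)
  rel[, 1] <- rel[, 1] * exp(0.4 * g)           # planted clr effect
  rel[sample(n, 495), 5] <- 0                   # 1% prevalence -> excluded
  rel[sample(n, 300), 6] <- 0                   # 40% -> presence/absence
  counts <- round(rel / rowSums(rel) * 2e4)
  tab <- abundance_table(counts)
  snps <- matrix(g, n, 1, dimnames = list(NULL, "rs1"))
  res <- snp_microbiota_effects(snps, tab)
  expect_false("g5" %in% res$genus)
  expect_equal(res$model[res$genus == "g6"], "presence_logistic")
  expect_equal(res$model[res$genus == "g1"], "clr_linear")
  expect_true(res$significant[res$genus == "g1"])
})
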