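#' Simulation configuration
#'
#' The stated world of the synthetic cohort: a two-enterotype
#' Dirichlet-multinomial genus community with designated driver genera,
#' HWE genotypes with optional LD blocks, a liability-threshold binary
#' enterotype phenotype, and enterotype-shifted performance traits with
#' birthplace confounding. Defaults follow the cohort the package models:
#' two clusters, 10x driver enrichment, Dirichlet concentration 50, library
#' sizes 5,000-20,000, prevalence 553/1150, liability heritability 0.43.
#'
#' @param n_samples,n_genera,n_snps cohort dimensions.
#' @param k_true number of planted communities.
#' @param driver_ids list (length `k_true`) of genus indices enriched in
#'   each cluster; sets must be disjoint.
#' @param driver_fold enrichment factor of a driver in its own cluster.
#' @param dirichlet_concentration Dirichlet precision per cluster (recycled).
#' @param library_size_range integer pair; sizes are drawn log-uniform.
#' @param maf_range minor-allele-frequency range in (0, 0.5].
#' @param ld_block_size SNPs per LD block (1 = independent SNPs).
#' @param ld_flip_prob per-SNP probability of flipping the block's latent
#'   allele (sets within-block LD strength).
#' @param h2_liability heritability of the enterotype liability in \[0, 1\].
#' @param prevalence case (enterotype 2) fraction, strictly inside (0, 1).
#' @param causal_snps named numeric vector: SNP ids -> liability effects.
#'   Default: 5 causal SNPs of equal weight spread over the panel.
#' @param trait_effects named list of per-trait settings
#'   (`list(mean, shift, sd, birthplace_sd)`); see
#'   [gen_performance_phenotypes()]. Defaults emulate the feedlot traits
#'   the package targets (BW80, BW180, total feed intake, body length).
#' @param n_birthplaces birthplace levels for the confounded covariate.
#' @param seed master RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200L, n_genera = 50L, n_snps = 500L,
                       k_true = 2L,
                       driver_ids = NULL, driver_fold = 10,
                       dirichlet_concentration = 50,
                       library_size_range = c(5000L, 20000L),
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 1L, ld_flip_prob = 0.05,
                       h2_liability = 0.43, prevalence = 553 / 1150,
                       causal_snps = NULL,
                       trait_effects = NULL,
                       n_birthplaces = 5L,
                       seed = 1L) {
  if (is.null(driver_ids)) {
    per <- 3L
    driver_ids <- lapply(seq_len(k_true), function(k)
      ((k - 1L) * per + 1L):(k * per))
  }
  if (length(Reduce(intersect, driver_ids)) > 0 && k_true > 1)
    stop("driver sets must be disjoint across clusters")
  if (anyDuplicated(unlist(driver_ids))) stop("driver sets must be disjoint")
  if (h2_liability < 0 || h2_liability > 1) stop("h2_liability must be in [0, 1]")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be inside (0, 1)")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) stop("maf_range must be in (0, 0.5]")
  if (library_size_range[1] < 1 || diff(library_size_range) < 0)
    stop("invalid library_size_range")
  if (is.null(causal_snps)) {
    idx <- unique(pmax(1L, round(seq(1, n_snps, length.out = 5))))
    causal_snps <- stats::setNames(rep(1, length(idx)), paste0("snp", idx))
  }
  if (is.null(trait_effects)) {
    trait_effects <- list(
      BW80 = list(mean = 18.47, shift = 1.31, sd = 2.5, birthplace_sd = 1.0),
      BW180 = list(mean = 45.64, shift = 1.26, sd = 3.5, birthplace_sd = 1.5),
      feed_intake = list(mean = 158, shift = 5, sd = 12, birthplace_sd = 4),
      body_length = list(mean = 0.80, shift = 0.01, sd = 0.04,
                         birthplace_sd = 0.01))
  }
  cfg <- list(n_samples = as.integer(n_samples),
              n_genera = as.integer(n_genera), n_snps = as.integer(n_snps),
              k_true = as.integer(k_true), driver_ids = driver_ids,
              driver_fold = driver_fold,
              dirichlet_concentration =
                rep_len(dirichlet_concentration, k_true),
              library_size_range = as.integer(library_size_range),
              maf_range = maf_range,
              ld_block_size = as.integer(ld_block_size),
              ld_flip_prob = ld_flip_prob,
              h2_liability = h2_liability, prevalence = prevalence,
              causal_snps = causal_snps, trait_effects = trait_effects,
              n_birthplaces = as.integer(n_birthplaces),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Simulate a Dirichlet-multinomial genus table
#'
#' Each sample's composition is drawn from a Dirichlet whose base depends
#' on the sample's cluster: a shared geometric rank-abundance baseline with
#' the cluster's driver genera multiplied by `driver_fold` and
#' renormalized. Counts are multinomial at a log-uniform library size.
#'
#' @param cfg a [sim_config()].
#' @param assignments optional integer cluster labels (1..k_true) per
#'   sample; default i.i.d. uniform.
#' @return list: `table` (an [abundance_table()]) and `truth` (list with
#'   `assignments`, `base_composition` per cluster).
#' @export
gen_abundance_table <- function(cfg, assignments = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples; p <- cfg$n_genera
  if (is.null(assignments)) {
    assignments <- sample.int(cfg$k_true, n, replace = TRUE)
  }
  base <- 0.9^(seq_len(p) - 1)          # geometric rank-abundance baseline
  comp <- lapply(seq_len(cfg$k_true), function(k) {
    b <- base
    b[cfg$driver_ids[[k]]] <- b[cfg$driver_ids[[k]]] * cfg$driver_fold
    b / sum(b)
  })
  lsr <- log(cfg$library_size_range)
  libsize <- round(exp(stats::runif(n, lsr[1], lsr[2])))
  counts <- matrix(0L, n, p,
                   dimnames = list(paste0("S", seq_len(n)),
                                   paste0("g", seq_len(p))))
  for (i in seq_len(n)) {
    k <- assignments[i]
    pi <- rdirichlet_one(cfg$dirichlet_concentration[k] * comp[[k]])
    counts[i, ] <- stats::rmultinom(1, libsize[i], pi)
  }
  names(assignments) <- rownames(counts)
  list(table = abundance_table(counts),
       truth = list(assignments = assignments, base_composition = comp))
}

#' Simulate HWE genotypes with block LD
#'
#' SNPs are grouped into blocks of `ld_block_size`. Each block draws a
#' latent haplotype pair at a block-level allele frequency (uniform in
#' `maf_range`); each SNP copies the latent alleles, flipping each with
#' probability `ld_flip_prob` (block-copula LD, orders faster than a
#' coalescent and sufficient for pruning / LD tests). With block size 1
#' SNPs are independent HWE draws.
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()] (block ids in the `block` attribute).
#' @export
gen_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_samples; m <- cfg$n_snps; bs <- cfg$ld_block_size
  block <- rep(seq_len(ceiling(m / bs)), each = bs)[seq_len(m)]
  dos <- matrix(0L, n, m,
                dimnames = list(paste0("S", seq_len(n)),
                                paste0("snp", seq_len(m))))
  for (b in unique(block)) {
    snps <- which(block == b)
    f <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
    h1 <- stats::rbinom(n, 1, f)
    h2 <- stats::rbinom(n, 1, f)
    for (j in snps) {
      flip1 <- stats::rbinom(n, 1, cfg$ld_flip_prob)
      flip2 <- stats::rbinom(n, 1, cfg$ld_flip_prob)
      dos[, j] <- as.integer(abs(h1 - flip1) + abs(h2 - flip2))
    }
  }
  G <- genotype_matrix(dos, chrom = rep("1", m), pos = seq_len(m) * 1000L)
  attr(G, "block") <- block
  G
}

#' Simulate a liability-threshold binary enterotype
#'
#' The genetic score is built from standardized dosages of the causal SNPs,
#' rescaled to variance `h2_liability`; the residual is normal with
#' variance `1 - h2_liability`, so the generating truth is directly
#' checkable against the observed-to-liability transform. The binary trait
#' is `liability > qnorm(1 - prevalence)`.
#'
#' @param G a [genotype_matrix()] containing the causal SNPs.
#' @param cfg a [sim_config()].
#' @return list: `phenotype` (0/1 per sample, 1 = enterotype 2 / case),
#'   `truth` (list with `liability`, `genetic_score`, `threshold`,
#'   `causal_effects`).
#' @export
gen_enterotype_liability <- function(G, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  miss <- setdiff(names(cfg$causal_snps), G$snp_ids)
  if (length(miss)) stop("causal SNPs absent from genotypes: ",
                         paste(miss, collapse = ", "))
  set.seed(cfg$seed + 2L)
  n <- nrow(G$dosage)
  h2 <- cfg$h2_liability
  if (h2 > 0) {
    Z <- scale(G$dosage[, names(cfg$causal_snps), drop = FALSE])
    score <- drop(Z %*% cfg$causal_snps)
    score <- score / stats::sd(score) * sqrt(h2)
  } else {
    score <- rep(0, n)
  }
  liability <- score + stats::rnorm(n, 0, sqrt(1 - h2))
  thr <- stats::qnorm(1 - cfg$prevalence)
  pheno <- as.integer(liability > thr)
  names(pheno) <- G$sample_ids
  list(phenotype = pheno,
       truth = list(liability = liability, genetic_score = score,
                    threshold = thr, causal_effects = cfg$causal_snps))
}

#' Simulate enterotype-shifted performance phenotypes
#'
#' Each trait is `mean + shift * (cluster - 1) + birthplace effect +
#' N(0, sd)`; birthplace levels are assigned with cluster-dependent
#' probabilities so the covariate is genuinely confounded with enterotype,
#' and level effects are drawn `N(0, birthplace_sd)`. The raw fields needed
#' by [derive_performance_traits()] (BW80, BW180, feed intake, body
#' length) are included by the default `trait_effects`.
#'
#' @param assignments integer cluster labels (1..k) per sample.
#' @param cfg a [sim_config()].
#' @param covariates optional data.frame with a `birthplace` factor;
#'   generated when `NULL`.
#' @return data.frame: sample_id, birthplace, one column per trait.
#' @export
gen_performance_phenotypes <- function(assignments, cfg, covariates = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  n <- length(assignments)
  if (is.null(covariates)) {
    # mild confounding: birthplace probabilities tilted by cluster
    probs <- matrix(1, max(assignments), cfg$n_birthplaces)
    for (k in seq_len(nrow(probs)))
      probs[k, ] <- probs[k, ] + 0.5 * ((seq_len(cfg$n_birthplaces) + k) %% 2)
    bp <- vapply(assignments, function(k)
      sample.int(cfg$n_birthplaces, 1, prob = probs[k, ]), integer(1))
    covariates <- data.frame(birthplace = factor(paste0("B", bp)))
  }
  out <- data.frame(sample_id = if (!is.null(names(assignments)))
    names(assignments) else paste0("S", seq_len(n)),
    covariates, stringsAsFactors = FALSE)
  for (tr in names(cfg$trait_effects)) {
    te <- cfg$trait_effects[[tr]]
    bp_eff <- stats::rnorm(nlevels(out$birthplace), 0, te$birthplace_sd)
    out[[tr]] <- te$mean + te$shift * (assignments - 1) +
      bp_eff[as.integer(out$birthplace)] + stats::rnorm(n, 0, te$sd)
  }
  out
}

#' Write a complete fixture set
#'
#' Runs the full generative chain (genotypes -> liability -> enterotype
#' assignment -> abundance table -> phenotypes) and writes: abundance TSV,
#' phenotype TSV, genotype VCF and a JSON truth sidecar. Files round-trip
#' losslessly through the package readers.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisible list of file paths plus the in-memory objects.
#' @export
write_fixture_set <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  G <- gen_genotypes(cfg)
  lia <- gen_enterotype_liability(G, cfg)
  assignments <- lia$phenotype + 1L          # 1 = control cluster, 2 = case
  ab <- gen_abundance_table(cfg, assignments = assignments)
  ph <- gen_performance_phenotypes(assignments, cfg)
  paths <- list(abundance = file.path(dir, "abundance.tsv"),
                phenotypes = file.path(dir, "phenotypes.tsv"),
                genotypes = file.path(dir, "genotypes.vcf"),
                truth = file.path(dir, "truth.json"))
  write_abundance_tsv(ab$table, paths$abundance)
  utils::write.table(cbind(ph, enterotype = assignments), paths$phenotypes,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_genotype_vcf(G, paths$genotypes)
  jsonlite::write_json(
    list(seed = cfg$seed,
         assignments = as.list(stats::setNames(as.integer(assignments),
                                               G$sample_ids)),
         causal_snps = as.list(cfg$causal_snps),
         threshold = lia$truth$threshold,
         prevalence = cfg$prevalence,
         h2_liability = cfg$h2_liability),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, table = ab$table, genotypes = G,
                 phenotypes = ph, liability = lia,
                 assignments = assignments))
}
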