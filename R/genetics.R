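#' Genotype matrix container
#'
#' @param dosage samples x SNPs matrix of 0/1/2 dosages (`NA` = missing).
#' @param chrom,pos per-SNP chromosome and position (defaults supplied).
#' @return `genotype_matrix`: list with `dosage`, `sample_ids`, `snp_ids`,
#'   `chrom`, `pos`.
#' @export
genotype_matrix <- function(dosage, chrom = NULL, pos = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage))) rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage))) colnames(dosage) <- paste0("snp", seq_len(ncol(dosage)))
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0/1/2 or NA")
  if (is.null(chrom)) chrom <- rep("1", ncol(dosage))
  if (is.null(pos)) pos <- seq_len(ncol(dosage))
  structure(list(dosage = dosage, sample_ids = rownames(dosage),
                 snp_ids = colnames(dosage),
                 chrom = as.character(chrom), pos = as.integer(pos)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Read genotypes from a VCF file
#'
#' GT-based biallelic dosages (count of ALT alleles). Multi-allelic records
#' are dropped (the biallelic-only part of the QC contract); missing
#' genotypes (`./.`) become `NA`.
#'
#' @param path VCF v4.x file (plain text or bgzipped).
#' @return a [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  alt_n <- S4Vectors::elementNROWS(VariantAnnotation::alt(v))
  v <- v[alt_n == 1L]
  gt <- VariantAnnotation::geno(v)$GT
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  dos[gt %in% c("1/1", "1|1")] <- 2
  rr <- SummarizedExperiment::rowRanges(v)
  genotype_matrix(t(dos),
                  chrom = as.character(GenomicRanges::seqnames(rr)),
                  pos = GenomicRanges::start(rr))
}

#' Write genotypes to a VCF v4.2 file
#'
#' Minimal GT-only records (REF=A, ALT=G placeholders for simulated data).
#'
#' @param G a [genotype_matrix()].
#' @param path output file.
#' @export
write_genotype_vcf <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=rumentype",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", G$sample_ids), collapse = "\t")), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_along(G$snp_ids)) {
    d <- G$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    writeLines(paste(c(G$chrom[j], G$pos[j], G$snp_ids[j], "A", "G", ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

snp_maf <- function(dosage) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' SNP quality control
#'
#' Retains SNPs with minor allele frequency at or above `maf_min` and
#' genotype missingness strictly below `miss_max`. Multi-allelic records
#' are already excluded by the VCF reader; a per-SNP `min_depth` filter is
#' applied when a depth matrix is supplied (sites with mean depth at or
#' below the threshold are dropped).
#'
#' @param G a [genotype_matrix()].
#' @param maf_min MAF threshold (default 0.05, inclusive).
#' @param miss_max missingness ceiling (default 0.3, exclusive).
#' @param depth optional samples x SNPs depth matrix; SNPs must have mean
#'   depth > `min_depth`.
#' @param min_depth depth floor (default 3).
#' @return filtered [genotype_matrix()] with a `qc_log` attribute.
#' @export
qc_filter_variants <- function(G, maf_min = 0.05, miss_max = 0.3,
                               depth = NULL, min_depth = 3) {
  maf <- snp_maf(G$dosage)
  miss <- colMeans(is.na(G$dosage))
  keep <- maf >= maf_min & miss < miss_max & !is.na(maf)
  if (!is.null(depth)) keep <- keep & colMeans(depth, na.rm = TRUE) > min_depth
  if (!any(keep)) stop("all SNPs removed by QC")
  out <- genotype_matrix(G$dosage[, keep, drop = FALSE],
                         G$chrom[keep], G$pos[keep])
  attr(out, "qc_log") <- c(input = length(keep), retained = sum(keep),
                           removed_maf = sum(maf < maf_min, na.rm = TRUE),
                           removed_missing = sum(miss >= miss_max))
  out
}

#' LD pruning (indep-pairwise style)
#'
#' Sliding window of `window` SNPs advancing by `step`, per chromosome.
#' Within a window, while any retained pair has `r^2 > r2_max` the member of
#' the worst pair with the higher mean r-squared against the other retained
#' window SNPs is removed (ties: the later position).
#'
#' @param G a QC'd [genotype_matrix()].
#' @param window window size in SNPs (default 50).
#' @param step step in SNPs (default 10).
#' @param r2_max r-squared ceiling (default 0.1).
#' @return character vector of retained SNP ids.
#' @export
ld_prune <- function(G, window = 50L, step = 10L, r2_max = 0.1) {
  removed <- logical(length(G$snp_ids))
  names(removed) <- G$snp_ids
  dos <- G$dosage
  for (chr in unique(G$chrom)) {
    idx <- which(G$chrom == chr)
    idx <- idx[order(G$pos[idx])]
    start <- 1L
    repeat {
      win <- idx[start:min(start + window - 1L, length(idx))]
      win <- win[!removed[win]]
      if (length(win) > 1) {
        R2 <- suppressWarnings(stats::cor(dos[, win, drop = FALSE],
                                          use = "pairwise.complete.obs"))^2
        diag(R2) <- 0
        R2[is.na(R2)] <- 0
        while (max(R2) > r2_max) {
          worst <- which(R2 == max(R2), arr.ind = TRUE)[1, ]
          mr <- rowMeans(R2)
          drop_local <- if (mr[worst[1]] > mr[worst[2]]) worst[1]
                        else if (mr[worst[2]] > mr[worst[1]]) worst[2]
                        else worst[which.max(G$pos[win[worst]])]
          removed[win[drop_local]] <- TRUE
          R2[drop_local, ] <- 0; R2[, drop_local] <- 0
        }
      }
      if (start + window - 1L >= length(idx)) break
      start <- start + step
    }
  }
  G$snp_ids[!removed]
}

#' Genomic relationship matrix
#'
#' VanRaden/GCTA form: `g_jk = (1/m) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) /
#' (2 p_i (1 - p_i))`, equivalently `Z Z' / m` with `Z` the per-SNP
#' standardized dosage matrix. Missing dosages are mean-imputed per SNP
#' first (count logged); monomorphic SNPs are an error (QC should have
#' removed them).
#'
#' @param G a [genotype_matrix()].
#' @return list of class `grm`: `matrix` (n x n), `n_snps`, `n_imputed`.
#' @export
compute_grm <- function(G) {
  X <- G$dosage
  n_imp <- sum(is.na(X))
  if (n_imp > 0) {
    mu <- colMeans(X, na.rm = TRUE)
    for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  }
  p <- colMeans(X) / 2
  if (any(p <= 0 | p >= 1)) stop("monomorphic SNP reached GRM stage")
  Z <- sweep(sweep(X, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(Z) / ncol(X)
  dimnames(A) <- list(G$sample_ids, G$sample_ids)
  structure(list(matrix = A, n_snps = ncol(X), n_imputed = n_imp),
            class = "grm")
}

grm_values <- function(grm) if (inherits(grm, "grm")) grm$matrix else as.matrix(grm)

reml_loglik <- function(h2, lambda, ystar, Xstar) {
  w <- h2 * lambda + (1 - h2)
  n <- length(ystar); p <- ncol(Xstar)
  XtWX <- crossprod(Xstar / w, Xstar)
  XtWy <- crossprod(Xstar / w, ystar)
  b <- solve(XtWX, XtWy)
  r <- ystar - Xstar %*% b
  rss <- sum(r^2 / w)
  s2 <- rss / (n - p)
  -0.5 * ((n - p) * log(s2) + sum(log(w)) +
            determinant(XtWX, logarithm = TRUE)$modulus +
            (n - p))
}

#' REML heritability on the observed scale
#'
#' Single-variance-component linear mixed model `y = X b + g + e`,
#' `g ~ N(0, sigma_g^2 G)`. After rotating by the GRM eigenvectors the
#' restricted likelihood is profiled over `h2 = sigma_g^2 / sigma_p^2` on
#' `[0, 0.999]` by bounded one-dimensional optimization. The SE comes from
#' the numerical observed information in `h2`; the likelihood-ratio test
#' against `h2 = 0` uses the 0.5 chi-square(1) boundary mixture.
#'
#' @param y phenotype (binary 0/1 for the enterotype use case, but any
#'   numeric works).
#' @param grm a `grm` (or plain matrix). Non-PSD matrices are eigenvalue
#'   clipped with a warning.
#' @param covariates optional data.frame / matrix of fixed effects
#'   (an intercept is always added).
#' @return list: `h2_observed`, `se_observed`, `loglik`, `loglik0`, `lrt`,
#'   `lrt_p`.
#' @export
reml_h2_observed <- function(y, grm, covariates = NULL) {
  A <- grm_values(grm)
  n <- length(y)
  stopifnot(nrow(A) == n)
  X <- if (is.null(covariates)) matrix(1, n, 1)
       else stats::model.matrix(~ ., data = as.data.frame(covariates))
  e <- eigen(A, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(e$values)) {
    warning("GRM not PSD: clipping negative eigenvalues")
  }
  lambda <- pmax(e$values, 0)
  U <- e$vectors
  ystar <- drop(crossprod(U, y))
  Xstar <- crossprod(U, X)
  opt <- stats::optimize(reml_loglik, c(0, 0.999), lambda = lambda,
                         ystar = ystar, Xstar = Xstar, maximum = TRUE,
                         tol = 1e-8)
  h2 <- opt$maximum
  ll <- opt$objective
  ll0 <- reml_loglik(0, lambda, ystar, Xstar)
  if (ll0 >= ll) { # boundary optimum: optimize() never probes exactly 0
    h2 <- 0; ll <- ll0
  }
  # numerical observed information
  h <- 1e-4
  hh <- min(max(h2, h), 0.999 - h)
  d2 <- (reml_loglik(hh + h, lambda, ystar, Xstar) - 2 *
           reml_loglik(hh, lambda, ystar, Xstar) +
           reml_loglik(hh - h, lambda, ystar, Xstar)) / h^2
  se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  lrt <- max(2 * (ll - ll0), 0)
  list(h2_observed = h2, se_observed = se, loglik = as.numeric(ll),
       loglik0 = as.numeric(ll0), lrt = as.numeric(lrt),
       lrt_p = 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE) +
         0.5 * (lrt <= 0))
}

#' Observed-scale to liability-scale heritability
#'
#' Threshold-model transform
#' `h2_l = h2_obs * K(1-K)/z^2 * K(1-K)/(P(1-P))` with `K` the population
#' prevalence, `P` the sample case fraction and `z` the standard-normal
#' density at the threshold `qnorm(1 - K)`. With `K = P = 0.5` the
#' multiplier is exactly `pi/2`.
#'
#' @param h2_obs observed-scale heritability.
#' @param K population prevalence in (0, 1).
#' @param P sample case fraction (defaults to `K`, the convention when no
#'   external prevalence is known).
#' @param se_obs optional observed-scale SE, transformed by the same linear
#'   multiplier.
#' @return list: `h2_liability`, `multiplier`, and `se_liability` when
#'   `se_obs` is given.
#' @export
observed_to_liability <- function(h2_obs, K, P = K, se_obs = NULL) {
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1) stop("K and P must be in (0, 1)")
  z <- stats::dnorm(stats::qnorm(1 - K))
  mult <- (K * (1 - K) / z^2) * (K * (1 - K) / (P * (1 - P)))
  out <- list(h2_liability = h2_obs * mult, multiplier = mult)
  if (!is.null(se_obs)) out$se_liability <- se_obs * mult
  out
}

he_regress <- function(prod, gvec) sum(prod * gvec) / sum(gvec^2)

#' Genetic correlation by Haseman-Elston regression
#'
#' Moment estimator: regress pairwise phenotype cross-products of the
#' standardized traits on the GRM off-diagonal elements to obtain the two
#' genetic variances and the genetic covariance; `rG = cov / sqrt(vX vY)`.
#' The SE is a block jackknife over samples. `|rG| > 1` is clamped with a
#' flag.
#'
#' @param yX,yY numeric traits on the same samples.
#' @param grm a `grm` or matrix.
#' @param n_blocks jackknife blocks (default 20).
#' @return list: `rG`, `se`, `vX`, `vY`, `cov`, `clamped`.
#' @export
genetic_correlation <- function(yX, yY, grm, n_blocks = 20L) {
  A <- grm_values(grm)
  n <- length(yX)
  zx <- as.vector(scale(yX)); zy <- as.vector(scale(yY))
  ut <- upper.tri(A)
  est_from <- function(keep) {
    Ak <- A[keep, keep]; u <- upper.tri(Ak)
    g <- Ak[u]
    x <- zx[keep]; y <- zy[keep]
    px <- tcrossprod(x)[u]; py <- tcrossprod(y)[u]
    pxy <- (tcrossprod(x, y)[u] + tcrossprod(y, x)[u]) / 2
    c(vx = he_regress(px, g), vy = he_regress(py, g), cov = he_regress(pxy, g))
  }
  full <- est_from(rep(TRUE, n))
  if (full["vx"] <= 0 || full["vy"] <= 0) {
    return(list(rG = NA_real_, se = NA_real_, vX = full[["vx"]],
                vY = full[["vy"]], cov = full[["cov"]], clamped = FALSE,
                flag = "nonpositive genetic variance"))
  }
  rg_of <- function(v) unname(v["cov"] / sqrt(v["vx"] * v["vy"]))
  rg <- rg_of(full)
  blocks <- split(seq_len(n), rep_len(seq_len(n_blocks), n))
  rg_jack <- vapply(blocks, function(b) {
    keep <- rep(TRUE, n); keep[b] <- FALSE
    v <- est_from(keep)
    if (v["vx"] <= 0 || v["vy"] <= 0) return(NA_real_)
    rg_of(v)
  }, numeric(1))
  rg_jack <- rg_jack[is.finite(rg_jack)]
  m <- length(rg_jack)
  se <- if (m > 1) sqrt((m - 1) / m * sum((rg_jack - mean(rg_jack))^2)) else NA_real_
  clamped <- abs(rg) > 1
  list(rG = max(min(rg, 1), -1), se = se, vX = unname(full["vx"]),
       vY = unname(full["vy"]), cov = unname(full["cov"]), clamped = clamped)
}

#' Binary-trait GWAS (logistic score test)
#'
#' Per-SNP association of a binary trait with covariate adjustment. The
#' primary p-value is the logistic score test (robust to separation); the
#' effect (log-odds) and SE come from a per-SNP Wald fit when
#' `wald = TRUE`. Reports the genomic inflation factor
#' `lambda = median(chi^2) / 0.4549` and attaches Bonferroni thresholds.
#'
#' @param y binary 0/1 phenotype.
#' @param G a [genotype_matrix()] (missing dosages mean-imputed).
#' @param covariates optional data.frame of covariates.
#' @param wald also fit per-SNP logistic Wald effects (slower).
#' @param n_independent number of independent SNPs for the thresholds
#'   (default: number of SNPs tested).
#' @return list of class `gwas_result`: `table` (snp, chrom, pos, beta, se,
#'   chi2, p), `lambda`, `thresholds`.
#' @export
gwas_binary_trait <- function(y, G, covariates = NULL, wald = TRUE,
                              n_independent = NULL) {
  X <- if (is.null(covariates)) matrix(1, length(y), 1)
       else stats::model.matrix(~ ., data = as.data.frame(covariates))
  dos <- G$dosage
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    for (j in which(colSums(is.na(dos)) > 0)) dos[is.na(dos[, j]), j] <- mu[j]
  }
  null_fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  mu0 <- null_fit$fitted.values
  w <- mu0 * (1 - mu0)
  res <- y - mu0
  XtWX_inv <- solve(crossprod(X * w, X))
  # score statistic per SNP, vectorized
  U <- drop(crossprod(dos, res))
  GW <- crossprod(dos * w, X)                # m x p
  V <- colSums(dos^2 * w) - rowSums((GW %*% XtWX_inv) * GW)
  chi2 <- ifelse(V > 1e-12, U^2 / V, NA_real_)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  beta <- se <- rep(NA_real_, ncol(dos))
  if (wald) {
    for (j in seq_len(ncol(dos))) {
      fit <- tryCatch(suppressWarnings(
        stats::glm.fit(cbind(X, dos[, j]), y, family = stats::binomial())),
        error = function(e) NULL)
      if (is.null(fit)) next
      cf <- fit$coefficients
      k <- length(cf)
      Xf <- cbind(X, dos[, j])
      wf <- fit$fitted.values * (1 - fit$fitted.values)
      Vf <- tryCatch(solve(crossprod(Xf * wf, Xf)), error = function(e) NULL)
      if (!is.null(Vf)) { beta[j] <- cf[k]; se[j] <- sqrt(Vf[k, k]) }
    }
  }
  lambda <- stats::median(chi2, na.rm = TRUE) /
    stats::qchisq(0.5, df = 1)
  if (is.null(n_independent)) n_independent <- sum(!is.na(p))
  structure(list(
    table = data.frame(snp = G$snp_ids, chrom = G$chrom, pos = G$pos,
                       beta = beta, se = se, chi2 = chi2, p = p,
                       stringsAsFactors = FALSE),
    lambda = lambda,
    thresholds = significance_thresholds(n_independent)),
    class = "gwas_result")
}

#' Bonferroni significance thresholds
#'
#' Genome-wide `0.05 / n` and suggestive `1 / n`, each reported at full
#' precision and rounded to two significant figures.
#'
#' @param n_independent_snps number of independent SNPs (> 0).
#' @return list: `genome_wide`, `suggestive`, `genome_wide_2sf`,
#'   `suggestive_2sf`.
#' @export
significance_thresholds <- function(n_independent_snps) {
  if (n_independent_snps <= 0) stop("n must be > 0")
  gw <- 0.05 / n_independent_snps
  sug <- 1 / n_independent_snps
  list(genome_wide = gw, suggestive = sug,
       genome_wide_2sf = signif(gw, 2), suggestive_2sf = signif(sug, 2))
}

#' Centered log-ratio transform
#'
#' `clr(x)_g = ln(x_g / geometric mean(x))` per sample, after replacing
#' zeros. Rows sum to zero by construction and the transform is invariant
#' to per-sample scaling.
#'
#' @param tab an [abundance_table()] or relative-abundance matrix.
#' @param zero_replacement numeric replacement value, or `"half_min"`
#'   (default): half the smallest nonzero relative abundance in the matrix.
#' @return samples x genera matrix of clr values.
#' @export
clr_transform <- function(tab, zero_replacement = "half_min") {
  X <- rel_abundance(tab)
  if (any(rowSums(X) == 0) || anyNA(X)) stop("all-zero sample: clr undefined")
  if (identical(zero_replacement, "half_min")) {
    zero_replacement <- min(X[X > 0]) / 2
  }
  X[X == 0] <- zero_replacement
  X <- X / rowSums(X)
  L <- log(X)
  sweep(L, 1, rowMeans(L))
}

#' SNP effects on the rumen microbiota
#'
#' For each (significant) SNP and each genus passing the prevalence floor:
#' genera at or above `prevalence_cut` are tested with a linear model on
#' clr-transformed abundance (`clr ~ genotype + birthplace`); rarer genera
#' with logistic presence/absence regression. BH-FDR is applied across all
#' genus x SNP tests.
#'
#' @param snps samples x SNPs dosage matrix (the significant set) or
#'   [genotype_matrix()].
#' @param tab an [abundance_table()] aligned on samples.
#' @param birthplace factor covariate (optional).
#' @param prevalence_cut clr vs presence/absence routing (default 0.60).
#' @param genus_prevalence_floor minimum prevalence for a genus to be
#'   tested at all (default 0.015, exclusive).
#' @param fdr FDR level (default 0.05).
#' @return data.frame: snp, genus, model, estimate, se, p, q, significant.
#' @export
snp_microbiota_effects <- function(snps, tab, birthplace = NULL,
                                   prevalence_cut = 0.60,
                                   genus_prevalence_floor = 0.015,
                                   fdr = 0.05) {
  dos <- if (inherits(snps, "genotype_matrix")) snps$dosage else as.matrix(snps)
  rel <- rel_abundance(tab)
  stopifnot(nrow(dos) == nrow(rel))
  prev <- colMeans(rel > 0)
  genera <- colnames(rel)[prev > genus_prevalence_floor]
  clr <- clr_transform(tab)
  bp <- if (is.null(birthplace)) NULL else as.factor(birthplace)
  rows <- list()
  for (s in colnames(dos)) {
    gvec <- dos[, s]
    if (length(unique(gvec[!is.na(gvec)])) < 2) next  # monomorphic
    for (g in genera) {
      if (prev[g] >= prevalence_cut) {
        df <- data.frame(y = clr[, g], g = gvec)
        form <- y ~ g
        if (!is.null(bp)) { df$bp <- bp; form <- y ~ g + bp }
        sm <- summary(stats::lm(form, data = df))$coefficients
        model <- "clr_linear"
      } else {
        df <- data.frame(y = as.integer(rel[, g] > 0), g = gvec)
        form <- y ~ g
        if (!is.null(bp)) { df$bp <- bp; form <- y ~ g + bp }
        fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                           data = df))
        sm <- summary(fit)$coefficients
        model <- "presence_logistic"
      }
      if (!"g" %in% rownames(sm)) next
      rows[[length(rows) + 1L]] <- data.frame(
        snp = s, genus = g, model = model,
        estimate = sm["g", 1], se = sm["g", 2], p = sm["g", 4],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("nothing to test")
  out$q <- bh_adjust(out$p)
  out$significant <- out$q <= fdr
  rownames(out) <- NULL
  out
}
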