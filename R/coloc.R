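#' Hypergeometric overlap test
#'
#' Upper-tail probability of observing at least the observed overlap
#' between two SNP sets drawn from a common universe. An observed overlap
#' of zero is reported as `P(X >= 0) = 1`.
#'
#' @param setA,setB character vectors of SNP ids.
#' @param universe_size size of the common universe (must be at least the
#'   size of the union).
#' @return list: `overlap`, `p`.
#' @export
overlap_hypergeometric <- function(setA, setB, universe_size) {
  setA <- unique(setA); setB <- unique(setB)
  if (length(union(setA, setB)) > universe_size)
    stop("universe smaller than the union of the sets")
  ov <- length(intersect(setA, setB))
  p <- if (ov == 0) 1 else
    stats::phyper(ov - 1, length(setA), universe_size - length(setA),
                  length(setB), lower.tail = FALSE)
  list(overlap = ov, p = p)
}

#' Cross-signal LD
#'
#' Squared Pearson correlation of dosages for every pair (one SNP from each
#' signal set), plus the mean. Monomorphic SNPs are skipped with a warning.
#'
#' @param snpsA,snpsB character vectors of SNP ids present in `G`.
#' @param G a [genotype_matrix()].
#' @return list: `r2` (|A| x |B| matrix), `mean_r2`.
#' @export
cross_signal_ld <- function(snpsA, snpsB, G) {
  dos <- G$dosage
  miss <- setdiff(c(snpsA, snpsB), colnames(dos))
  if (length(miss)) stop("SNPs absent from genotype matrix: ",
                         paste(miss, collapse = ", "))
  mono <- colnames(dos)[apply(dos, 2, function(x)
    length(unique(x[!is.na(x)])) < 2)]
  dropA <- intersect(snpsA, mono); dropB <- intersect(snpsB, mono)
  if (length(c(dropA, dropB)))
    warning("monomorphic SNP(s) skipped: ",
            paste(unique(c(dropA, dropB)), collapse = ", "))
  snpsA <- setdiff(snpsA, mono); snpsB <- setdiff(snpsB, mono)
  r <- suppressWarnings(stats::cor(dos[, snpsA, drop = FALSE],
                                   dos[, snpsB, drop = FALSE],
                                   use = "pairwise.complete.obs"))
  list(r2 = r^2, mean_r2 = mean(r^2, na.rm = TRUE))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

logdiff <- function(a, b) {
  # log(exp(a) - exp(b)), a >= b
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Bayesian colocalization via approximate Bayes factors
#'
#' Wakefield approximate Bayes factor per SNP per trait,
#' `log ABF = (log(1 - s) + s z^2) / 2` with shrinkage `s = W/(V + W)`,
#' `V = SE^2` and `W` the prior effect variance. Posterior probabilities of the five
#' hypotheses (H0 no association ... H4 shared causal variant) follow the
#' single-causal-variant enumeration with priors `p1`, `p2`, `p12`. A
#' shared-variant call is `PP.H4 > 0.50`.
#'
#' @param statsA,statsB data.frames with columns `snp`, `beta`, `se` over a
#'   shared SNP list (intersection is used; disjoint lists are an error).
#' @param p1,p2,p12 prior probabilities that a SNP is causal for trait A
#'   only, B only, or both (defaults 1e-4, 1e-4, 1e-5).
#' @param prior_sd_a,prior_sd_b prior effect SDs (`sqrt(W)`): 0.15 for a
#'   binary log-odds trait, 0.2 for a quantitative trait.
#' @return list of class `coloc_result`: `pp` (named PP.H0..PP.H4),
#'   `n_snps`, `priors`, `shared_call`.
#' @export
coloc_abf <- function(statsA, statsB, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd_a = 0.15, prior_sd_b = 0.2) {
  shared <- intersect(statsA$snp, statsB$snp)
  if (length(shared) == 0) stop("SNP lists are disjoint")
  a <- statsA[match(shared, statsA$snp), ]
  b <- statsB[match(shared, statsB$snp), ]
  labf <- function(beta, se, W) {
    V <- se^2
    r <- W / (V + W)
    0.5 * (log1p(-r) + r * (beta / se)^2)
  }
  lA <- labf(a$beta, a$se, prior_sd_a^2)
  lB <- labf(b$beta, b$se, prior_sd_b^2)
  sumA <- logsumexp(lA)
  sumB <- logsumexp(lB)
  sumAB <- logsumexp(lA + lB)
  lH0 <- 0
  lH1 <- log(p1) + sumA
  lH2 <- log(p2) + sumB
  lH3 <- log(p1) + log(p2) + logdiff(sumA + sumB, sumAB)
  lH4 <- log(p12) + sumAB
  l <- c(lH0, lH1, lH2, lH3, lH4)
  pp <- exp(l - logsumexp(l))
  names(pp) <- paste0("PP.H", 0:4)
  structure(list(pp = pp, n_snps = length(shared),
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 shared_call = unname(pp["PP.H4"] > 0.50)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc_result over %d SNPs: %s\n", x$n_snps,
              paste(sprintf("%s=%.3f", names(x$pp), x$pp), collapse = " ")))
  cat(if (x$shared_call) "shared causal variant called (PP.H4 > 0.50)\n"
      else "no shared-variant call\n")
  invisible(x)
}
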