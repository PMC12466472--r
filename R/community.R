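#' Rarefy counts to a common depth
#'
#' Subsamples each sample's counts without replacement to exactly `depth`
#' reads (the "minimum library size" convention when `depth = "auto"`).
#' Samples whose total is below `depth` are dropped with a warning.
#'
#' @param tab an [abundance_table()].
#' @param depth integer target depth, or `"auto"` for the minimum library
#'   size across samples.
#' @param seed integer RNG seed.
#' @return A rarefied [abundance_table()].
#' @export
rarefy_counts <- function(tab, depth = "auto", seed = 1L) {
  counts <- tab$counts
  tot <- rowSums(counts)
  if (identical(depth, "auto")) depth <- min(tot)
  depth <- as.integer(depth)
  if (depth < 1) stop("depth must be >= 1")
  keep <- tot >= depth
  if (!all(keep)) {
    warning(sprintf("%d sample(s) below depth %d dropped: %s",
                    sum(!keep), depth,
                    paste(rownames(counts)[!keep], collapse = ", ")))
    counts <- counts[keep, , drop = FALSE]
  }
  set.seed(seed)
  out <- t(apply(counts, 1, function(x) {
    if (sum(x) == depth) return(x)
    # draw `depth` reads without replacement from the expanded read pool
    picked <- sample.int(sum(x), depth)
    cum <- cumsum(x)
    tabulate(findInterval(picked - 1L, c(0, cum), rightmost.closed = FALSE),
             nbins = length(x))
  }))
  dimnames(out) <- dimnames(counts)
  abundance_table(out)
}

fisher_alpha_solve <- function(S, N, tol = 1e-10, max_iter = 200) {
  if (S <= 0 || N <= 0) return(NA_real_)
  if (S >= N) return(Inf)
  f <- function(a) a * log1p(N / a) - S
  lo <- 1e-8; hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  a <- max(S / log(N), lo) # Newton from a sensible start
  for (i in seq_len(max_iter)) {
    fa <- f(a)
    da <- log1p(N / a) - N / (a + N)
    step <- fa / da
    a_new <- a - step
    if (!is.finite(a_new) || a_new <= lo || a_new >= hi * 2) {
      # bisection fallback
      if (fa > 0) hi <- a else lo <- a
      a_new <- (lo + hi) / 2
    }
    if (abs(a_new - a) < tol) return(a_new)
    a <- a_new
  }
  a
}

alpha_one <- function(x, rare_cutoff = 10L) {
  x <- x[x > 0]
  N <- sum(x)
  if (N == 0) {
    return(c(observed = NA, shannon = NA, simpson = NA, invsimpson = NA,
             pielou = NA, chao1 = NA, ace = NA, fisher_alpha = NA))
  }
  S <- length(x)
  p <- x / N
  H <- -sum(p * log(p))
  D <- sum(p^2)
  F1 <- sum(x == 1); F2 <- sum(x == 2)
  chao1 <- S + F1 * (F1 - 1) / (2 * (F2 + 1)) # bias-corrected form
  # ACE, classic form with rare-species cutoff
  rare <- x[x <= rare_cutoff]
  Srare <- length(rare); Sabund <- S - Srare
  Nrare <- sum(rare)
  if (Srare == 0 || Nrare == F1) {
    ace <- if (Srare == 0) S else NA_real_
  } else {
    Cace <- 1 - F1 / Nrare
    Fi <- tabulate(rare, nbins = rare_cutoff)
    gamma2 <- max(Srare / Cace * sum(seq_len(rare_cutoff) *
                  (seq_len(rare_cutoff) - 1) * Fi) /
                  (Nrare * (Nrare - 1)) - 1, 0)
    ace <- Sabund + Srare / Cace + F1 / Cace * gamma2
  }
  c(observed = S,
    shannon = H,
    simpson = 1 - D,     # reported as 1 - sum(p^2); see `complement` flag
    invsimpson = 1 / D,
    pielou = if (S > 1) H / log(S) else NA_real_,
    chao1 = chao1,
    ace = ace,
    fisher_alpha = fisher_alpha_solve(S, N))
}

#' Alpha-diversity profile
#'
#' Computes, per sample: observed richness, Shannon (natural log), Simpson
#' (as 1 - sum p^2 by default, or the raw concentration sum p^2), inverse
#' Simpson, Pielou's evenness H/ln S, bias-corrected Chao1
#' S + F1(F1-1)/(2(F2+1)), ACE (rare cutoff 10) and Fisher's alpha (root of
#' S = alpha ln(1 + N/alpha)). All-zero samples yield `NA` metrics.
#'
#' @param tab an [abundance_table()] (counts are used).
#' @param simpson_complement report Simpson as `1 - sum(p^2)` (default) or
#'   the raw `sum(p^2)` concentration when `FALSE`.
#' @return data.frame, one row per sample.
#' @export
alpha_diversity <- function(tab, simpson_complement = TRUE) {
  res <- t(apply(tab$counts, 1, alpha_one))
  res <- as.data.frame(res)
  if (!simpson_complement) res$simpson <- 1 - res$simpson
  cbind(sample_id = tab$sample_ids, res,
        stringsAsFactors = FALSE)
}

as_dist_matrix <- function(m, ids) {
  dimnames(m) <- list(ids, ids)
  structure(list(ids = ids, matrix = m), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d samples\n", length(x$ids)))
  invisible(x)
}

dist_values <- function(D) if (inherits(D, "distance_matrix")) D$matrix else as.matrix(D)

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(a, b) = 1 - 2 sum min(a_i, b_i) / sum (a_i + b_i)` on relative
#' abundances.
#'
#' @param tab an [abundance_table()].
#' @return A `distance_matrix` (symmetric, zero diagonal).
#' @export
bray_curtis <- function(tab) {
  rel <- rel_abundance(tab)
  if (nrow(rel) < 2) stop("need at least two samples")
  if (anyNA(rel)) stop("zero-total sample: Bray-Curtis undefined")
  n <- nrow(rel)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    xi <- rel[i, ]
    for (j in (i + 1):n) {
      s <- sum(pmin(xi, rel[j, ]))
      D[i, j] <- D[j, i] <- 1 - 2 * s / (sum(xi) + sum(rel[j, ]))
    }
  }
  as_dist_matrix(D, rownames(rel))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Eigendecomposition of the double-centred matrix `-1/2 J D^2 J`. Axes with
#' positive eigenvalues carry coordinates scaled by `sqrt(eigenvalue)`;
#' negative eigenvalues are reported but their axes dropped.
#'
#' @param D a `distance_matrix` (or square symmetric matrix).
#' @param n_axes number of axes to return (truncated to the positive rank,
#'   with a warning if more were requested).
#' @return list with `coordinates` (n x k), `eigenvalues` (all, sorted
#'   decreasing) and `prop_explained` over positive eigenvalues.
#' @export
pcoa <- function(D, n_axes = 2L) {
  d <- dist_values(D)
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-12
  k <- sum(pos)
  if (n_axes > k) {
    warning(sprintf("n_axes = %d exceeds positive rank %d; truncated", n_axes, k))
    n_axes <- k
  }
  coords <- e$vectors[, seq_len(n_axes), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(n_axes)]), n_axes)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(n_axes))
  list(coordinates = coords,
       eigenvalues = e$values,
       prop_explained = e$values[seq_len(n_axes)] / sum(e$values[pos]))
}

permanova_ssw <- function(D2, groups) {
  ssw <- 0
  for (g in split(seq_along(groups), groups)) {
    ssw <- ssw + sum(D2[g, g]) / (2 * length(g))
  }
  ssw
}

#' PERMANOVA (marginal, single factor per model)
#'
#' Distance-based pseudo-F with permutation p-value:
#' `F = (SS_between/(k-1)) / (SS_within/(n-k))`,
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`. When several factors are
#' supplied each is tested in its own single-factor model (marginal R^2).
#'
#' @param D `distance_matrix`.
#' @param groups factor, or data.frame of factors (one marginal model each).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return data.frame with term, df, pseudo_F, r_squared, p_perm, n_perm.
#' @export
permanova <- function(D, groups, n_perm = 999L, seed = 1L) {
  d <- dist_values(D)
  if (!is.data.frame(groups)) groups <- data.frame(group = groups)
  n <- nrow(d)
  D2 <- d^2
  sst <- sum(D2) / (2 * n)
  set.seed(seed)
  out <- lapply(names(groups), function(term) {
    g <- as.factor(groups[[term]])
    if (nlevels(droplevels(g)) < 2) stop(sprintf("factor '%s' has a single level", term))
    g <- droplevels(g)
    k <- nlevels(g)
    ssw <- permanova_ssw(D2, g)
    ssb <- sst - ssw
    f_obs <- (ssb / (k - 1)) / (ssw / (n - k))
    f_perm <- vapply(seq_len(n_perm), function(i) {
      gp <- g[sample.int(n)]
      sswp <- permanova_ssw(D2, gp)
      ((sst - sswp) / (k - 1)) / (sswp / (n - k))
    }, numeric(1))
    data.frame(term = term, df = k - 1L, pseudo_F = f_obs,
               r_squared = ssb / sst,
               p_perm = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
               n_perm = n_perm, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
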