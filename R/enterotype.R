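#' Square-root Jensen-Shannon distance matrix
#'
#' The enterotyping distance of Arumugam-style analyses:
#' `d(a, b) = sqrt(JSD(a, b))` with
#' `JSD = 1/2 KL(a || m) + 1/2 KL(b || m)`, `m = (a + b)/2`, natural
#' logarithms. Zero entries are replaced by a small pseudocount (a fraction
#' of each profile's mass) and the profile renormalized, so the KL terms are
#' finite.
#'
#' @param tab an [abundance_table()] or matrix of relative abundances.
#' @param pseudocount zero replacement, as a fraction of row mass
#'   (default 1e-9).
#' @return A `distance_matrix`.
#' @export
jsd_matrix <- function(tab, pseudocount = 1e-9) {
  rel <- rel_abundance(tab)
  if (any(rel < 0, na.rm = TRUE)) stop("negative abundances")
  if (anyNA(rel)) stop("zero-total sample: JSD undefined")
  rel[rel == 0] <- pseudocount
  rel <- rel / rowSums(rel)
  n <- nrow(rel)
  xlogx <- rel * log(rel)
  H <- rowSums(xlogx) # negative entropy per profile
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    a <- rel[i, ]
    for (j in (i + 1):n) {
      m <- (a + rel[j, ]) / 2
      jsd <- (H[i] + H[j]) / 2 - sum(m * log(m))
      D[i, j] <- D[j, i] <- sqrt(max(jsd, 0))
    }
  }
  as_dist_matrix(D, rownames(rel))
}

#' Partitioning around medoids (BUILD + SWAP)
#'
#' Deterministic k-medoids on a precomputed distance matrix: the BUILD phase
#' seeds medoids greedily, the SWAP phase exchanges a medoid for a
#' non-medoid while the objective (total distance of samples to their
#' nearest medoid) strictly decreases. All ties break toward the lowest
#' sample index, so results are reproducible without randomness; `seed` is
#' accepted for interface symmetry.
#'
#' @param D `distance_matrix` or square symmetric matrix.
#' @param k number of clusters, `2 <= k < n`.
#' @param seed unused (algorithm is deterministic); kept for interface
#'   stability.
#' @return list with `assignments` (integer cluster per sample, named),
#'   `medoid_ids`, `medoid_idx`, `objective`.
#' @export
pam_cluster <- function(D, k, seed = NULL) {
  d <- dist_values(D)
  n <- nrow(d)
  if (k < 2 || k >= n) stop("require 2 <= k < n")
  # BUILD: start from the 1-medoid minimizer, then add greedily
  med <- which.min(colSums(d))
  dmin <- d[, med]
  while (length(med) < k) {
    gain <- vapply(seq_len(n), function(c) {
      if (c %in% med) return(-Inf)
      sum(pmax(dmin - d[, c], 0))
    }, numeric(1))
    med <- c(med, which.max(gain))
    dmin <- pmin(dmin, d[, med[length(med)]])
  }
  objective <- function(medset) sum(apply(d[, medset, drop = FALSE], 1, min))
  obj <- objective(med)
  repeat {
    eps <- 1e-10 * (1 + obj) # require strictly positive improvement
    best <- list(delta = eps, med = NULL)
    nonmed <- setdiff(seq_len(n), med)
    dm <- d[, med, drop = FALSE]
    ord <- apply(dm, 1, order)
    d1 <- dm[cbind(seq_len(n), ord[1, ])]      # nearest-medoid distance
    nearest <- ord[1, ]
    d2 <- dm[cbind(seq_len(n), ord[2, ])]      # second-nearest distance
    for (mi in seq_along(med)) {
      # distance to nearest medoid excluding med[mi]
      dex <- ifelse(nearest == mi, d2, d1)
      for (c in nonmed) {
        newobj <- sum(pmin(dex, d[, c]))
        delta <- obj - newobj
        if (delta > best$delta) {
          best <- list(delta = delta, med = sort(c(med[-mi], c)))
        }
      }
    }
    if (is.null(best$med)) break
    med <- best$med
    obj <- obj - best$delta
  }
  med <- sort(med)
  assign_idx <- apply(d[, med, drop = FALSE], 1, which.min)
  out <- list(assignments = stats::setNames(assign_idx, rownames(d)),
              medoid_ids = rownames(d)[med],
              medoid_idx = med,
              objective = objective(med))
  out
}

#' Calinski-Harabasz index of a partition
#'
#' Samples are embedded by classical PCoA (positive-eigenvalue axes only);
#' the index is `[B/(k-1)] / [W/(n-k)]` with `B` / `W` the between- /
#' within-cluster sums of squared Euclidean distances to the relevant
#' centroids in that embedding.
#'
#' @param D `distance_matrix`.
#' @param assignments integer or factor cluster labels, one per sample.
#' @return numeric CH value.
#' @export
ch_index <- function(D, assignments) {
  g <- as.integer(as.factor(assignments))
  k <- length(unique(g))
  if (k < 2) stop("CH index undefined for a single cluster")
  d <- dist_values(D)
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B0 <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B0 + t(B0)) / 2, symmetric = TRUE)
  pos <- which(e$values > max(e$values) * 1e-12)
  X <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), length(pos))
  mu <- colMeans(X)
  W <- 0; B <- 0
  for (grp in split(seq_len(n), g)) {
    Xg <- X[grp, , drop = FALSE]
    mg <- colMeans(Xg)
    W <- W + sum(sweep(Xg, 2, mg)^2)
    B <- B + length(grp) * sum((mg - mu)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Enterotype discovery
#'
#' Distance matrix (sqrt-JSD by default, Bray-Curtis optional), PAM for each
#' k in `k_range`, Calinski-Harabasz curve, and `k_opt = argmax CH` (ties to
#' the smallest k). Clusters are relabelled by decreasing size so label 1 is
#' always the largest enterotype.
#'
#' @param tab an [abundance_table()].
#' @param k_range candidate cluster counts (default 2:10).
#' @param distance_kind `"jsd"` (default) or `"bray"`.
#' @param seed passed through to [pam_cluster()] (deterministic anyway).
#' @return An `enterotype_model`: list with `distance_kind`, `assignments`,
#'   `medoid_ids`, `ch_curve` (named by k), `k_opt`, `cluster_sizes`,
#'   `distance` (the matrix, for reuse).
#' @export
fit_enterotypes <- function(tab, k_range = 2:10, distance_kind = c("jsd", "bray"),
                            seed = 1L) {
  distance_kind <- match.arg(distance_kind)
  if (ncol(tab$counts) < 2) stop("degenerate table: need >= 2 genera")
  n <- nrow(tab$counts)
  if (n < max(k_range) + 1) stop("too few samples for requested k_range")
  D <- if (distance_kind == "jsd") jsd_matrix(tab) else bray_curtis(tab)
  fits <- lapply(k_range, function(k) pam_cluster(D, k, seed))
  ch <- vapply(fits, function(f) ch_index(D, f$assignments), numeric(1))
  names(ch) <- k_range
  k_opt <- k_range[which.max(ch)]
  best <- fits[[which.max(ch)]]
  # relabel clusters by decreasing size (ties: lower original label first)
  sizes <- table(best$assignments)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relab <- stats::setNames(seq_along(ord), names(sizes)[ord])
  assignments <- stats::setNames(
    as.integer(relab[as.character(best$assignments)]),
    names(best$assignments))
  structure(
    list(distance_kind = distance_kind,
         assignments = assignments,
         medoid_ids = best$medoid_ids[as.integer(names(sizes)[ord])],
         ch_curve = ch,
         k_opt = k_opt,
         cluster_sizes = as.integer(table(assignments)),
         distance = D),
    class = "enterotype_model")
}

#' @export
print.enterotype_model <- function(x, ...) {
  cat(sprintf("enterotype_model (%s distance): k_opt = %d, sizes = %s\n",
              x$distance_kind, x$k_opt, paste(x$cluster_sizes, collapse = "/")))
  cat("CH curve:\n"); print(round(x$ch_curve, 2))
  invisible(x)
}

#' Driver-genus ranking by random-forest importance
#'
#' Trains a random-forest classifier (enterotype ~ genus relative
#' abundances) under repeated k-fold cross-validation; for each fold the
#' forest is fit on the training folds and permutation importance (drop in
#' held-out accuracy when a genus column is permuted) is measured on the
#' held-out fold. Importance is the mean over folds and repeats, `cv_sd` the
#' between-repeat standard deviation.
#'
#' @param tab an [abundance_table()].
#' @param assignments cluster labels per sample (>= 2 clusters; every
#'   cluster needs at least `n_folds` members).
#' @param n_repeats CV repeats (default 99; means stabilize well below the
#'   999 sometimes used).
#' @param n_folds folds per repeat (default 10).
#' @param seed RNG seed.
#' @param n_trees trees per forest.
#' @return data.frame (genus_id, importance, rank, cv_sd), sorted by rank.
#' @export
rank_driver_genera <- function(tab, assignments, n_repeats = 99L, n_folds = 10L,
                               seed = 1L, n_trees = 100L) {
  X <- rel_abundance(tab)
  y <- as.integer(as.factor(assignments[rownames(X)]))
  k <- length(unique(y))
  if (k < 2) stop("need >= 2 clusters")
  if (min(table(y)) < n_folds) stop("each cluster needs >= n_folds samples")
  n <- nrow(X); p <- ncol(X)
  mtry <- max(1L, floor(sqrt(p)))
  set.seed(seed)
  per_repeat <- matrix(0, n_repeats, p)
  for (r in seq_len(n_repeats)) {
    fold <- sample(rep_len(seq_len(n_folds), n))
    acc <- matrix(0, n_folds, p)
    for (f in seq_len(n_folds)) {
      te <- fold == f
      imp <- rf_cv_importance(X[!te, , drop = FALSE], y[!te] - 1L,
                              X[te, , drop = FALSE], y[te] - 1L,
                              as.integer(n_trees), as.integer(mtry), 5L, k)
      acc[f, ] <- imp$importance
    }
    per_repeat[r, ] <- colMeans(acc)
  }
  importance <- colMeans(per_repeat)
  cv_sd <- apply(per_repeat, 2, stats::sd)
  ord <- order(-importance, colnames(X))
  data.frame(genus_id = colnames(X)[ord],
             importance = importance[ord],
             rank = seq_len(p),
             cv_sd = cv_sd[ord],
             stringsAsFactors = FALSE)
}
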