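#' Shrink proportions into the open unit interval
#'
#' Smithson-Verkuilen transform `y' = (y (n - 1) + 0.5) / n`, needed because
#' the Beta likelihood is undefined at exactly 0 or 1.
#'
#' @param y values in \[0, 1\].
#' @param n sample size used for the shrinkage (>= 2).
#' @return values strictly inside (0, 1).
#' @export
smooth_unit_interval <- function(y, n) {
  if (n < 2) stop("n must be >= 2")
  if (any(y < 0 | y > 1, na.rm = TRUE)) stop("y must lie in [0, 1]")
  (y * (n - 1) + 0.5) / n
}

beta_nll <- function(theta, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% theta[seq_len(p)])
  mu <- stats::plogis(eta)
  phi <- exp(theta[p + 1])
  a <- mu * phi; b <- (1 - mu) * phi
  -sum(lgamma(phi) - lgamma(a) - lgamma(b) +
         (a - 1) * log(y) + (b - 1) * log1p(-y))
}

beta_grad <- function(theta, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% theta[seq_len(p)])
  mu <- stats::plogis(eta)
  phi <- exp(theta[p + 1])
  a <- mu * phi; b <- (1 - mu) * phi
  dla <- -digamma(a) + log(y)
  dlb <- -digamma(b) + log1p(-y)
  dmu <- phi * (dla - dlb) * mu * (1 - mu)
  dphi <- digamma(phi) - mu * digamma(a) - (1 - mu) * digamma(b) +
    mu * log(y) + (1 - mu) * log1p(-y)
  -c(drop(crossprod(X, dmu)), phi * sum(dphi))
}

#' Beta regression with logit mean link
#'
#' Maximum likelihood under `y ~ Beta(mu * phi, (1 - mu) * phi)` with
#' `logit(mu) = X beta`; the design is enterotype + birthplace (either may
#' be dropped by passing `NULL`). Optimization is quasi-Newton (BFGS with
#' analytic gradient) on the unconstrained scale (`log phi`), with random
#' restarts; Wald standard errors come from the numerically observed
#' information at the optimum.
#'
#' @param y response strictly inside (0, 1) (see [smooth_unit_interval()]).
#' @param enterotype factor (the tested term).
#' @param birthplace optional factor covariate.
#' @param n_restarts total optimizer starts (first is moment-based; rest
#'   are jittered). Default 5.
#' @return list of class `beta_reg_fit`: `coefficients`, `phi`, `loglik`,
#'   `se`, `p` (named per term), `p_enterotype`, `converged`, `vcov`.
#' @export
fit_beta_regression <- function(y, enterotype, birthplace = NULL,
                                n_restarts = 5L) {
  df <- data.frame(enterotype = as.factor(enterotype))
  form <- ~ enterotype
  if (!is.null(birthplace)) {
    df$birthplace <- as.factor(birthplace)
    form <- ~ enterotype + birthplace
  }
  X <- stats::model.matrix(form, df)
  if (qr(X)$rank < ncol(X)) stop("design matrix not full rank")
  if (any(y <= 0 | y >= 1)) stop("y must be strictly inside (0, 1)")
  p <- ncol(X)
  # moment-based start
  beta0 <- stats::coef(stats::lm.fit(X, stats::qlogis(y)))
  mu0 <- stats::plogis(drop(X %*% beta0))
  v <- stats::var(y - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(v, 1e-8) - 1, 1)
  start <- c(beta0, log(phi0))
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    th <- if (r == 1) start else start + stats::rnorm(p + 1, 0, 0.5)
    fit <- tryCatch(
      stats::optim(th, beta_nll, beta_grad, X = X, y = y, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    if (r == 1 && !is.null(fit) && fit$convergence == 0) break
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE), class = "beta_reg_fit"))
  }
  H <- tryCatch(stats::optimHess(best$par, beta_nll, beta_grad, X = X, y = y),
                error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  se <- if (!is.null(V) && all(diag(V) > 0)) sqrt(diag(V)) else rep(NA_real_, p + 1)
  est <- best$par
  names(est) <- names(se) <- c(colnames(X), "log_phi")
  z <- est / se
  pv <- 2 * stats::pnorm(-abs(z))
  i_et <- grep("^enterotype", colnames(X))[1]
  structure(list(
    coefficients = est[seq_len(p)], phi = unname(exp(est[p + 1])),
    loglik = -best$value, se = se, p = pv,
    p_enterotype = unname(pv[i_et]),
    estimate_enterotype = unname(est[i_et]),
    se_enterotype = unname(se[i_et]),
    converged = best$convergence == 0 && all(is.finite(se)),
    vcov = V, n = length(y)), class = "beta_reg_fit")
}

#' Zero-inflated Beta regression (ZIBR)
#'
#' Mixture of a point mass at zero and a Beta density for the positive part:
#' `P(y = 0) = nu`, `y | y > 0 ~ Beta(mu phi, (1 - mu) phi)` with
#' `logit(nu) = Z gamma` (zero model) and `logit(mu) = X beta` (mean model).
#' The mixture log-likelihood factorizes, so the joint MLE is the logistic
#' MLE of the zero indicator plus the Beta MLE on the positive part; both
#' are reported with Wald tests on the enterotype terms. With no zeros the
#' function falls back to [fit_beta_regression()] (noted via `branch`).
#'
#' @param y response in \[0, 1) with some exact zeros; positive values
#'   should be strictly below 1 (exact ones are shrunk).
#' @param enterotype,birthplace model terms as in [fit_beta_regression()].
#' @param n_restarts passed to the Beta part.
#' @return list of class `zibr_fit`: `gamma` (zero-model coefficients with
#'   `se`/`p`), `beta_fit` (the positive-part `beta_reg_fit`), `loglik`,
#'   `p_enterotype_zero`, `p_enterotype_mean`, `branch`.
#' @export
fit_zibr <- function(y, enterotype, birthplace = NULL, n_restarts = 5L) {
  if (all(y == 0)) stop("all observations zero: ZIBR undefined")
  n <- length(y)
  y[y >= 1] <- smooth_unit_interval(y[y >= 1], n)
  if (!any(y == 0)) {
    fit <- fit_beta_regression(y, enterotype, birthplace, n_restarts)
    return(structure(list(gamma = NULL, beta_fit = fit, loglik = fit$loglik,
                          p_enterotype_zero = NA_real_,
                          p_enterotype_mean = fit$p_enterotype,
                          branch = "beta_fallback"), class = "zibr_fit"))
  }
  z <- as.integer(y == 0)
  df <- data.frame(z = z, enterotype = as.factor(enterotype))
  form <- z ~ enterotype
  if (!is.null(birthplace)) {
    df$birthplace <- as.factor(birthplace)
    form <- z ~ enterotype + birthplace
  }
  zfit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = df))
  zsm <- summary(zfit)$coefficients
  pos <- y > 0
  bfit <- fit_beta_regression(y[pos],
                              droplevels(as.factor(enterotype)[pos]),
                              if (is.null(birthplace)) NULL
                              else droplevels(as.factor(birthplace)[pos]),
                              n_restarts)
  ll <- as.numeric(stats::logLik(zfit)) +
    if (isTRUE(bfit$converged)) bfit$loglik else NA_real_
  i_et <- grep("^enterotype", rownames(zsm))[1]
  structure(list(
    gamma = data.frame(term = rownames(zsm), estimate = zsm[, 1],
                       se = zsm[, 2], p = zsm[, 4], row.names = NULL,
                       stringsAsFactors = FALSE),
    beta_fit = bfit, loglik = ll,
    p_enterotype_zero = zsm[i_et, 4],
    estimate_enterotype_zero = zsm[i_et, 1],
    p_enterotype_mean = bfit$p_enterotype,
    branch = "zibr"), class = "zibr_fit")
}

#' Two-part genus screening across enterotypes
#'
#' Routes each genus by prevalence (fraction of samples with nonzero
#' abundance): genera at or above `prevalence_cut` are fit with Beta
#' regression on shrunk relative abundances; rarer genera with zero-inflated
#' Beta regression. Enterotype p-values (mean model; plus zero model for the
#' ZIBR branch) are BH-adjusted across all converged tests, and each genus
#' is called significant when its smallest q is at or below `fdr`. Both the
#' raw `p < 0.05` and `q <= fdr` calls are reported.
#'
#' @param tab an [abundance_table()].
#' @param enterotype,birthplace factors aligned with the table's samples.
#' @param prevalence_cut routing threshold (default 0.60; equality routes
#'   to the Beta branch).
#' @param fdr FDR level (default 0.05).
#' @param n_restarts optimizer restarts per fit.
#' @return data.frame, one row per tested term (genus x term): genus,
#'   prevalence, branch, term, estimate, se, p, q, plus per-genus summary
#'   columns `sig_raw`, `sig_fdr` (computed on the genus-minimum p / q).
#' @export
screen_genera <- function(tab, enterotype, birthplace = NULL,
                          prevalence_cut = 0.60, fdr = 0.05,
                          n_restarts = 2L) {
  rel <- rel_abundance(tab)
  n <- nrow(rel)
  rows <- list()
  for (g in colnames(rel)) {
    y <- rel[, g]
    prev <- mean(y > 0)
    if (prev == 0) next
    if (prev >= prevalence_cut) {
      ys <- smooth_unit_interval(y, n)
      fit <- fit_beta_regression(ys, enterotype, birthplace, n_restarts)
      if (!isTRUE(fit$converged)) next
      rows[[length(rows) + 1L]] <- data.frame(
        genus = g, prevalence = prev, branch = "beta", term = "mean",
        estimate = fit$estimate_enterotype, se = fit$se_enterotype,
        p = fit$p_enterotype, stringsAsFactors = FALSE)
    } else {
      fit <- tryCatch(fit_zibr(y, enterotype, birthplace, n_restarts),
                      error = function(e) NULL)
      if (is.null(fit)) next
      if (!is.null(fit$gamma)) {
        rows[[length(rows) + 1L]] <- data.frame(
          genus = g, prevalence = prev, branch = "zibr", term = "zero",
          estimate = fit$estimate_enterotype_zero,
          se = fit$gamma$se[grep("^enterotype", fit$gamma$term)[1]],
          p = fit$p_enterotype_zero, stringsAsFactors = FALSE)
      }
      if (isTRUE(fit$beta_fit$converged)) {
        rows[[length(rows) + 1L]] <- data.frame(
          genus = g, prevalence = prev, branch = "zibr", term = "mean",
          estimate = fit$beta_fit$estimate_enterotype,
          se = fit$beta_fit$se_enterotype,
          p = fit$beta_fit$p_enterotype, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no genus could be tested")
  out$q <- bh_adjust(out$p)
  gm_p <- tapply(out$p, out$genus, min)
  gm_q <- tapply(out$q, out$genus, min)
  out$sig_raw <- gm_p[out$genus] < 0.05
  out$sig_fdr <- gm_q[out$genus] <= fdr
  rownames(out) <- NULL
  out
}
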