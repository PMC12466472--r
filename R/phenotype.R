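#' Derived performance traits
#'
#' Standard feedlot trait derivations over a `period_days` recording window:
#' * `ADG = (BW180 - BW80) / period` (kg/day)
#' * `ADFI = feed_intake / period` (kg/day)
#' * `FCR = ADFI / ADG` (set `NA` and flagged when `ADG <= 0`)
#' * `MBW = [0.5 (BW80 + BW180)]^0.75` (mid-test metabolic weight, kg^0.75)
#' * `BMI = BW180 / body_length^2` (kg/m^2, length in metres)
#' * `dressing_pct = carcass_weight / live_weight`
#' * relative fat weights on both the carcass-weight and live-weight
#'   denominators, when the fat fields are present.
#'
#' @param ph data.frame with at least `BW80`, `BW180` (kg); optionally
#'   `feed_intake` (total kg over the period), `body_length` (m),
#'   `carcass_weight`, `live_weight`, `tail_fat`, `perirenal_fat`,
#'   `omental_fat` (kg).
#' @param period_days length of the recording period (default 100).
#' @return data.frame of derived traits with a `fcr_flagged` logical column.
#' @export
derive_performance_traits <- function(ph, period_days = 100) {
  stopifnot(all(c("BW80", "BW180") %in% names(ph)))
  out <- data.frame(sample_id = if (!is.null(ph$sample_id)) ph$sample_id
                    else seq_len(nrow(ph)), stringsAsFactors = FALSE)
  out$ADG <- (ph$BW180 - ph$BW80) / period_days
  out$MBW <- (0.5 * (ph$BW80 + ph$BW180))^0.75
  if (!is.null(ph$feed_intake)) {
    out$ADFI <- ph$feed_intake / period_days
    out$FCR <- ifelse(out$ADG > 0, out$ADFI / out$ADG, NA_real_)
    out$fcr_flagged <- !(out$ADG > 0)
  }
  if (!is.null(ph$body_length)) out$BMI <- ph$BW180 / ph$body_length^2
  if (!is.null(ph$carcass_weight) && !is.null(ph$live_weight)) {
    out$dressing_pct <- ph$carcass_weight / ph$live_weight
    for (fat in c("tail_fat", "perirenal_fat", "omental_fat")) {
      if (!is.null(ph[[fat]])) {
        out[[paste0(fat, "_rel_carcass")]] <- ph[[fat]] / ph$carcass_weight
        out[[paste0(fat, "_rel_live")]] <- ph[[fat]] / ph$live_weight
      }
    }
  }
  out
}

#' Residual feed intake
#'
#' OLS of average daily feed intake on metabolic body weight and average
#' daily gain; RFI is the residual (lower = more efficient).
#'
#' @param derived data.frame with `ADFI`, `MBW`, `ADG` (e.g. from
#'   [derive_performance_traits()]).
#' @return numeric vector of residuals (named by `sample_id` when present).
#' @export
compute_rfi <- function(derived) {
  cc <- stats::complete.cases(derived[, c("ADFI", "MBW", "ADG")])
  if (sum(cc) < 3) stop("need ADFI, MBW, ADG for at least 3 animals")
  fit <- stats::lm(ADFI ~ MBW + ADG, data = derived[cc, ])
  if (fit$rank < 3) stop("collinear MBW/ADG: RFI regression rank deficient")
  rfi <- rep(NA_real_, nrow(derived))
  rfi[cc] <- stats::residuals(fit)
  if (!is.null(derived$sample_id)) names(rfi) <- derived$sample_id
  rfi
}

#' Benjamini-Hochberg adjustment
#' @param p numeric p-values (NA allowed, passed through).
#' @return BH-adjusted q-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Enterotype-phenotype association (per-trait linear model)
#'
#' For every trait column, fits `y = b0 + b1 Enterotype + b2 Birthplace + e`
#' by OLS, reports the enterotype contrast (t-test on `b1`) and adjusts
#' p-values across traits by Benjamini-Hochberg. Constant traits are skipped
#' (recorded in the `skipped` attribute).
#'
#' @param traits data.frame of numeric trait columns.
#' @param enterotype factor (or coercible) with >= 2 levels.
#' @param birthplace factor covariate; `NULL` drops the covariate.
#' @return data.frame (trait, term, estimate, se, statistic, p, q).
#' @export
enterotype_trait_assoc <- function(traits, enterotype, birthplace = NULL) {
  et <- droplevels(as.factor(enterotype))
  if (nlevels(et) < 2) stop("need >= 2 enterotype levels")
  skipped <- character(0)
  rows <- lapply(names(traits), function(tr) {
    y <- traits[[tr]]
    if (!is.numeric(y) || length(unique(y[!is.na(y)])) < 2) {
      skipped <<- c(skipped, tr); return(NULL)
    }
    df <- data.frame(y = y, enterotype = et)
    form <- y ~ enterotype
    if (!is.null(birthplace)) {
      df$birthplace <- droplevels(as.factor(birthplace))
      if (nlevels(df$birthplace) > 1) form <- y ~ enterotype + birthplace
    }
    sm <- summary(stats::lm(form, data = df))$coefficients
    i <- grep("^enterotype", rownames(sm))[1]
    data.frame(trait = tr, term = rownames(sm)[i], estimate = sm[i, 1],
               se = sm[i, 2], statistic = sm[i, 3], p = sm[i, 4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Chi-square test of enterotype vs a covariate
#'
#' Pearson chi-square (no continuity correction by default) on the full
#' contingency table, plus all pairwise two-level comparisons with BH
#' adjustment. Empty covariate levels are dropped with a warning.
#'
#' @param enterotype factor of enterotype labels.
#' @param covariate factor covariate.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with `chi2`, `df`, `p`, `table`, and `pairwise`
#'   (data.frame: level_a, level_b, chi2, p, q).
#' @export
covariate_chi_square <- function(enterotype, covariate, correct = FALSE) {
  et <- as.factor(enterotype); cv <- as.factor(covariate)
  tab <- table(cv, et)
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning(sprintf("dropping empty level(s): %s",
                    paste(rownames(tab)[empty], collapse = ", ")))
    tab <- tab[!empty, , drop = FALSE]
  }
  overall <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  lv <- rownames(tab)
  pw <- NULL
  if (length(lv) > 2) {
    combs <- utils::combn(lv, 2)
    pw <- data.frame(level_a = combs[1, ], level_b = combs[2, ],
                     chi2 = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(ncol(combs))) {
      sub <- tab[combs[, i], , drop = FALSE]
      ct <- suppressWarnings(stats::chisq.test(sub, correct = correct))
      pw$chi2[i] <- unname(ct$statistic); pw$p[i] <- ct$p.value
    }
    pw$q <- bh_adjust(pw$p)
  }
  list(chi2 = unname(overall$statistic), df = unname(overall$parameter),
       p = overall$p.value, table = tab, pairwise = pw)
}

#' Logistic regression of enterotype on a covariate
#'
#' One maximum-likelihood logit model per call (the per-covariate "Model
#' 1-4" convention); additional adjustment covariates may be supplied.
#' Perfect separation is flagged via the `converged` column.
#'
#' @param enterotype binary outcome (factor or 0/1).
#' @param covariate factor or numeric covariate of interest.
#' @param others optional data.frame of extra covariates.
#' @return data.frame of coefficients (term, estimate, se, statistic, p,
#'   converged).
#' @export
covariate_logistic <- function(enterotype, covariate, others = NULL) {
  y <- as.integer(as.factor(enterotype)) - 1L
  if (any(!y %in% c(0L, 1L))) stop("enterotype must be binary")
  df <- data.frame(y = y, covariate = covariate)
  form <- y ~ covariate
  if (!is.null(others)) {
    df <- cbind(df, others)
    form <- stats::as.formula(paste("y ~ covariate +",
                                    paste(names(others), collapse = " + ")))
  }
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = df))
  sm <- summary(fit)$coefficients
  converged <- fit$converged && all(abs(sm[, 1]) < 15) && all(sm[, 2] < 1e3)
  data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
             statistic = sm[, 3], p = sm[, 4], converged = converged,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Covariate collinearity diagnostics
#'
#' Spearman rank correlations between integer-coded covariates and, per
#' covariate model, the condition index of the column-scaled dummy design
#' matrix (largest / smallest singular value). Indices above 10 are
#' annotated as potential and above 30 as severe collinearity; nothing is
#' filtered.
#'
#' @param covariates data.frame of factors (>= 2 columns).
#' @return list with `spearman` (correlation matrix), `condition_index`
#'   (named vector: one joint model per covariate-left-out plus `all`),
#'   `annotation` (character: none/potential/severe).
#' @export
covariate_collinearity <- function(covariates) {
  if (ncol(covariates) < 2) stop("need >= 2 covariates")
  coded <- vapply(covariates, function(x) as.numeric(as.factor(x)),
                  numeric(nrow(covariates)))
  constant <- apply(coded, 2, function(x) length(unique(x)) < 2)
  sp <- matrix(NA_real_, ncol(coded), ncol(coded),
               dimnames = list(colnames(coded), colnames(coded)))
  ok <- !constant
  sp[ok, ok] <- stats::cor(coded[, ok, drop = FALSE], method = "spearman")
  ci_of <- function(df) {
    X <- stats::model.matrix(~ ., data = df)
    X <- sweep(X, 2, sqrt(colSums(X^2)), "/") # unit-length columns
    sv <- svd(X, nu = 0, nv = 0)$d
    max(sv) / max(min(sv), .Machine$double.eps)
  }
  ci <- c(vapply(names(covariates), function(nm)
    ci_of(covariates[, nm, drop = FALSE]), numeric(1)),
    all = ci_of(covariates))
  annotation <- cut(ci, c(-Inf, 10, 30, Inf),
                    labels = c("none", "potential", "severe"))
  list(spearman = sp, condition_index = ci,
       annotation = stats::setNames(as.character(annotation), names(ci)))
}
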