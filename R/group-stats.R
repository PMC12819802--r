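#' Covariate-adjusted two-group contrast
#'
#' Fits, per feature, the linear model `feature ~ group + covariates` by
#' least squares and reports the t statistic and two-sided p value of the
#' group coefficient. With no covariates this is algebraically the classic
#' pooled-variance two-sample t test. All features share one design matrix,
#' so the fit is a single QR decomposition.
#'
#' @param features Subjects x features numeric matrix (or data frame).
#' @param group Length-n vector with exactly two levels; the contrast is
#'   level 2 minus level 1 (alphabetical).
#' @param covariates Optional subjects x q data frame / matrix of numeric or
#'   factor covariates (e.g. age, sex).
#' @return A tibble (feature, estimate, t, df, p) with one row per feature.
#' @export
adjusted_group_contrast <- function(features, group, covariates = NULL) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  g <- factor(group)
  stop_not(nlevels(g) == 2, "`group` must have exactly two levels")
  stop_not(all(table(g) >= 3), "need at least 3 subjects per group")
  stop_not(nrow(x) == length(g), "features and group lengths differ")
  design <- stats::model.matrix(~g)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cv <- as.data.frame(covariates)
    cmat <- stats::model.matrix(~., data = cv)[, -1, drop = FALSE]
    design <- cbind(design, cmat)
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    abort(sprintf("design is rank deficient; collinear column(s): %s",
                  paste(dropped, collapse = ", ")))
  }
  cf <- qr.coef(qrd, x)
  res <- x - design %*% cf
  df <- nrow(x) - ncol(design)
  sigma2 <- colSums(res^2) / df
  v_group <- solve(crossprod(design))[2, 2]
  est <- cf[2, ]
  tval <- est / sqrt(v_group * sigma2)
  tibble(feature = colnames(x), estimate = unname(est), t = unname(tval),
         df = df, p = 2 * pt(-abs(unname(tval)), df))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH q values with monotonicity enforced. Optionally applied
#' separately within groups of features (e.g. per network).
#'
#' @param p Numeric vector of p values in \eqn{[0, 1]}.
#' @param by Optional grouping vector of the same length; BH is applied
#'   within each group.
#' @return Numeric q values, same length and order as `p`.
#' @export
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04))
fdr_bh <- function(p, by = NULL) {
  stop_not(all(p >= 0 & p <= 1, na.rm = TRUE), "p values must lie in [0, 1]")
  if (is.null(by)) return(p.adjust(p, method = "BH"))
  stop_not(length(by) == length(p), "`by` must match `p` in length")
  q <- rep(NA_real_, length(p))
  for (g in unique(by)) {
    i <- which(by == g)
    q[i] <- p.adjust(p[i], method = "BH")
  }
  q
}

# group t statistics for every feature after residualizing on covariates;
# vectorized for permutation reuse. Returns function(gres) -> |t| vector.
.maxstat_machinery <- function(features, group, covariates) {
  x <- as.matrix(features)
  g <- as.numeric(factor(group)) - 1
  n <- nrow(x)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cv <- stats::model.matrix(~., data = as.data.frame(covariates))
  } else {
    cv <- matrix(1, n, 1)
  }
  qz <- qr(cv)
  xres <- qr.resid(qz, x)
  gres <- qr.resid(qz, g)
  df <- n - ncol(cv) - 1
  xnorm <- sqrt(colSums(xres^2))
  list(
    gres = gres, df = df,
    tstat = function(gperm) {
      gn <- sqrt(sum(gperm^2))
      r <- as.vector(crossprod(xres, gperm)) / (xnorm * gn)
      r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
      abs(r * sqrt(df / (1 - r^2)))
    }
  )
}

#' Max-statistic permutation family-wise error control
#'
#' Freedman-Lane style permutation: group and features are residualized on
#' the covariates, group residuals are permuted, and the null distribution
#' of the maximum |t| across features is accumulated. The corrected p for
#' each feature is `(1 + #(null max >= observed |t|)) / (n_perm + 1)`.
#'
#' @param features Subjects x features matrix.
#' @param group Two-level group vector.
#' @param covariates Optional covariate data frame.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return A tibble (feature, t, p_corrected).
#' @export
maxstat_permutation <- function(features, group, covariates = NULL,
                                n_perm = 999, seed = 1L) {
  stop_not(n_perm >= 100, "`n_perm` must be >= 100")
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  mach <- .maxstat_machinery(x, group, covariates)
  obs <- mach$tstat(mach$gres)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      max(mach$tstat(sample(mach$gres)))
    }, numeric(1))
  })
  p_corr <- vapply(obs, function(t0) {
    (1 + sum(null_max >= t0)) / (n_perm + 1)
  }, numeric(1))
  tibble(feature = colnames(x), t = unname(obs),
         p_corrected = unname(p_corr))
}

#' Clinical correlation
#'
#' Pearson or Spearman correlation between a feature and a clinical
#' variable, with two-sided p. `method = "auto"` screens both variables with
#' a Shapiro-Wilk test and falls back to Spearman when either departs from
#' normality (p < 0.05).
#'
#' @param feature Numeric vector.
#' @param clinical Numeric vector of the same length.
#' @param method `"pearson"`, `"spearman"`, or `"auto"`.
#' @return A tibble (method, r, p, n).
#' @export
correlate_clinical <- function(feature, clinical,
                               method = c("pearson", "spearman", "auto")) {
  method <- match.arg(method)
  keep <- complete.cases(feature, clinical)
  x <- feature[keep]; y <- clinical[keep]
  stop_not(length(x) >= 5, "need at least 5 complete pairs")
  stop_not(sd(x) > 0 && sd(y) > 0, "zero variance in feature or clinical")
  if (method == "auto") {
    non_normal <- shapiro.test(x)$p.value < 0.05 ||
      shapiro.test(y)$p.value < 0.05
    method <- if (non_normal) "spearman" else "pearson"
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  tibble(method = method, r = unname(ct$estimate), p = ct$p.value,
         n = length(x))
}
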