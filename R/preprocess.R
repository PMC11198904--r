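# Count preprocessing: CPM filtering, TMM scaling factors, log2(CPM + 1)
# transformation with per-gene standardization, and covariate residualization.

#' Filter genes by counts-per-million support
#'
#' Retains exactly the genes with CPM strictly greater than `cpm_min` in at
#' least `min_samples` samples. CPM is computed against the column totals of
#' the input matrix, before any filtering.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param cpm_min CPM cutoff (strict inequality).
#' @param min_samples minimum number of samples at which the cutoff must hold.
#' @return the filtered counts matrix (all samples retained).
#' @export
cpm_filter <- function(counts, cpm_min = 1, min_samples) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (!is_count(min_samples) || min_samples > ncol(counts)) {
    stopf("min_samples must be an integer <= number of samples")
  }
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stopf("sample(s) with zero total counts: %s",
          paste(colnames(counts)[tot == 0] %||% which(tot == 0), collapse = ", "))
  }
  cpm <- sweep(counts, 2, tot, "/") * 1e6
  keep <- rowSums(cpm > cpm_min) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Trimmed-mean-of-M-values (TMM) scaling factors
#'
#' Between-sample normalization for count data. The reference sample is the
#' one whose upper-quartile CPM is closest to the mean upper-quartile. For
#' every other sample, per-gene log2 expression ratios to the reference
#' (M-values) are doubly trimmed -- the top and bottom `logratio_trim` by M and
#' `abs_trim` by average log intensity A -- and averaged with inverse
#' asymptotic-variance (delta-method) weights. The factor is 2 to that
#' weighted mean; factors are rescaled to geometric mean 1.
#'
#' @param counts filtered counts matrix (genes x samples, >= 2 samples).
#' @param logratio_trim two-sided trim fraction on M-values.
#' @param abs_trim two-sided trim fraction on A-values.
#' @return named numeric vector of positive per-sample factors. Normalized
#'   expression is count * 1e6 / (library size * factor).
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stopf("TMM needs at least 2 samples")
  lib <- colSums(counts)
  uq <- apply(counts, 2, stats::quantile, 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    ys <- counts[, s]; yr <- counts[, ref]
    ok <- ys > 0 & yr > 0
    if (!any(ok)) stopf("sample %s shares no expressed genes with the reference",
                        colnames(counts)[s] %||% s)
    ys <- ys[ok]; yr <- yr[ok]
    ps <- ys / lib[s]; pr <- yr / lib[ref]
    M <- log2(ps / pr)
    A <- 0.5 * log2(ps * pr)
    # delta-method variance of M; weights are its inverse
    v <- (lib[s] - ys) / (lib[s] * ys) + (lib[ref] - yr) / (lib[ref] * yr)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) return(1)
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Normalize, log-transform and standardize a counts matrix
#'
#' Values become log2(1 + count * 1e6 / (library size * factor)), then each
#' gene row is centered and scaled to zero mean, unit variance. Genes with
#' zero variance after transformation are removed with a warning.
#'
#' @param counts counts matrix. @param factors output of [tmm_factors()].
#' @return standardized expression matrix with attribute `state` set to
#'   `"standardized"` and attribute `removed_constant` listing dropped genes.
#' @export
normalize_log_standardize <- function(counts, factors) {
  counts <- as.matrix(counts)
  if (length(factors) != ncol(counts)) stopf("one factor per sample required")
  eff <- colSums(counts) * factors
  expr <- log2(1 + sweep(counts, 2, eff, "/") * 1e6)
  std <- standardize_rows(expr)
  constant <- attr(std, "constant")
  if (any(constant)) {
    warnf("%d constant gene(s) removed after normalization", sum(constant))
  }
  out <- std[!constant, , drop = FALSE]
  attr(out, "state") <- "standardized"
  attr(out, "removed_constant") <- rownames(counts)[constant]
  out
}

# Build the covariate design matrix: standardized age plus one-hot encodings.
# Missing ages are imputed to the mean, missing categories to the reference
# (first) level; all-missing columns are dropped with a warning.
covariate_design <- function(cov, sample_ids) {
  if (!all(sample_ids %in% cov$sample_id)) stopf("covariates missing for some samples")
  cov <- cov[match(sample_ids, cov$sample_id), , drop = FALSE]
  cols <- setdiff(names(cov), "sample_id")
  mats <- list()
  n_imputed <- 0L
  for (cl in cols) {
    v <- cov[[cl]]
    if (all(is.na(v))) { warnf("covariate '%s' is all-missing; dropped", cl); next }
    if (is.numeric(v)) {
      if (anyNA(v)) { n_imputed <- n_imputed + sum(is.na(v)); v[is.na(v)] <- mean(v, na.rm = TRUE) }
      s <- standardize_vec(v)
      if (!isTRUE(attr(s, "constant"))) mats[[cl]] <- matrix(as.numeric(s), ncol = 1,
                                                            dimnames = list(NULL, cl))
    } else {
      v <- as.character(v)
      lev <- sort(unique(v[!is.na(v)]))
      if (anyNA(v)) { n_imputed <- n_imputed + sum(is.na(v)); v[is.na(v)] <- lev[1] }
      if (length(lev) > 1) {
        m <- vapply(lev[-1], function(l) as.numeric(v == l), numeric(length(v)))
        colnames(m) <- paste(cl, lev[-1], sep = "_")
        mats[[cl]] <- m
      }
    }
  }
  if (n_imputed > 0) message(sprintf("imputed %d missing covariate value(s)", n_imputed))
  X <- do.call(cbind, c(list(`(Intercept)` = matrix(1, length(sample_ids), 1)), mats))
  colnames(X)[1] <- "(Intercept)"
  X
}

#' Residualize expression against sample covariates
#'
#' Per gene, ordinary least squares of expression on standardized age and
#' one-hot sex/ethnicity/race (with intercept); the output is the residual,
#' re-standardized per gene. Genes whose residual is constant (expression
#' exactly linear in covariates) are flagged in attribute `constant_residual`.
#'
#' @param expr standardized expression matrix (genes x samples).
#' @param cov data.frame with `sample_id`, `age`, `sex`, `ethnicity`, `race`
#'   (missing values allowed; any subset of columns works).
#' @return expression matrix with `state = "covariate_residual"`.
#' @export
residualize_covariates <- function(expr, cov) {
  expr <- as.matrix(expr)
  X <- covariate_design(cov, colnames(expr) %||% cov$sample_id)
  qx <- qr(X)
  resid <- t(qr.resid(qx, t(expr)))
  std <- standardize_rows(resid)
  constant <- attr(std, "constant")
  out <- ifelse(matrix(constant, nrow(std), ncol(std)), 0, std)
  dimnames(out) <- dimnames(expr)
  attr(out, "state") <- "covariate_residual"
  attr(out, "constant_residual") <- rownames(expr)[constant]
  out
}
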