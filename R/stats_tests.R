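# Statistical kernel: correlation thresholds, enrichment tails, distribution
# comparisons and multiple-testing corrections used throughout the pipeline.
# All tail probabilities go through R's log-space distribution functions so
# that extreme significance levels (log10 p < -300) remain reportable.

#' Pearson correlation matrix between two sets of expression profiles
#'
#' @param A,B numeric matrices with features in rows and the same samples in
#'   columns. If `B` is omitted, correlations among the rows of `A` are
#'   returned (symmetric, unit diagonal).
#' @return matrix of product-moment correlations, rows of `A` x rows of `B`.
#' @export
pearson_matrix <- function(A, B = NULL) {
  A <- as.matrix(A)
  check_rows <- function(m, label) {
    v <- apply(m, 1, stats::var)
    bad <- which(!is.finite(v) | v < 1e-300)
    if (length(bad)) {
      stopf("zero-variance row(s) in %s: %s", label,
            paste(rownames(m)[bad] %||% bad, collapse = ", "))
    }
  }
  check_rows(A, "A")
  if (is.null(B)) return(stats::cor(t(A)))
  B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stopf("A and B must share samples")
  check_rows(B, "B")
  stats::cor(t(A), t(B))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bonferroni-critical Pearson correlation threshold
#'
#' Smallest absolute correlation whose two-sided test p-value (t-statistic with
#' n - 2 degrees of freedom) is at or below `alpha / n_tests`. Obtained by
#' inverting t = r * sqrt((n - 2) / (1 - r^2)).
#'
#' @param n_samples number of paired observations (> 3).
#' @param n_tests number of correlations tested (Bonferroni denominator).
#' @param alpha family-wise significance level.
#' @return list with `threshold` (raw) and `threshold_2dp` (rounded as printed
#'   in figure captions).
#' @export
bonferroni_pcc_threshold <- function(n_samples, n_tests, alpha = 0.05) {
  if (n_samples <= 3) stopf("n_samples must exceed 3")
  if (n_tests < 1) stopf("n_tests must be >= 1")
  a <- alpha / n_tests
  if (a >= 1) {
    warnf("corrected alpha >= 1; threshold is 0")
    return(list(threshold = 0, threshold_2dp = 0))
  }
  df <- n_samples - 2
  tcrit <- stats::qt(1 - a / 2, df = df)
  r <- tcrit / sqrt(df + tcrit^2)
  list(threshold = r, threshold_2dp = round(r, 2))
}

#' Hypergeometric upper-tail enrichment test
#'
#' P(X >= k) for k draws of interest among n draws from a universe of N
#' containing K marked items; computed in log space.
#'
#' @param N universe size. @param K marked items. @param n draws.
#' @param k observed overlap.
#' @return list with `p_value`, `log10_p`, `parameters`, `method`.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  for (v in c(N, K, n, k)) if (!is_count(v)) stopf("parameters must be non-negative integers")
  if (K > N || n > N || k > min(K, n)) stopf("inconsistent hypergeometric parameters")
  lp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  list(statistic = k, p_value = exp(lp), log10_p = lp / log(10),
       parameters = c(N = N, K = K, n = n, k = k), method = "hypergeometric upper tail")
}

#' Exact binomial tail test
#'
#' @param k successes. @param n trials. @param p0 null success probability.
#' @param alternative "greater" (default) or "less".
#' @return list with `p_value`, `log10_p` (reported even when `p_value`
#'   underflows double precision), `parameters`, `method`.
#' @export
binomial_tail <- function(k, n, p0, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is_count(k) || !is_count(n) || k > n) stopf("need 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) stopf("p0 must be in (0, 1)")
  lp <- if (alternative == "greater") {
    stats::pbinom(k - 1, n, p0, lower.tail = FALSE, log.p = TRUE)
  } else {
    stats::pbinom(k, n, p0, lower.tail = TRUE, log.p = TRUE)
  }
  list(statistic = k, p_value = exp(lp), log10_p = lp / log(10),
       parameters = c(n = n, k = k, p0 = p0), method = paste("binomial tail,", alternative))
}

#' Ratio of two proportions with a companion Fisher exact p-value
#'
#' Returns (a/b) / (c/d) -- the "odds ratio" as printed in enrichment reports
#' comparing a subset hit fraction against a background hit fraction -- plus a
#' two-sided Fisher exact test on the 2x2 table (a, b - a; c, d - c).
#'
#' @param a,b hits and size of the foreground set.
#' @param c,d hits and size of the background set.
#' @export
proportion_ratio <- function(a, b, c, d) {
  if (b <= 0 || d <= 0) stopf("set sizes must be positive")
  if (a > b || c > d) stopf("hits cannot exceed set size")
  ratio <- (a / b) / (c / d)
  fp <- stats::fisher.test(matrix(c(a, b - a, c, d - c), nrow = 2))$p.value
  list(ratio = ratio, ratio_2dp = round(ratio, 2), fisher_p = fp)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param x,y numeric samples (length >= 2 each).
#' @return list with `D` and asymptotic two-sided `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stopf("both samples need >= 2 values")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Preranked enrichment score with a gene-permutation p-value
#'
#' Walks the ranking from top to bottom; hitting a set member increments the
#' running sum by |score|^w normalized over the set, a miss decrements by
#' 1 / (N - set size). The enrichment score is the extremum of the running sum,
#' and the p-value is the fraction of random set placements whose |ES| reaches
#' the observed |ES|.
#'
#' @param ids character ids sorted by decreasing score.
#' @param scores numeric scores aligned to `ids` (non-increasing).
#' @param gene_set character subset of `ids` (proper, non-empty).
#' @param weight_exponent exponent on |score| for hit increments (0 recovers
#'   the classical Kolmogorov-Smirnov running statistic).
#' @param n_perms permutations of set labels. @param seed RNG seed.
#' @export
preranked_enrichment <- function(ids, scores, gene_set, weight_exponent = 1,
                                 n_perms = 1000, seed = 1) {
  if (length(ids) != length(scores)) stopf("ids and scores must align")
  if (is.unsorted(rev(scores))) stopf("scores must be sorted in decreasing order")
  if (!length(gene_set)) stopf("gene set is empty")
  if (!all(gene_set %in% ids)) stopf("gene set contains ids absent from the ranking")
  if (length(gene_set) >= length(ids)) stopf("gene set must be a proper subset of the ranking")
  hit <- ids %in% gene_set
  es_of <- function(hit) {
    w <- abs(scores)^weight_exponent
    inc <- ifelse(hit, w, 0)
    tot <- sum(inc)
    if (tot == 0) inc[hit] <- 1  # all-zero scores: fall back to uniform hits
    tot <- sum(inc)
    step <- ifelse(hit, inc / tot, -1 / (length(ids) - sum(hit)))
    rs <- cumsum(step)
    rs[which.max(abs(rs))]
  }
  es <- es_of(hit)
  perm <- with_seed(seed, replicate(n_perms, {
    es_of(seq_along(ids) %in% sample.int(length(ids), sum(hit)))
  }))
  list(ES = es, p_value = mean(abs(perm) >= abs(es)), n_perms = n_perms)
}

#' Multiple-testing correction
#'
#' @param p numeric p-values in [0, 1].
#' @param method "bonferroni" or "bh" (Benjamini-Hochberg step-up).
#' @export
multiple_testing <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}
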