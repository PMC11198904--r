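# Per-target expression modeling: ElasticNet support selection, OLS refit with
# coefficient t-tests, 5-fold cross-validated test R-squared (selection re-run
# inside each training fold), and model-based residualization used to subtract
# transcription-factor effects before lncRNA modeling.

#' Select ~k predictors for a target by ElasticNet support-size targeting
#'
#' If there are `k_target` candidates or fewer, all are returned (the model is
#' then fit directly by OLS). Otherwise an ElasticNet path (mixing parameter
#' 0.5, geometric ladder of regularization strengths) is fit and the nonzero
#' support at the path point whose size is closest to `k_target` is returned;
#' ties go to the stronger regularization.
#'
#' @param y standardized response vector.
#' @param candidates matrix of candidate predictors, features x samples, with
#'   rownames as ids.
#' @param k_target desired support size.
#' @param exclude ids to remove from the candidate set (always includes the
#'   target itself at call sites).
#' @param seed unused by the deterministic gaussian path; kept so every model
#'   call site threads the pipeline seed.
#' @param alpha ElasticNet mixing parameter. @param nlambda path length.
#' @return character vector of selected ids, ordered by decreasing |coefficient|.
#' @export
select_predictors <- function(y, candidates, k_target = 10, exclude = character(),
                              seed = 1, alpha = 0.5, nlambda = 100) {
  if (stats::var(y) < 1e-12) stopf("target has zero variance")
  keep <- setdiff(rownames(candidates), exclude)
  if (!length(keep)) stopf("empty candidate set")
  X <- t(candidates[keep, , drop = FALSE])
  if (ncol(X) <= k_target) {
    return(colnames(X))
  }
  fit <- glmnet::glmnet(X, y, alpha = alpha, nlambda = nlambda,
                        standardize = FALSE, family = "gaussian")
  i <- which.min(abs(fit$df - k_target))  # first index = largest lambda on ties
  beta <- fit$beta[, i]
  sel <- beta[beta != 0]
  out <- names(sel)[order(abs(sel), decreasing = TRUE)]
  # the geometric path can jump past the target support size; keep the
  # strongest k_target so the model stays at "~k" predictors
  utils::head(out, k_target)
}

# Fast OLS with intercept on a samples x predictors matrix; returns what the
# pipeline needs (coefficients, t-test p-values, R2) without lm() overhead.
ols_core <- function(y, X) {
  n <- length(y)
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  qx <- qr(Xd)
  if (qx$rank < p) {
    bad <- colnames(Xd)[qx$pivot[(qx$rank + 1):p]]
    stopf("rank-deficient design; collinear columns: %s", paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, y)
  res <- y - Xd %*% coefs
  rss <- sum(res^2)
  df <- n - p
  sigma2 <- rss / df
  Rinv <- backsolve(qr.R(qx), diag(p))
  xtx_inv_diag <- rowSums(Rinv^2)[order(qx$pivot)]
  se <- sqrt(sigma2 * xtx_inv_diag)
  tval <- coefs / se
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  list(coefficients = coefs, se = se, p_values = pval,
       residuals = as.numeric(res), rss = rss, df = df,
       r2 = if (tss > 0) 1 - rss / tss else 0, fitted = as.numeric(Xd %*% coefs))
}

#' Fit the OLS refit model for a target gene
#'
#' Exact-duplicate predictor columns are dropped (with a warning) before the
#' fit; remaining rank deficiency is an error naming the collinear ids.
#'
#' @param y response vector. @param X_selected matrix predictors x samples with
#'   rownames as ids (may have zero rows: intercept-only model, R2 = 0).
#' @return a `model_fit` list: `target_id`, `predictor_ids`, `intercept`,
#'   `coefficients`, `coef_pvalues`, `overall_r2`, `n_samples`.
#' @export
ols_fit <- function(y, X_selected, target_id = NA_character_) {
  n <- length(y)
  if (is.null(dim(X_selected))) X_selected <- matrix(X_selected, nrow = 0)
  p <- nrow(X_selected)
  if (p > 0) {
    if (ncol(X_selected) != n) stopf("predictors and response must share samples")
    dup <- duplicated(lapply(seq_len(p), function(i) X_selected[i, ]))
    if (any(dup)) {
      warnf("dropping exact duplicate predictor(s): %s",
            paste(rownames(X_selected)[dup], collapse = ", "))
      X_selected <- X_selected[!dup, , drop = FALSE]
      p <- nrow(X_selected)
    }
  }
  if (n <= p + 1) stopf("need n > p + 1 (n = %d, p = %d)", n, p)
  if (p == 0) {
    fit <- list(coefficients = c(`(Intercept)` = mean(y)), p_values = c(`(Intercept)` = NA_real_),
                r2 = 0, residuals = y - mean(y), fitted = rep(mean(y), n))
    ids <- character()
  } else {
    fit <- ols_core(y, t(X_selected))
    ids <- rownames(X_selected)
  }
  structure(list(
    target_id = target_id,
    predictor_ids = ids,
    intercept = unname(fit$coefficients[1]),
    coefficients = unname(fit$coefficients[-1])[seq_along(ids)],
    coef_pvalues = unname(fit$p_values[-1])[seq_along(ids)],
    overall_r2 = max(0, fit$r2),
    residuals = fit$residuals,
    fitted = fit$fitted,
    n_samples = n
  ), class = "model_fit")
}

#' Cross-validated test R-squared for one target
#'
#' Seeded shuffle assigns samples to `folds` near-equal folds. Within each
#' fold, predictor selection and the OLS refit use only the training samples;
#' test R2 is 1 - SS_res / SS_tot on the held-out samples, centered at the
#' held-out mean (negative values preserved).
#'
#' @inheritParams select_predictors
#' @param folds number of cross-validation folds.
#' @return a `cv_result` list: `fold_test_r2`, `mean_test_r2`, `fold_selected`,
#'   `test_pcc` (pooled predicted-vs-observed correlation).
#' @export
cross_validated_r2 <- function(y, candidates, k_target = 10, folds = 5, seed = 1,
                               exclude = character(), target_id = NA_character_) {
  n <- length(y)
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  keep <- setdiff(rownames(candidates), exclude)
  if (!length(keep)) stopf("empty candidate set")
  cand <- candidates[keep, , drop = FALSE]
  preds <- numeric(n)
  fold_r2 <- numeric(folds)
  fold_sel <- vector("list", folds)
  for (f in seq_len(folds)) {
    te <- fold_id == f
    ytr <- y[!te]
    sel <- select_predictors(ytr, cand[, !te, drop = FALSE], k_target = k_target,
                             seed = derive_seed(seed, "cv_select", f))
    if (sum(!te) <= length(sel) + 1) stopf("fold %d too small for %d predictors", f, length(sel))
    fit <- ols_fit(ytr, cand[sel, !te, drop = FALSE], target_id = target_id)
    yhat <- if (length(fit$predictor_ids)) {
      fit$intercept + as.numeric(fit$coefficients %*% cand[fit$predictor_ids, te, drop = FALSE])
    } else rep(fit$intercept, sum(te))
    preds[te] <- yhat
    sst <- sum((y[te] - mean(y[te]))^2)
    fold_r2[f] <- 1 - sum((y[te] - yhat)^2) / sst
    fold_sel[[f]] <- sel
  }
  structure(list(
    target_id = target_id,
    fold_test_r2 = fold_r2,
    mean_test_r2 = mean(fold_r2),
    fold_selected = fold_sel,
    test_pcc = if (stats::sd(preds) > 0) stats::cor(preds, y) else NA_real_
  ), class = "cv_result")
}

#' Residualize a target against a fitted model's predictions
#'
#' Subtracts intercept + X * coefficients from `y` and re-standardizes the
#' residual so downstream coefficient magnitudes stay comparable. A residual
#' with (near-)zero variance is returned as all zeros and flagged constant.
#'
#' @param y response vector. @param fit a [ols_fit()] result.
#' @param X predictor matrix (features x samples) containing the fit's
#'   predictors, on the same samples as `y`.
#' @return standardized residual vector with attributes `state = "tf_residual"`
#'   and `constant`.
#' @export
residualize_by_model <- function(y, fit, X) {
  if (length(fit$predictor_ids)) {
    if (!all(fit$predictor_ids %in% rownames(X))) stopf("fit predictors missing from X")
    if (ncol(X) != length(y)) stopf("sample mismatch between y and X")
    pred <- fit$intercept + as.numeric(fit$coefficients %*% X[fit$predictor_ids, , drop = FALSE])
  } else {
    pred <- rep(fit$intercept, length(y))
  }
  r <- standardize_vec(y - pred)
  out <- if (isTRUE(attr(r, "constant"))) rep(0, length(y)) else as.numeric(r)
  structure(out, state = "tf_residual", constant = isTRUE(attr(r, "constant")))
}

#' Model a set of targets against a regulator class
#'
#' Orchestrates self-exclusion, ElasticNet selection, the OLS refit and
#' cross-validation for every target against either a named regulator class
#' (rows of `expr` given by `candidate_ids`) or per-target candidate lists.
#' Targets with zero candidates are recorded as unmodeled, not errors.
#'
#' @param target_ids character ids of targets (rows of `expr` or rows of
#'   `response` if given).
#' @param candidate_ids either a character vector (shared candidate pool) or a
#'   named list of per-target character vectors.
#' @param expr expression matrix containing all candidates (and targets unless
#'   `response` is supplied).
#' @param response optional matrix of response vectors per target (e.g.
#'   TF-residualized expression), genes x samples.
#' @param k_target,folds,seed modeling options.
#' @return list with `fits` (per-target `model_fit`), `cv` (per-target
#'   `cv_result`), and `table`, a long-format data.frame (one row per target x
#'   selected predictor; unmodeled targets appear with NA predictor).
#' @export
model_class <- function(target_ids, candidate_ids, expr, response = NULL,
                        k_target = 10, folds = 5, seed = 1) {
  fits <- list(); cvs <- list(); rows <- list()
  for (g in target_ids) {
    cand <- if (is.list(candidate_ids)) candidate_ids[[g]] else candidate_ids
    cand <- setdiff(cand, g)
    cand <- intersect(cand, rownames(expr))
    y <- if (is.null(response)) expr[g, ] else response[g, ]
    if (!length(cand) || stats::var(y) < 1e-12) {
      rows[[g]] <- data.frame(target_id = g, predictor_id = NA_character_,
                              coefficient = NA_real_, coef_p = NA_real_,
                              overall_r2 = NA_real_, mean_test_r2 = NA_real_,
                              n_candidates = length(cand), modeled = FALSE)
      next
    }
    gseed <- derive_seed(seed, "model_class", match(g, target_ids))
    sel <- select_predictors(y, expr[cand, , drop = FALSE], k_target = k_target, seed = gseed)
    fit <- ols_fit(y, expr[sel, , drop = FALSE], target_id = g)
    cv <- cross_validated_r2(y, expr[cand, , drop = FALSE], k_target = k_target,
                             folds = folds, seed = gseed, target_id = g)
    fits[[g]] <- fit; cvs[[g]] <- cv
    ids <- if (length(fit$predictor_ids)) fit$predictor_ids else NA_character_
    rows[[g]] <- data.frame(
      target_id = g, predictor_id = ids,
      coefficient = if (length(fit$predictor_ids)) fit$coefficients else NA_real_,
      coef_p = if (length(fit$predictor_ids)) fit$coef_pvalues else NA_real_,
      overall_r2 = fit$overall_r2, mean_test_r2 = cv$mean_test_r2,
      n_candidates = length(cand), modeled = TRUE)
  }
  list(fits = fits, cv = cvs, table = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Draw a seeded control pool of regulator ids
#'
#' Used for the enzyme-control analyses: a random candidate pool of the same
#' size as the true regulator pool, drawn without replacement.
#' @export
draw_control_pool <- function(pool_ids, size, seed) {
  if (size > length(pool_ids)) stopf("control pool smaller than requested size")
  with_seed(seed, sample(pool_ids, size))
}
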