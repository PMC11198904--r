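# ElasticNet selection, OLS refit, cross-validation and TF residualization.

test_that("selection passes through small candidate sets and finds planted signal", {
  X <- gaussian_predictors(5, 50, seed = 1)
  y <- as.numeric(scale(X[1, ] + rnorm(50)))
  expect_setequal(select_predictors(y, X, k_target = 10), rownames(X))
  # a strongly driving candidate is always selected
  found <- 0
  for (s in 1:20) {
    X <- gaussian_predictors(50, 400, seed = s)
    y <- as.numeric(scale(2 * X[3, ] + with_seed(1000 + s, rnorm(400, sd = 0.2))))
    if ("x3" %in% select_predictors(y, X, k_target = 10, seed = s)) found <- found + 1
  }
  expect_equal(found, 20)
  expect_error(select_predictors(rep(1, 50), gaussian_predictors(5, 50, 2)), "zero variance")
  expect_error(select_predictors(rnorm(50), gaussian_predictors(5, 50, 2),
                                 exclude = paste0("x", 1:5)), "empty candidate")
})

test_that("selection on pure noise stays sparse and has no predictive value", {
  r2s <- numeric(20); sizes <- numeric(20)
  for (s in 1:20) {
    X <- gaussian_predictors(50, 400, seed = 200 + s)
    y <- with_seed(300 + s, as.numeric(scale(rnorm(400))))
    sizes[s] <- length(select_predictors(y, X, k_target = 10, seed = s))
    r2s[s] <- cross_validated_r2(y, X, k_target = 10, seed = s)$mean_test_r2
  }
  expect_true(all(sizes <= 10))
  expect_lt(mean(r2s), 0.05)
  expect_gt(mean(r2s <= 0), 0.3)  # negative test R2 is common under the null
})

test_that("OLS refit matches hand least-squares and degenerate constructions", {
  # hand example: slope 6.5/5 = 1.3, intercept 0.8, R2 = 1.69*5/8.75
  fit <- ols_fit(c(1, 2, 3, 5), rbind(x = c(0, 1, 2, 3)))
  expect_equal(fit$coefficients, 1.3)
  expect_equal(fit$intercept, 0.8)
  expect_equal(fit$overall_r2, 1.69 * 5 / 8.75, tolerance = 1e-12)
  # y identical to a predictor
  y <- with_seed(4, rnorm(30))
  f2 <- ols_fit(y, rbind(self = y))
  expect_equal(f2$coefficients, 1, tolerance = 1e-10)
  expect_equal(f2$overall_r2, 1)
  expect_lt(f2$coef_pvalues, 1e-12)
  # y orthogonal to the predictor by construction
  x <- c(-1, 1, -1, 1, -1, 1)
  f3 <- ols_fit(c(1, 1, 0, 0, -1, -1), rbind(x = x))
  expect_equal(f3$coefficients, 0, tolerance = 1e-12)
  expect_equal(f3$overall_r2, 0, tolerance = 1e-12)
  # duplicates dropped; residual collinearity errors
  expect_warning(f4 <- ols_fit(y, rbind(a = x <- rnorm(30), b = x)), "duplicate")
  expect_equal(f4$predictor_ids, "a")
  expect_error(ols_fit(rnorm(30), rbind(a = z <- rnorm(30), b = 2 * z)), "collinear")
  expect_error(ols_fit(rnorm(3), gaussian_predictors(3, 3, 1)), "n > p")
})

test_that("OLS coefficient p-values match lm()'s t-tests", {
  X <- gaussian_predictors(4, 60, seed = 8)
  y <- as.numeric(0.7 * X[2, ] + with_seed(9, rnorm(60)))
  fit <- ols_fit(y, X)
  ref <- summary(lm(y ~ t(X)))$coefficients
  expect_equal(unname(fit$coef_pvalues), unname(ref[-1, 4]), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), unname(ref[-1, 1]), tolerance = 1e-10)
})

test_that("cross-validation reports honest held-out R2", {
  X <- gaussian_predictors(20, 200, seed = 30)
  y <- as.numeric(X[5, ])  # exactly linear, no noise
  cv <- cross_validated_r2(y, X, k_target = 5, seed = 1)
  expect_true(all(cv$fold_test_r2 > 0.999))
  expect_equal(cv$mean_test_r2, mean(cv$fold_test_r2))
  # folds partition the samples
  expect_error(cross_validated_r2(rnorm(10), gaussian_predictors(8, 10, 2),
                                  k_target = 8, folds = 5), "too small")
})

test_that("selection happens inside training folds only (no leakage)", {
  # deleting the held-out samples before selecting for a fold must reproduce
  # the fold's selection exactly
  X <- gaussian_predictors(30, 150, seed = 44)
  y <- as.numeric(scale(X[7, ] + with_seed(45, rnorm(150))))
  cv <- cross_validated_r2(y, X, k_target = 5, seed = 3)
  fold_id <- with_seed(3, sample(rep(1:5, length.out = 150)))
  for (f in c(1, 4)) {
    tr <- fold_id != f
    sel <- select_predictors(y[tr], X[, tr], k_target = 5,
                             seed = lncregnet:::derive_seed(3, "cv_select", f))
    expect_equal(cv$fold_selected[[f]], sel)
  }
})

test_that("model residualization subtracts fitted structure", {
  y <- with_seed(50, rnorm(80))
  X <- rbind(self = y)
  fit <- ols_fit(y, X)
  r <- residualize_by_model(y, fit, X)
  expect_true(attr(r, "constant"))
  expect_true(all(r == 0))
  # empty predictor set: residual is the centered response
  f0 <- ols_fit(y, matrix(numeric(0), 0, 80))
  r0 <- residualize_by_model(y, f0, X)
  expect_equal(as.numeric(r0), as.numeric(scale(y)), tolerance = 1e-10)
  expect_equal(attr(r0, "state"), "tf_residual")
})

test_that("TF residualization recovers the lncRNA variance share", {
  # y = tf + lnc + noise, all unit SD: lnc share of the TF-residual is
  # beta^2 / (beta^2 + 1) = 0.5
  deltas <- numeric(20)
  for (s in 1:20) {
    n <- 500
    tf <- with_seed(3 * s, rnorm(n)); lnc <- with_seed(3 * s + 1, rnorm(n))
    y <- tf + lnc + with_seed(3 * s + 2, rnorm(n))
    X <- rbind(TF1 = tf, LNC1 = lnc)
    fit <- ols_fit(y, X["TF1", , drop = FALSE])
    r <- residualize_by_model(y, fit, X)
    cv <- cross_validated_r2(as.numeric(r), X["LNC1", , drop = FALSE], k_target = 10, seed = s)
    deltas[s] <- cv$mean_test_r2
  }
  expect_true(all(abs(deltas - 0.5) < 0.1))
})

test_that("with standardized inputs the full-sample intercept is ~0", {
  X <- gaussian_predictors(10, 300, seed = 60)
  y <- as.numeric(scale(X[1, ] - X[2, ] + with_seed(61, rnorm(300))))
  sel <- select_predictors(y, X, k_target = 5)
  fit <- ols_fit(y, X[sel, , drop = FALSE])
  expect_lt(abs(fit$intercept), 1e-10)
  expect_gte(fit$overall_r2, cross_validated_r2(y, X, k_target = 5, seed = 1)$mean_test_r2 - 0.05)
})

test_that("planted regulators are recovered with correct signs", {
  hits <- 0
  for (s in 1:20) {
    n <- 500
    X <- gaussian_predictors(100, n, seed = 700 + s)
    y <- as.numeric(scale(X[10, ] - X[20, ] + with_seed(800 + s, rnorm(n))))
    sel <- select_predictors(y, X, k_target = 10, seed = s)
    if (all(c("x10", "x20") %in% sel)) {
      fit <- ols_fit(y, X[sel, , drop = FALSE])
      if (fit$coefficients[match("x10", fit$predictor_ids)] > 0 &&
          fit$coefficients[match("x20", fit$predictor_ids)] < 0) hits <- hits + 1
    }
  }
  expect_gte(hits, 18)
})

test_that("model_class orchestrates per-target modeling and bookkeeping", {
  b <- simulate_bundle(small_config(seed = 12))
  e <- preprocess_bundle(b)
  lnc <- intersect(b$annotation$gene_id[b$annotation$class == "lncRNA"], rownames(e))
  planted <- b$truth$lnc_edges$gene_id
  others <- setdiff(b$annotation$gene_id[b$annotation$class == "mRNA"], planted)
  targets <- intersect(c(planted[1:6], others[1:6]), rownames(e))
  res <- model_class(targets, lnc, e, k_target = 5, seed = 2)
  expect_true(all(res$table$target_id %in% targets))
  expect_true(all(res$table$overall_r2 >= 0 & res$table$overall_r2 <= 1, na.rm = TRUE))
  # a target with exactly one candidate yields a 1-predictor model
  one <- model_class(targets[1], lnc[1], e, k_target = 5, seed = 2)
  expect_equal(one$fits[[targets[1]]]$predictor_ids, lnc[1])
  # zero candidates: unmodeled record, no error
  none <- model_class(targets[1], character(), e, k_target = 5, seed = 2)
  expect_false(none$table$modeled)
  # control pool draw is seeded and sized
  pool <- draw_control_pool(letters, 5, seed = 9)
  expect_equal(pool, draw_control_pool(letters, 5, seed = 9))
  expect_length(pool, 5)
  expect_error(draw_control_pool(letters[1:3], 5, 1), "smaller")
})

test_that("targets with planted regulators are better modeled than those without", {
  b <- simulate_bundle(small_config(seed = 31))
  e <- preprocess_bundle(b)
  lnc <- intersect(b$annotation$gene_id[b$annotation$class == "lncRNA"], rownames(e))
  planted <- intersect(unique(b$truth$lnc_edges$gene_id), rownames(e))
  others <- setdiff(intersect(b$annotation$gene_id[b$annotation$class == "mRNA"],
                              rownames(e)), planted)
  res_p <- model_class(planted, lnc, e, k_target = 10, seed = 4)
  res_o <- model_class(others[seq_along(planted)], lnc, e, k_target = 10, seed = 4)
  r2_p <- vapply(res_p$cv, function(cv) cv$mean_test_r2, numeric(1))
  r2_o <- vapply(res_o$cv, function(cv) cv$mean_test_r2, numeric(1))
  expect_gt(mean(r2_p >= 0.2), mean(r2_o >= 0.2))
})
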