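# Empirical null distributions for cross-validated R-squared: control
# regulator sets (e.g. enzyme-encoding mRNAs or random lncRNA pools in place
# of the true candidates) and target-permutation nulls. Ties between observed
# and null values count toward the null (>=), so an empirical p of 0 requires
# that no control replicate matched the observed value.

#' Control-set empirical null for one target
#'
#' Each replicate draws `pool_size` control ids without replacement and runs
#' the identical select -> OLS -> CV pipeline on them; the empirical p-value
#' is the fraction of replicates whose mean test R2 meets or exceeds the
#' observed one (resolution 1 / n_reps).
#'
#' @param observed_r2 mean test R2 obtained with the true candidate class.
#' @param y response vector for the target (same state as the observed run).
#' @param expr expression matrix holding the control pool rows.
#' @param control_pool ids to draw from (must exclude the target and the true
#'   regulator class).
#' @param pool_size ids per replicate.
#' @param n_reps replicates. @param seed root seed; replicate r uses a seed
#'   derived from (seed, r).
#' @param k_target,folds modeling options, as for [cross_validated_r2()].
#' @param add_one use the (count + 1) / (n_reps + 1) estimator instead of
#'   count / n_reps (off by default; 0 is attainable).
#' @return `empirical_null` list: `observed_r2`, `null_r2`, `n_reps`,
#'   `empirical_p`.
#' @export
control_set_null <- function(observed_r2, y, expr, control_pool, pool_size,
                             n_reps = 100, seed = 1, k_target = 10, folds = 5,
                             target_id = NA_character_, add_one = FALSE) {
  if (pool_size > length(control_pool)) stopf("control pool smaller than pool_size")
  if (target_id %in% control_pool) stopf("target present in control pool")
  null_r2 <- vapply(seq_len(n_reps), function(r) {
    rseed <- derive_seed(seed, "control_rep", r)
    ids <- with_seed(rseed, sample(control_pool, pool_size))
    cv <- cross_validated_r2(y, expr[ids, , drop = FALSE], k_target = k_target,
                             folds = folds, seed = rseed, target_id = target_id)
    cv$mean_test_r2
  }, numeric(1))
  k <- sum(null_r2 >= observed_r2)
  structure(list(target_id = target_id, observed_r2 = observed_r2, null_r2 = null_r2,
                 n_reps = n_reps,
                 empirical_p = if (add_one) (k + 1) / (n_reps + 1) else k / n_reps),
            class = "empirical_null")
}

#' Target-permutation null distribution
#'
#' For each target and permutation, the target's expression vector is
#' shuffled by a seeded permutation (predictors untouched) and the full
#' select -> OLS -> CV pipeline re-run. Returns the pooled null R2
#' distribution with per-threshold tail counts.
#'
#' @param targets character target ids (rows of `response` or `expr`).
#' @param expr candidate expression matrix. @param candidate_ids candidate
#'   pool (self excluded per target).
#' @param response optional response matrix (defaults to `expr` rows).
#' @param n_perms permutations per target (>= 1).
#' @param thresholds R2 cutoffs for tail counts.
#' @param identity_perm if TRUE, use the identity permutation (testing hook:
#'   reproduces the observed statistic exactly).
#' @return list with `null_r2` (pooled), `per_target` data.frame, and
#'   `tail_counts`.
#' @export
permutation_null <- function(targets, expr, candidate_ids, response = NULL,
                             n_perms = 1, seed = 1, k_target = 10, folds = 5,
                             thresholds = c(0.1, 0.2), identity_perm = FALSE) {
  if (n_perms < 1) stopf("n_perms must be >= 1")
  rows <- list()
  for (g in targets) {
    y0 <- if (is.null(response)) expr[g, ] else response[g, ]
    cand <- setdiff(candidate_ids, g)
    for (p in seq_len(n_perms)) {
      pseed <- derive_seed(seed, paste0("perm_", g), p)
      y <- if (identity_perm) y0 else with_seed(pseed, y0[sample(length(y0))])
      cv <- cross_validated_r2(y, expr[cand, , drop = FALSE], k_target = k_target,
                               folds = folds, seed = pseed, target_id = g)
      rows[[paste(g, p)]] <- data.frame(target_id = g, perm = p, null_r2 = cv$mean_test_r2)
    }
  }
  per_target <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  pooled <- per_target$null_r2
  list(null_r2 = pooled, per_target = per_target,
       tail_counts = vapply(thresholds, function(t) sum(pooled >= t), numeric(1)) |>
         stats::setNames(paste0(">=", thresholds)))
}

#' Summarize how many targets pass the R2 and empirical-p gates
#'
#' @param mean_test_r2 named numeric vector of per-target CV R2.
#' @param empirical_p named numeric vector of per-target empirical p-values
#'   (aligned or name-matched).
#' @param r2_min,p_max gates (R2 >= r2_min, empirical p <= p_max).
#' @param chance_rate null passing rate for the binomial enrichment test.
#' @return list of counts, fractions and the binomial tail for the joint gate.
#' @export
threshold_summary <- function(mean_test_r2, empirical_p, r2_min = 0.2, p_max = 0.01,
                              chance_rate = 0.01) {
  if (!is.null(names(mean_test_r2)) && !is.null(names(empirical_p))) {
    empirical_p <- empirical_p[names(mean_test_r2)]
  }
  if (length(mean_test_r2) != length(empirical_p)) stopf("inputs must align")
  n <- length(mean_test_r2)
  pass_r2 <- mean_test_r2 >= r2_min
  pass_p <- empirical_p <= p_max
  both <- pass_r2 & pass_p
  bt <- binomial_tail(sum(both), n, chance_rate, alternative = "greater")
  list(n_targets = n,
       n_pass_r2 = sum(pass_r2), frac_pass_r2 = mean(pass_r2),
       n_pass_p = sum(pass_p), frac_pass_p = mean(pass_p),
       n_pass_both = sum(both), frac_pass_both = mean(both),
       binomial_p = bt$p_value, binomial_log10_p = bt$log10_p)
}
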