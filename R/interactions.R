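# lncRNA x protein statistical interaction discovery: forward Step-AIC
# selection of standardized product terms over a lncRNA + protein baseline
# model, Bonferroni correction over the per-target candidate count, and the
# median-split HH/HL/LH/LL contrast filter.

aic_gaussian <- function(rss, n, n_coef) n * log(rss / n) + 2 * (n_coef + 1)

#' Forward Step-AIC selection of lncRNA x protein interaction terms
#'
#' The baseline model contains all supplied lncRNA and protein main effects.
#' Candidate terms are all elementwise products lncRNA x protein,
#' standardized. At each step every remaining candidate is added to the
#' current model; the candidate with the lowest AIC (n ln(RSS/n) + 2(p+1)) is
#' admitted if it improves on the current AIC, otherwise selection stops.
#' The raw p-value of a term is its coefficient t-test p in the model at
#' admission; Bonferroni scope is the target's candidate count.
#'
#' @param y response (typically the TF-residualized target expression).
#' @param lnc_predictors,protein_predictors matrices, features x samples.
#' @param protein_class label stored on emitted terms ("TF" or "RBP").
#' @param max_terms cap on admitted terms.
#' @return list with `terms` (data.frame, one row per admitted term:
#'   lncrna_id, protein_id, coef, raw_p, bonferroni_p, aic_before, aic_after)
#'   and `fit` (final `model_fit`-style list with `overall_r2`,
#'   `baseline_r2`, `aic`).
#' @export
step_aic_interactions <- function(y, lnc_predictors, protein_predictors,
                                  protein_class = "TF", max_terms = 20) {
  n <- length(y)
  Xl <- t(lnc_predictors); Xp <- t(protein_predictors)
  base <- cbind(Xl, Xp)
  colnames(base) <- c(rownames(lnc_predictors), rownames(protein_predictors))
  if (n <= ncol(base) + 2) stopf("too few samples for the baseline model plus one term")
  cand <- expand.grid(lncrna_id = rownames(lnc_predictors),
                      protein_id = rownames(protein_predictors),
                      stringsAsFactors = FALSE)
  n_cand <- nrow(cand)
  prods <- matrix(0, n, n_cand)
  for (i in seq_len(n_cand)) {
    v <- Xl[, cand$lncrna_id[i]] * Xp[, cand$protein_id[i]]
    prods[, i] <- as.numeric(standardize_vec(v))
  }
  fit0 <- ols_core(y, base)
  cur_aic <- aic_gaussian(fit0$rss, n, ncol(base) + 1)
  baseline_r2 <- fit0$r2
  X <- base
  # forward steps by incremental orthogonalization: with candidates and the
  # response residualized against the current design, adding candidate c
  # changes RSS by (r_y . r_c)^2 / ||r_c||^2, and the admitted term's t-test
  # follows from the same partial regression -- identical statistics to
  # refitting the full design, at O(n) per candidate and step
  qb <- qr(cbind(1, base))
  r_y <- qr.resid(qb, y)
  R_c <- qr.resid(qb, prods)
  rss_cur <- sum(r_y^2)
  n_coef <- ncol(base) + 1
  remaining <- seq_len(n_cand)
  out <- list()
  while (length(remaining) && length(out) < max_terms && n > n_coef + 2) {
    d <- colSums(R_c[, remaining, drop = FALSE]^2)
    s <- as.numeric(crossprod(R_c[, remaining, drop = FALSE], r_y))
    rss_new <- rss_cur - ifelse(d > 1e-10, s^2 / d, 0)
    aics <- ifelse(d > 1e-10, aic_gaussian(rss_new, n, n_coef + 1), Inf)
    best <- which.min(aics)
    if (aics[best] >= cur_aic) break
    i <- remaining[best]
    df_new <- n - (n_coef + 1)
    tval <- s[best] / sqrt(d[best] * rss_new[best] / df_new)
    out[[length(out) + 1]] <- data.frame(
      lncrna_id = cand$lncrna_id[i], protein_id = cand$protein_id[i],
      protein_class = protein_class,
      coef = s[best] / d[best],
      raw_p = 2 * stats::pt(abs(tval), df = df_new, lower.tail = FALSE),
      aic_before = cur_aic, aic_after = aics[best])
    cur_aic <- aics[best]
    q <- R_c[, i]
    r_y <- r_y - (s[best] / d[best]) * q
    rss_cur <- rss_new[best]
    n_coef <- n_coef + 1
    X <- cbind(X, prods[, i])
    colnames(X)[ncol(X)] <- paste(cand$lncrna_id[i], cand$protein_id[i], sep = ":")
    remaining <- remaining[-best]
    if (length(remaining)) {
      proj <- as.numeric(crossprod(R_c[, remaining, drop = FALSE], q)) / sum(q^2)
      R_c[, remaining] <- R_c[, remaining, drop = FALSE] - outer(q, proj)
    }
  }
  terms <- if (length(out)) do.call(rbind, out) else data.frame(
    lncrna_id = character(), protein_id = character(), protein_class = character(),
    coef = numeric(), raw_p = numeric(), aic_before = numeric(), aic_after = numeric())
  if (nrow(terms)) terms$bonferroni_p <- pmin(1, terms$raw_p * n_cand)
  else terms$bonferroni_p <- numeric()
  final <- ols_core(y, X)
  list(terms = terms,
       fit = list(overall_r2 = max(0, final$r2), baseline_r2 = max(0, baseline_r2),
                  aic = cur_aic, n_candidates = n_cand,
                  predictor_ids = colnames(X)))
}

#' Median-split contrast table for one (target, lncRNA, protein) triplet
#'
#' Samples are split into HH/HL/LH/LL groups by whether the lncRNA and the
#' protein are above (strictly) or at-or-below their medians; medians come
#' from the analyzed samples and ties go to "low". Welch t-tests compare
#' target expression between groups for the five contrasts HH-HL, HH-LH,
#' HH-LL, HL-LL, LH-LL; direction is the sign of the mean difference.
#'
#' @param y target expression. @param lnc,protein regulator expression
#'   vectors, sample-aligned with `y`.
#' @param min_group groups smaller than this make the triplet not evaluable.
#' @return data.frame with one row per contrast: `contrast`, `direction`,
#'   `p`, plus attribute `evaluable` and `group_sizes`.
#' @export
median_split_contrasts <- function(y, lnc, protein, min_group = 3) {
  hl <- ifelse(lnc > stats::median(lnc), "H", "L")
  hp <- ifelse(protein > stats::median(protein), "H", "L")
  grp <- paste0(hl, hp)
  sizes <- vapply(c("HH", "HL", "LH", "LL"), function(g) sum(grp == g), numeric(1))
  contrasts <- list(c("HH", "HL"), c("HH", "LH"), c("HH", "LL"),
                    c("HL", "LL"), c("LH", "LL"))
  evaluable <- all(sizes >= min_group) && stats::var(y) > 0
  rows <- lapply(contrasts, function(cc) {
    if (!evaluable || stats::var(y[grp == cc[1]]) + stats::var(y[grp == cc[2]]) == 0) {
      return(data.frame(contrast = paste(cc, collapse = "-"), direction = NA_real_, p = NA_real_))
    }
    tt <- stats::t.test(y[grp == cc[1]], y[grp == cc[2]], var.equal = FALSE)
    data.frame(contrast = paste(cc, collapse = "-"),
               direction = sign(mean(y[grp == cc[1]]) - mean(y[grp == cc[2]])),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  attr(out, "evaluable") <- evaluable
  attr(out, "group_sizes") <- sizes
  out
}

#' Shortlist interaction triplets by significance and consistent contrasts
#'
#' Keeps triplets whose Bonferroni-corrected term p-value passes `p_term` and
#' whose HH-HL, HH-LH and HH-LL contrasts are all significant at `p_contrast`
#' with identical direction (all +1 or all -1).
#'
#' @param terms data.frame of admitted interaction terms (with `target_id`,
#'   `lncrna_id`, `protein_id`, `bonferroni_p`).
#' @param contrasts data.frame stacking [median_split_contrasts()] rows per
#'   triplet, keyed by target_id/lncrna_id/protein_id.
#' @param p_term gate on bonferroni_p (<=). @param p_contrast gate on the
#'   three HH contrasts (strict <).
#' @export
shortlist_triplets <- function(terms, contrasts, p_term = 0.05, p_contrast = 0.05) {
  if (!nrow(terms)) return(terms[0, , drop = FALSE])
  keep <- logical(nrow(terms))
  for (i in seq_len(nrow(terms))) {
    if (is.na(terms$bonferroni_p[i]) || terms$bonferroni_p[i] > p_term) next
    cc <- contrasts[contrasts$target_id == terms$target_id[i] &
                      contrasts$lncrna_id == terms$lncrna_id[i] &
                      contrasts$protein_id == terms$protein_id[i] &
                      contrasts$contrast %in% c("HH-HL", "HH-LH", "HH-LL"), ]
    if (nrow(cc) != 3 || anyNA(cc$p) || anyNA(cc$direction)) next
    keep[i] <- all(cc$p < p_contrast) && length(unique(cc$direction)) == 1 &&
      all(cc$direction != 0)
  }
  terms[keep, , drop = FALSE]
}

#' Frequency tables of regulators across significant interaction terms
#'
#' @param terms deduplicated (target, lncRNA, protein) term table.
#' @return list with `per_protein` and `per_lncrna` data.frames counting
#'   distinct targets (`n_genes`) and distinct partners (`n_partners`).
#' @export
regulator_frequency <- function(terms) {
  terms <- unique(terms[, c("target_id", "lncrna_id", "protein_id")])
  count_by <- function(key, partner) {
    if (!nrow(terms)) {
      return(data.frame(id = character(), n_genes = integer(), n_partners = integer()))
    }
    sp <- split(terms, terms[[key]])
    out <- data.frame(
      id = names(sp),
      n_genes = vapply(sp, function(d) length(unique(d$target_id)), integer(1)),
      n_partners = vapply(sp, function(d) length(unique(d[[partner]])), integer(1)))
    rownames(out) <- NULL
    out[order(-out$n_genes, out$id), ]
  }
  list(per_protein = count_by("protein_id", "lncrna_id"),
       per_lncrna = count_by("lncrna_id", "protein_id"))
}
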