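# Strong-pair table, evidence-gated multi-evidence network assembly, the
# co-expression baseline, external RNA-DNA support annotation, network
# summaries and the per-regulator sign-bias test.

#' Strong lncRNA-mRNA pair table
#'
#' Four gates, applied jointly: the target's CV R2 (>= r2_min), its empirical
#' p-value (<= emp_p_max... strict < when `emp_p_strict`), the predictor's
#' OLS coefficient p-value (<= ols_p_max) and the absolute pairwise
#' correlation (>= pcc_min). Pairs are annotated with their genomic category
#' flags and correlation sign, plus a per-category composition summary.
#'
#' @param fit_table long-format model table (target_id, predictor_id,
#'   coefficient, coef_p, mean_test_r2) from [model_class()].
#' @param empirical_p named per-target empirical p-values.
#' @param expr expression matrix used for the correlation filter.
#' @param annotation,tads genome context for category flags.
#' @param cerna_pairs optional [find_cerna_pairs()] `$pairs`.
#' @param r2_min,emp_p_max,ols_p_max,pcc_min the four gates.
#' @param emp_p_strict use strict < for the empirical-p gate.
#' @return list with `pairs` (annotated table) and `category_summary`
#'   (count and positive-correlation count per category).
#' @export
strong_pairs <- function(fit_table, empirical_p, expr, annotation, tads,
                         cerna_pairs = NULL, r2_min = 0.2, emp_p_max = 0.01,
                         ols_p_max = 1e-10, pcc_min = 0.1, emp_p_strict = TRUE,
                         proximal_dist = 1e6) {
  ft <- fit_table[!is.na(fit_table$predictor_id), , drop = FALSE]
  if (!nrow(ft)) return(list(pairs = ft, category_summary = NULL))
  ep <- empirical_p[ft$target_id]
  pass_emp <- if (emp_p_strict) ep < emp_p_max else ep <= emp_p_max
  keep <- !is.na(ft$mean_test_r2) & ft$mean_test_r2 >= r2_min &
    !is.na(ep) & pass_emp & ft$coef_p <= ols_p_max
  ft <- ft[keep, , drop = FALSE]
  if (!nrow(ft)) return(list(pairs = ft, category_summary = NULL))
  pcc <- vapply(seq_len(nrow(ft)), function(i) {
    stats::cor(expr[ft$predictor_id[i], ], expr[ft$target_id[i], ])
  }, numeric(1))
  ft$pcc <- pcc
  ft <- ft[abs(ft$pcc) >= pcc_min, , drop = FALSE]
  if (!nrow(ft)) return(list(pairs = ft, category_summary = NULL))
  fl <- classify_pairs(ft$predictor_id, ft$target_id, annotation, tads, proximal_dist)
  ft <- cbind(ft, fl[, c("overlapping", "same_tad", "proximal", "same_chrom",
                         "distance", "orientation")])
  ft$cerna <- FALSE
  if (!is.null(cerna_pairs) && nrow(cerna_pairs)) {
    key <- paste(ft$predictor_id, ft$target_id)
    ft$cerna <- key %in% paste(cerna_pairs$lncrna_id, cerna_pairs$gene_id)
  }
  ft$non_proximal <- !ft$proximal
  cats <- c("overlapping", "same_tad", "proximal", "same_chrom", "cerna", "non_proximal")
  summ <- data.frame(
    category = cats,
    n_pairs = vapply(cats, function(cc) sum(ft[[cc]]), numeric(1)),
    n_positive = vapply(cats, function(cc) sum(ft[[cc]] & ft$pcc > 0), numeric(1)))
  summ$frac_of_pairs <- summ$n_pairs / nrow(ft)
  rownames(ft) <- rownames(summ) <- NULL
  list(pairs = ft, category_summary = summ)
}

#' Assemble the multi-evidence regulatory network
#'
#' For each target, candidates are the lncRNAs that were statistically
#' significant in earlier per-class models (coef p <= sig_p) and hold at
#' least one evidence flag (location category, ceRNA, or an interaction
#' term). Those candidates are refit jointly by OLS; the target is retained
#' iff the refit overall R2 meets `r2_min`, and edges are the refit
#' coefficients with p <= coef_p_max.
#'
#' @param evidence data.frame with one row per (target_id, lncrna_id) holding
#'   logical columns `overlapping`, `same_tad`, `proximal`, `cerna`,
#'   `tf_interaction`, `rbp_interaction` (missing columns treated FALSE) and
#'   a `sig_p` column with the candidate's earlier-model coefficient p.
#' @param expr expression matrix for the refit (candidates).
#' @param response response matrix for targets (e.g. TF residuals); defaults
#'   to `expr`.
#' @param coef_p_max edge gate on refit coefficient p.
#' @param r2_min target retention gate on refit overall R2.
#' @param sig_p gate on the earlier-model coefficient p.
#' @return `lnc_network` list: `edges` data.frame (lncrna_id, target_id,
#'   coef, coef_p, sign, evidence flags), `skipped` targets, `n_candidates`.
#' @export
assemble_network <- function(evidence, expr, response = NULL, coef_p_max = 0.01,
                             r2_min = 0.2, sig_p = 0.01) {
  flags <- c("overlapping", "same_tad", "proximal", "cerna", "tf_interaction",
             "rbp_interaction")
  for (f in flags) if (is.null(evidence[[f]])) evidence[[f]] <- rep(FALSE, nrow(evidence))
  ev_any <- Reduce(`|`, lapply(flags, function(f) evidence[[f]]))
  ok <- ev_any & !is.na(evidence$sig_p) & evidence$sig_p <= sig_p
  evidence <- evidence[ok, , drop = FALSE]
  edges <- list(); skipped <- character(); ncand <- integer()
  for (g in unique(evidence$target_id)) {
    cand <- evidence[evidence$target_id == g, , drop = FALSE]
    cand <- cand[!duplicated(cand$lncrna_id), , drop = FALSE]
    ncand[g] <- nrow(cand)
    y <- if (is.null(response)) expr[g, ] else response[g, ]
    fit <- tryCatch(ols_fit(y, expr[cand$lncrna_id, , drop = FALSE], target_id = g),
                    error = function(e) NULL)
    if (is.null(fit) || fit$overall_r2 < r2_min) { skipped <- c(skipped, g); next }
    sig <- which(fit$coef_pvalues <= coef_p_max)
    if (!length(sig)) { skipped <- c(skipped, g); next }
    ids <- fit$predictor_ids[sig]
    m <- match(ids, cand$lncrna_id)
    edges[[g]] <- data.frame(
      lncrna_id = ids, target_id = g,
      coef = fit$coefficients[sig], coef_p = fit$coef_pvalues[sig],
      sign = sign(fit$coefficients[sig]),
      overall_r2 = fit$overall_r2,
      cand[m, flags, drop = FALSE], row.names = NULL)
  }
  edges <- if (length(edges)) do.call(rbind, c(edges, list(make.row.names = FALSE))) else
    data.frame(lncrna_id = character(), target_id = character(), coef = numeric(),
               coef_p = numeric(), sign = numeric(), overall_r2 = numeric())
  structure(list(edges = edges, skipped = skipped, n_candidates = ncand),
            class = "lnc_network")
}

#' Top-k co-expression baseline network
#'
#' The `k_edges` most correlated (|PCC|) lncRNA-mRNA pairs over the given id
#' sets; ties broken by lexicographic id order.
#'
#' @export
coexpression_baseline <- function(expr, lnc_ids, target_ids, k_edges) {
  if (!all(c(lnc_ids, target_ids) %in% rownames(expr))) stopf("ids missing from expr")
  cm <- pearson_matrix(expr[lnc_ids, , drop = FALSE], expr[target_ids, , drop = FALSE])
  df <- data.frame(lncrna_id = rep(lnc_ids, times = length(target_ids)),
                   target_id = rep(target_ids, each = length(lnc_ids)),
                   pcc = as.numeric(cm))
  df <- df[df$lncrna_id != df$target_id, , drop = FALSE]
  if (k_edges > nrow(df)) stopf("k_edges exceeds number of available pairs")
  df <- df[order(-abs(df$pcc), df$lncrna_id, df$target_id), , drop = FALSE]
  out <- df[seq_len(k_edges), , drop = FALSE]
  rownames(out) <- NULL
  out$mean_targets_per_lncrna <- nrow(out) / length(unique(out$lncrna_id))
  out
}

#' Annotate network edges with external RNA-DNA interaction support
#'
#' An edge is supported iff any interaction site of its lncRNA lies within
#' `window` bp of the target gene body (inclusive of the body itself).
#'
#' @param network `lnc_network`. @param rna_dna_pairs data.frame with
#'   `lncrna_id`, `chrom`, `start`, `end` interaction sites.
#' @param annotation gene annotation (for target bodies).
#' @param window support window in bp.
#' @export
annotate_external_support <- function(network, rna_dna_pairs, annotation, window = 1e6) {
  e <- network$edges
  sup <- logical(nrow(e))
  if (nrow(e)) for (i in seq_len(nrow(e))) {
    sites <- rna_dna_pairs[rna_dna_pairs$lncrna_id == e$lncrna_id[i], , drop = FALSE]
    if (!nrow(sites)) next
    g <- annotation[annotation$gene_id == e$target_id[i], ]
    sup[i] <- any(sites$chrom == g$chrom &
                    sites$start <= g$end + window &
                    sites$end >= g$start - window)
  }
  network$edges$external_support <- sup
  network$n_supported <- sum(sup)
  network
}

#' Summarize a regulatory network
#'
#' @param network `lnc_network` (or a bare edge data.frame with `lncrna_id`,
#'   `target_id`, `sign`).
#' @param hub_fraction a lncRNA is a hub if its out-degree exceeds this
#'   fraction of the network's targets.
#' @return list of edge/node counts, mean degrees (1 decimal as printed plus
#'   raw), activating/inhibitory counts and the hub list.
#' @export
network_summary <- function(network, hub_fraction = 0.1) {
  e <- if (inherits(network, "lnc_network")) network$edges else network
  if (!nrow(e)) stopf("empty network")
  out_deg <- table(e$lncrna_id)
  in_deg <- table(e$target_id)
  n_act <- if (!is.null(e$sign)) sum(e$sign > 0) else NA_integer_
  n_inh <- if (!is.null(e$sign)) sum(e$sign < 0) else NA_integer_
  hubs <- names(out_deg)[out_deg > hub_fraction * length(in_deg)]
  list(n_edges = nrow(e), n_lncrnas = length(out_deg), n_targets = length(in_deg),
       mean_out_degree = nrow(e) / length(out_deg),
       mean_out_degree_1dp = round(nrow(e) / length(out_deg), 1),
       mean_in_degree = nrow(e) / length(in_deg),
       mean_in_degree_1dp = round(nrow(e) / length(in_deg), 1),
       n_activating = n_act, n_inhibitory = n_inh,
       hubs = hubs[order(-out_deg[hubs])])
}

#' Per-lncRNA sign-bias test against the global activating fraction
#'
#' One-sided exact binomial tail of the lncRNA's activating edge count
#' against the network-wide activating fraction, sided toward the observed
#' departure.
#'
#' @param network `lnc_network` with signed edges. @param lncrna lncRNA id.
#' @param min_edges minimum out-degree for the test to be evaluable.
#' @return list with `direction` ("activating"/"inhibitory"), `p_value`,
#'   `k`, `n`, `global_fraction`; or `evaluable = FALSE` with a reason.
#' @export
sign_bias_test <- function(network, lncrna, min_edges = 5) {
  e <- if (inherits(network, "lnc_network")) network$edges else network
  p0 <- mean(e$sign > 0)
  if (p0 <= 0 || p0 >= 1) {
    return(list(evaluable = FALSE, reason = "degenerate global sign ratio"))
  }
  mine <- e[e$lncrna_id == lncrna, , drop = FALSE]
  n <- nrow(mine)
  if (n < min_edges) return(list(evaluable = FALSE, reason = "too few edges"))
  k <- sum(mine$sign > 0)
  side <- if (k / n >= p0) "greater" else "less"
  bt <- binomial_tail(k, n, p0, alternative = side)
  list(evaluable = TRUE,
       direction = if (side == "greater") "activating" else "inhibitory",
       p_value = bt$p_value, k = k, n = n, global_fraction = p0)
}
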