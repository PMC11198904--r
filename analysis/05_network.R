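#!/usr/bin/env Rscript

# Assemble the evidence-gated multi-evidence network, compare it with the
# top-|PCC| co-expression baseline, score it against the planted truth, and
# run the summary statistics (degrees, sign bias).

library(lncregnet)

expr <- as.matrix(read_counts_tsv("results/expression.tsv"))
resid <- as.matrix(read_counts_tsv("results/tf_residuals.tsv"))
ann <- read_annotation("results/sim/annotation.tsv")
tads <- read_bed3("results/sim/tads.bed")
lnc_tbl <- read_table_tsv("results/lnc_models.tsv")
pair_cat <- read_table_tsv("results/pair_categories.tsv")
terms <- tryCatch(read_table_tsv("results/interaction_terms.tsv"),
                  error = function(e) data.frame())
truth <- read_table_tsv("results/sim/truth_lnc_edges.tsv")
cfg <- analysis_config(seed = 1)

lt <- lnc_tbl[!is.na(lnc_tbl$predictor_id), ]
ev <- data.frame(target_id = lt$target_id, lncrna_id = lt$predictor_id,
                 sig_p = lt$coef_p)
m <- match(paste(ev$lncrna_id, ev$target_id),
           paste(pair_cat$lncrna_id, pair_cat$gene_id))
for (f in c("overlapping", "same_tad", "proximal", "cerna")) {
  ev[[f]] <- !is.na(m) & pair_cat[[f]][m]
}
key <- paste(ev$lncrna_id, ev$target_id)
for (pc in c("TF", "RBP")) {
  col <- if (pc == "TF") "tf_interaction" else "rbp_interaction"
  ev[[col]] <- if (nrow(terms)) key %in%
    paste(terms$lncrna_id[terms$protein_class == pc],
          terms$target_id[terms$protein_class == pc]) else FALSE
}

net <- assemble_network(ev, expr, response = resid,
                        coef_p_max = cfg$edge_coef_p, r2_min = cfg$r2_min,
                        sig_p = cfg$edge_coef_p)
write_table_tsv(net$edges, "results/network_edges.tsv")
s <- network_summary(net)
cat(sprintf("Network: %d edges, %d lncRNAs, %d targets (%.1f targets/lncRNA, %.1f regulators/target)\n",
            s$n_edges, s$n_lncrnas, s$n_targets, s$mean_out_degree_1dp,
            s$mean_in_degree_1dp))
cat(sprintf("  %d activating, %d inhibitory edges\n", s$n_activating, s$n_inhibitory))

truth_keys <- paste(truth$lncrna_id, truth$gene_id)
got_keys <- paste(net$edges$lncrna_id, net$edges$target_id)
cat(sprintf("  vs planted truth: precision %.2f, recall %.2f\n",
            mean(got_keys %in% truth_keys), mean(truth_keys %in% got_keys)))

base <- coexpression_baseline(expr, unique(net$edges$lncrna_id),
                              unique(net$edges$target_id),
                              k_edges = nrow(net$edges))
overlap <- sum(paste(base$lncrna_id, base$target_id) %in% got_keys)
cat(sprintf("  co-expression baseline with the same edge budget recovers %d of %d network edges;\n",
            overlap, nrow(net$edges)))
cat(sprintf("  baseline packs %.1f targets per lncRNA vs %.1f in the model-based network\n",
            base$mean_targets_per_lncrna[1], s$mean_out_degree_1dp))
write_table_tsv(base, "results/coexpression_baseline.tsv")

for (l in s$hubs) {
  sb <- sign_bias_test(net, l)
  if (isTRUE(sb$evaluable) && sb$p_value < 0.01) {
    cat(sprintf("  sign bias: %s is %s-biased (%d/%d, p = %.3g)\n",
                l, sb$direction, sb$k, sb$n, sb$p_value))
  }
}
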