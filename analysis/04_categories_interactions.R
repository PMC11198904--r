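#!/usr/bin/env Rscript

# Genomic categorization of selected lncRNA-target pairs, ceRNA detection
# from the miRNA interaction tables, and Step-AIC lncRNA x TF / lncRNA x RBP
# interaction discovery with median-split contrast verification.

library(lncregnet)

expr <- as.matrix(read_counts_tsv("results/expression.tsv"))
resid <- as.matrix(read_counts_tsv("results/tf_residuals.tsv"))
ann <- read_annotation("results/sim/annotation.tsv")
tads <- read_bed3("results/sim/tads.bed")
mirna <- read_table_tsv("results/sim/mirna_interactions.tsv")
lnc_tbl <- read_table_tsv("results/lnc_models.tsv")
tf_tbl <- read_table_tsv("results/tf_models.tsv")
cfg <- analysis_config(seed = 1)

lt <- lnc_tbl[!is.na(lnc_tbl$predictor_id), ]
pairs <- classify_pairs(lt$predictor_id, lt$target_id, ann, tads, cfg$proximal_dist)
cerna <- find_cerna_pairs(mirna[mirna$partner_class == "mRNA", ],
                          mirna[mirna$partner_class == "lncRNA", ])
pairs$cerna <- paste(pairs$lncrna_id, pairs$gene_id) %in%
  paste(cerna$pairs$lncrna_id, cerna$pairs$gene_id)
write_table_tsv(format_pair_table(pairs), "results/pair_categories.tsv")
cat(sprintf("Classified %d selected pairs: %d overlapping, %d same-TAD, %d proximal, %d ceRNA\n",
            nrow(pairs), sum(pairs$overlapping), sum(pairs$same_tad),
            sum(pairs$proximal), sum(pairs$cerna)))

# interactions for targets with both lncRNA and TF/RBP selections
cls <- split(ann$gene_id, ann$class)
rbp <- intersect(cls$RBP, rownames(expr))
rbp_models <- model_class(unique(lt$target_id), rbp, expr, response = resid,
                         k_target = cfg$k_predictors,
                         seed = lncregnet:::derive_seed(cfg$seed, "rbp_models"))
rows <- list(); contrasts <- list()
for (g in unique(lt$target_id)) {
  lsel <- lt$predictor_id[lt$target_id == g]
  tsel <- tf_tbl$predictor_id[tf_tbl$target_id == g & !is.na(tf_tbl$predictor_id)]
  rsel <- rbp_models$fits[[g]]$predictor_ids
  for (set in list(list(ids = tsel, class = "TF", gate = cfg$interaction_gate_tf),
                   list(ids = rsel, class = "RBP", gate = cfg$interaction_gate_rbp))) {
    if (!length(set$ids)) next
    st <- step_aic_interactions(resid[g, ], expr[lsel, , drop = FALSE],
                                expr[set$ids, , drop = FALSE],
                                protein_class = set$class)
    sig <- st$terms[!is.na(st$terms$bonferroni_p) & st$terms$bonferroni_p <= set$gate, ]
    if (!nrow(sig)) next
    rows[[paste(g, set$class)]] <- data.frame(target_id = g, sig)
    for (i in seq_len(nrow(sig))) {
      cc <- median_split_contrasts(resid[g, ], expr[sig$lncrna_id[i], ],
                                   expr[sig$protein_id[i], ])
      contrasts[[paste(g, i, set$class)]] <- data.frame(
        target_id = g, lncrna_id = sig$lncrna_id[i], protein_id = sig$protein_id[i], cc)
    }
  }
}
terms <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE))) else
  data.frame()
ctr <- if (length(contrasts)) do.call(rbind, c(contrasts, list(make.row.names = FALSE))) else
  data.frame()
write_table_tsv(terms, "results/interaction_terms.tsv")
write_table_tsv(ctr, "results/interaction_contrasts.tsv")
short <- if (nrow(terms)) shortlist_triplets(terms, ctr, p_term = cfg$interaction_gate_tf,
                                             p_contrast = cfg$contrast_p) else terms
write_table_tsv(short, "results/interaction_shortlist.tsv")
cat(sprintf("Significant interaction terms: %d (%d TF, %d RBP); %d pass the contrast filter\n",
            nrow(terms), sum(terms$protein_class == "TF"),
            sum(terms$protein_class == "RBP"), nrow(short)))
if (nrow(terms)) {
  freq <- regulator_frequency(terms)
  write_table_tsv(freq$per_protein, "results/interaction_protein_frequency.tsv")
}
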