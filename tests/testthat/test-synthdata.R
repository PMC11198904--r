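# Generator contracts: geometry of planted pairs, ground-truth structure,
# count-model oracles and determinism.

test_that("planted overlapping pairs intersect exactly as requested", {
  cfg <- sim_config(n_samples = 10, n_mrna = 5, n_lncrna = 5, n_tf = 2, n_rbp = 0,
                    n_enzyme = 0, n_mirna = 0, n_chrom = 2, chrom_length = 4e7,
                    pairs_per_category = c(overlapping = 2, same_tad = 0, proximal = 0,
                                           same_chrom = 0, trans = 0),
                    n_lnc_edges = 2, n_cerna = 0, n_interactions = 0, seed = 1)
  ga <- generate_annotation(cfg)
  ann <- ga$annotation
  lnc <- ann[ann$class == "lncRNA", ]; mr <- ann[ann$class == "mRNA", ]
  n_overlap <- 0
  for (i in seq_len(nrow(lnc))) for (j in seq_len(nrow(mr))) {
    if (lnc$chrom[i] == mr$chrom[j] && lnc$start[i] < mr$end[j] && mr$start[j] < lnc$end[i]) {
      n_overlap <- n_overlap + 1
    }
  }
  expect_equal(n_overlap, 2)
  expect_equal(nrow(attr(ann, "planted_pairs")), 2)
  # TADs tile without overlap
  for (ch in unique(ga$tads$chrom)) {
    t <- ga$tads[ga$tads$chrom == ch, ]
    expect_true(all(t$start[-1] == t$end[-nrow(t)]))
  }
})

test_that("planted category labels are consistent with coordinates", {
  cfg <- small_config(seed = 42)
  ga <- generate_annotation(cfg)
  pp <- attr(ga$annotation, "planted_pairs")
  flags <- truth_pair_flags(ga$annotation, ga$tads)
  key <- paste(flags$lncrna_id, flags$gene_id)
  for (i in seq_len(nrow(pp))) {
    fl <- flags[match(paste(pp$lncrna_id[i], pp$gene_id[i]), key), ]
    switch(pp$category[i],
      overlapping = expect_true(fl$overlapping),
      same_tad = { expect_true(fl$same_tad); expect_false(fl$overlapping) },
      proximal = { expect_true(fl$proximal); expect_false(fl$overlapping)
                   expect_false(fl$same_tad) },
      same_chrom = { expect_true(fl$same_chrom); expect_false(fl$proximal) },
      trans = expect_false(fl$same_chrom))
  }
})

test_that("cis fraction and sign rules shape the planted edges", {
  cfg0 <- small_config(seed = 5, frac_cis_regulators = 0)
  tr0 <- with(generate_annotation(cfg0), generate_truth(annotation, tads, cfg0))
  expect_false(any(tr0$lnc_edges$category %in% c("overlapping", "same_tad", "proximal")))
  cfg1 <- small_config(seed = 5, frac_cis_regulators = 1)  # 12 edges, 12 cis slots
  tr1 <- with(generate_annotation(cfg1), generate_truth(annotation, tads, cfg1))
  expect_true(all(tr1$lnc_edges$effect > 0))
  expect_true(all(tr1$lnc_edges$category %in% c("overlapping", "same_tad", "proximal")))
  # beta_lnc = 0: no planted lncRNA edges at all
  cfgz <- small_config(seed = 5, beta_lnc = 0)
  trz <- with(generate_annotation(cfgz), generate_truth(annotation, tads, cfgz))
  expect_null(trz$lnc_edges)
})

test_that("TF edge counting matches the configuration", {
  cfg <- sim_config(n_samples = 10, n_mrna = 50, n_lncrna = 0, n_tf = 5, n_rbp = 0,
                    n_enzyme = 0, n_mirna = 0, n_chrom = 2, chrom_length = 6e7,
                    pairs_per_category = c(overlapping = 0, same_tad = 0, proximal = 0,
                                           same_chrom = 0, trans = 0),
                    n_lnc_edges = 0, n_cerna = 0, n_interactions = 0,
                    n_tf_per_target = 2, seed = 3)
  tr <- with(generate_annotation(cfg), generate_truth(annotation, tads, cfg))
  mr <- tr$annotation$gene_id[tr$annotation$class == "mRNA"]
  expect_equal(sum(tr$tf_edges$target_id %in% mr), 100)  # 50 targets x 2 edges
})

test_that("the ground-truth graph is acyclic and cycles are rejected", {
  cfg <- small_config(seed = 8)
  tr <- with(generate_annotation(cfg), generate_truth(annotation, tads, cfg))
  expect_silent(lncregnet:::assert_truth_dag(tr))
  bad <- tr
  bad$tf_edges <- rbind(bad$tf_edges,
                        data.frame(tf_id = bad$tf_edges$target_id[1],
                                   target_id = bad$tf_edges$tf_id[1], effect = 1))
  expect_error(simulate_counts(bad, cfg), "cycle")
})

test_that("null counts carry no correlation structure beyond chance", {
  cfg <- sim_config(n_samples = 500, n_mrna = 10, n_lncrna = 10, n_tf = 2, n_rbp = 0,
                    n_enzyme = 0, n_mirna = 0, n_chrom = 2, chrom_length = 4e7,
                    pairs_per_category = c(overlapping = 0, same_tad = 0, proximal = 0,
                                           same_chrom = 0, trans = 2),
                    n_lnc_edges = 0, n_cerna = 0, n_interactions = 0,
                    beta_tf = 0, beta_lnc = 0, beta_interaction = 0,
                    covariate_effect = 0, nb_dispersion = 1e-4,
                    libsize_range = c(1, 1), seed = 17)
  b <- simulate_bundle(cfg)
  e <- suppressWarnings(normalize_log_standardize(b$counts, tmm_factors(b$counts)))
  cm <- pearson_matrix(e)
  offdiag <- abs(cm[upper.tri(cm)])
  n_pairs <- length(offdiag)  # 100+ gene pairs screened
  thr <- bonferroni_pcc_threshold(500, n_pairs)$threshold
  expect_lt(max(offdiag), thr)
})

test_that("a single planted edge reproduces the closed-form correlation", {
  # population PCC for y = b*x + e is b / sqrt(b^2 + 1) = 0.707 at b = 1
  cfg <- sim_config(n_samples = 500, n_mrna = 8, n_lncrna = 8, n_tf = 2, n_rbp = 0,
                    n_enzyme = 0, n_mirna = 0, n_chrom = 2, chrom_length = 4e7,
                    pairs_per_category = c(overlapping = 0, same_tad = 0, proximal = 0,
                                           same_chrom = 0, trans = 1),
                    n_lnc_edges = 1, frac_cis_regulators = 0, n_cerna = 0,
                    n_interactions = 0, beta_tf = 0, beta_lnc = 1,
                    covariate_effect = 0, nb_dispersion = 1e-3, seed = 23)
  b <- simulate_bundle(cfg)
  edge <- b$truth$lnc_edges
  expect_equal(nrow(edge), 1)
  r_latent <- cor(b$latent[edge$lncrna_id, ], b$latent[edge$gene_id, ])
  expect_lt(abs(abs(r_latent) - 1 / sqrt(2)), 0.1)
  e <- suppressWarnings(normalize_log_standardize(b$counts, tmm_factors(b$counts)))
  r_expr <- cor(e[edge$lncrna_id, ], e[edge$gene_id, ])
  expect_lt(abs(abs(r_expr) - 1 / sqrt(2)), 0.1)
  expect_equal(sign(r_expr), sign(edge$effect))
})

test_that("library size scales expected counts proportionally", {
  # regulatory effects off so no shared latent factor competes with depth
  cfg <- small_config(seed = 13, libsize_range = c(0.5, 2), nb_dispersion = 0.02,
                      beta_tf = 0, beta_lnc = 0, beta_interaction = 0,
                      covariate_effect = 0)
  b <- simulate_bundle(cfg)
  # median-of-ratios per-sample size factors track the drawn library factors
  ratios <- sweep(b$counts + 0.5, 1, rowMeans(b$counts + 0.5), "/")
  sf <- apply(ratios, 2, median)
  expect_gt(cor(sf, b$lib_factors), 0.95)
})

test_that("the generator is deterministic under a fixed seed", {
  b1 <- simulate_bundle(small_config(seed = 99))
  b2 <- simulate_bundle(small_config(seed = 99))
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$annotation, b2$annotation)
  expect_identical(b1$truth$lnc_edges, b2$truth$lnc_edges)
  b3 <- simulate_bundle(small_config(seed = 100))
  expect_false(identical(b1$counts, b3$counts))
})

test_that("config validation rejects invalid settings", {
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sim_config(frac_cis_regulators = 1.2), "frac_cis")
  expect_error(sim_config(libsize_range = c(2, 1)), "libsize_range")
  expect_error(sim_config(n_chrom = 1), "chromosomes")
  expect_error(generate_annotation(sim_config(chrom_length = 1e6, n_chrom = 2)),
               "too short")
})
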