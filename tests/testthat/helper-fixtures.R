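# Shared fixtures: small seeded bundles and matrices built in code.

small_config <- function(seed = 7, ...) {
  args <- list(n_samples = 150, n_mrna = 40, n_lncrna = 30, n_tf = 15, n_rbp = 8,
               n_enzyme = 15, n_mirna = 10, n_chrom = 4, chrom_length = 6e7,
               pairs_per_category = c(overlapping = 4, same_tad = 4, proximal = 4,
                                      same_chrom = 4, trans = 4),
               n_lnc_edges = 12, n_cerna = 5, n_interactions = 3, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# preprocessed expression for a bundle (suppresses the constant-gene warning)
preprocess_bundle <- function(bundle, min_frac = 0.41) {
  counts <- cpm_filter(bundle$counts, 1, ceiling(min_frac * ncol(bundle$counts)))
  e <- suppressWarnings(normalize_log_standardize(counts, tmm_factors(counts)))
  residualize_covariates(e, bundle$covariates)
}

# standardized gaussian predictor matrix, features x samples
gaussian_predictors <- function(p, n, seed, prefix = "x") {
  m <- with_seed(seed, matrix(rnorm(p * n), p, n))
  rownames(m) <- paste0(prefix, seq_len(p))
  t(scale(t(m)))
}

with_seed <- lncregnet:::with_seed
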