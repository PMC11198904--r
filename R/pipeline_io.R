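# Configuration, file formats and end-to-end orchestration. All tabular
# formats are plain TSV; GTF coordinates are converted from 1-based closed to
# the package's 0-based half-open convention on read.

#' Analysis configuration
#'
#' Houses the pipeline thresholds: ~10 predictors per model, 5-fold CV, 100
#' control replicates, CPM > 1 in at least a 0.41 fraction of samples,
#' 1 Mbp proximity, R2 >= 0.2 with empirical p <= 0.01, OLS p <= 1e-10 with
#' |PCC| >= 0.1 for strong pairs, edge coefficient p <= 0.01, and the
#' per-protein-class interaction gates (0.05 for TF, 0.01 for RBP).
#'
#' @export
analysis_config <- function(k_predictors = 10, folds = 5, n_null_reps = 100,
                            cpm_min = 1, min_samples_fraction = 0.41,
                            proximal_dist = 1e6, r2_min = 0.2, emp_p_max = 0.01,
                            strong_ols_p = 1e-10, pcc_min = 0.1, edge_coef_p = 0.01,
                            interaction_gate_tf = 0.05, interaction_gate_rbp = 0.01,
                            contrast_p = 0.05, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$folds >= 2, cfg$n_null_reps >= 1,
            cfg$min_samples_fraction >= 0, cfg$min_samples_fraction <= 1,
            cfg$r2_min >= 0, cfg$emp_p_max >= 0, cfg$emp_p_max <= 1)
  structure(cfg, class = "analysis_config")
}

#' Read/write an analysis configuration as YAML
#' @export
read_config <- function(path) do.call(analysis_config, yaml::read_yaml(path))

#' @rdname read_config
#' @export
write_config <- function(config, path) yaml::write_yaml(unclass(config), path)

#' Read and write counts matrices as TSV (gene rows, sample columns)
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a MatrixMarket counts matrix with gene/sample sidecar files
#'
#' `path` names the .mtx file; `<path>.genes` and `<path>.samples` hold one
#' id per line for rows and columns.
#' @export
read_counts_mtx <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  rownames(m) <- readLines(paste0(path, ".genes"))
  colnames(m) <- readLines(paste0(path, ".samples"))
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts_mtx
#' @export
write_counts_mtx <- function(counts, path) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
  writeLines(rownames(counts), paste0(path, ".genes"))
  writeLines(colnames(counts), paste0(path, ".samples"))
  invisible(path)
}

#' Export a network as GraphML (requires igraph)
#' @export
write_network_graphml <- function(network, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stopf("GraphML export requires the igraph package")
  }
  e <- if (inherits(network, "lnc_network")) network$edges else network
  g <- igraph::graph_from_data_frame(e[, c("lncrna_id", "target_id",
                                           setdiff(names(e), c("lncrna_id", "target_id")))],
                                     directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a gene annotation from TSV or GTF
#'
#' TSV needs columns gene_id, gene_name, class, chrom, start, end, strand
#' (already 0-based half-open). GTF gene lines are converted on read and the
#' biotype class taken from the `gene_biotype`/`gene_type` attribute.
#' @export
read_annotation <- function(path) {
  if (grepl("\\.gtf(\\.gz)?$", path)) return(read_annotation_gtf(path))
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "gene_name", "class", "chrom", "start", "end", "strand")
  if (!all(need %in% names(ann))) stopf("annotation needs columns: %s", paste(need, collapse = ", "))
  if (any(ann$start >= ann$end)) stopf("annotation interval with start >= end")
  if (anyDuplicated(ann$gene_id)) stopf("duplicate gene_id in annotation")
  ann
}

read_annotation_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) length(x) >= 9 && x[3] == "gene", logical(1))
  f <- f[keep]
  if (!length(f)) stopf("no gene lines in GTF")
  attr_get <- function(a, key) {
    m <- regmatches(a, regexec(paste0(key, ' "([^"]+)"'), a))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  rows <- lapply(f, function(x) {
    a <- x[9]
    data.frame(gene_id = attr_get(a, "gene_id"),
               gene_name = attr_get(a, "gene_name") %||% NA_character_,
               class = attr_get(a, "gene_biotype") %||% attr_get(a, "gene_type"),
               chrom = x[1],
               start = as.numeric(x[4]) - 1,  # 1-based closed -> 0-based half-open
               end = as.numeric(x[5]),
               strand = x[7])
  })
  do.call(rbind, rows)
}

#' @rdname read_annotation
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read/write BED3 intervals (TADs)
#' @export
read_bed3 <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  if (any(df$start >= df$end)) stopf("BED interval with start >= end")
  df
}

#' @rdname read_bed3
#' @export
write_bed3 <- function(df, path) {
  utils::write.table(df[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Generic TSV round-trip for pipeline tables
#' @export
read_table_tsv <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' @rdname read_table_tsv
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a GMT-style gene-set file (set name, description, ids...)
#' @export
read_gmt <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[`, character(1), 1))
}

#' Write a simulation bundle to disk as plain-text files
#'
#' counts TSV, annotation TSV, TAD BED3, miRNA interaction TSVs, covariate
#' TSV and (for test oracles) ground-truth edge TSVs.
#' @export
write_sim_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_counts_tsv(bundle$counts, file.path(outdir, "counts.tsv"))
  write_annotation(bundle$annotation, file.path(outdir, "annotation.tsv"))
  write_bed3(bundle$tads, file.path(outdir, "tads.bed"))
  write_table_tsv(bundle$covariates, file.path(outdir, "covariates.tsv"))
  write_table_tsv(rbind(bundle$truth$mirna_gene, bundle$truth$mirna_lnc),
                  file.path(outdir, "mirna_interactions.tsv"))
  if (!is.null(bundle$truth$lnc_edges)) {
    write_table_tsv(bundle$truth$lnc_edges, file.path(outdir, "truth_lnc_edges.tsv"))
  }
  if (!is.null(bundle$truth$tf_edges)) {
    write_table_tsv(bundle$truth$tf_edges, file.path(outdir, "truth_tf_edges.tsv"))
  }
  invisible(outdir)
}

#' Run the end-to-end analysis on an in-memory bundle
#'
#' Stages, in order: CPM filtering, TMM normalization + log + standardization,
#' covariate residualization, per-target TF models, TF residualization,
#' lncRNA models on the residuals, genomic categorization plus ceRNA
#' detection, lncRNA x TF and lncRNA x RBP Step-AIC interactions, and
#' evidence-gated network assembly. Returns every intermediate plus a run
#' report (config snapshot, stage record counts, seeds).
#'
#' @param bundle list with `counts`, `annotation`, `tads`, `covariates`,
#'   `mirna_gene`, `mirna_lnc` (as from [simulate_bundle()] + truth tables).
#' @param config an [analysis_config()].
#' @param targets optional subset of coding targets to model (default: all
#'   mRNA-class genes surviving preprocessing).
#' @param run_nulls whether to compute the control-set empirical null (the
#'   expensive stage; when FALSE `empirical_p` is NA and gates relying on it
#'   are skipped in the report).
#' @export
run_pipeline <- function(bundle, config = analysis_config(), targets = NULL,
                         run_nulls = FALSE, control_class = "enzyme") {
  ann <- bundle$annotation
  if (!any(ann$class == "lncRNA")) stopf("annotation contains no lncRNA class")
  report <- list(config = unclass(config), stages = list(), seed = config$seed)

  min_samples <- ceiling(config$min_samples_fraction * ncol(bundle$counts))
  counts <- cpm_filter(bundle$counts, cpm_min = config$cpm_min, min_samples = min_samples)
  report$stages$cpm_filter <- c(genes_in = nrow(bundle$counts), genes_kept = nrow(counts))
  factors <- tmm_factors(counts)
  expr <- normalize_log_standardize(counts, factors)
  expr <- residualize_covariates(expr, bundle$covariates)
  report$stages$preprocess <- c(genes = nrow(expr), samples = ncol(expr))

  cls <- split(ann$gene_id, ann$class)
  keep <- function(ids) intersect(ids, rownames(expr))
  lnc <- keep(cls$lncRNA); tfs <- keep(cls$TF); rbps <- keep(cls$RBP)
  if (is.null(targets)) targets <- keep(cls$mRNA)
  targets <- intersect(targets, rownames(expr))

  tf_models <- model_class(targets, tfs, expr, k_target = config$k_predictors,
                           folds = config$folds, seed = derive_seed(config$seed, "tf_models"))
  resid_mat <- matrix(0, length(targets), ncol(expr),
                      dimnames = list(targets, colnames(expr)))
  for (g in targets) {
    fit <- tf_models$fits[[g]]
    resid_mat[g, ] <- if (is.null(fit)) standardize_vec(expr[g, ]) else
      residualize_by_model(expr[g, ], fit, expr)
  }
  lnc_models <- model_class(targets, lnc, expr, response = resid_mat,
                            k_target = config$k_predictors, folds = config$folds,
                            seed = derive_seed(config$seed, "lnc_models"))
  report$stages$models <- c(targets = length(targets),
                            modeled = sum(!is.na(lnc_models$table$mean_test_r2)))

  mean_r2 <- vapply(targets, function(g) {
    cv <- lnc_models$cv[[g]]; if (is.null(cv)) NA_real_ else cv$mean_test_r2
  }, numeric(1))

  empirical_p <- stats::setNames(rep(NA_real_, length(targets)), targets)
  if (run_nulls) {
    pool <- keep(cls[[control_class]])
    for (g in targets) {
      if (is.na(mean_r2[g])) next
      nn <- control_set_null(mean_r2[g], resid_mat[g, ], expr, setdiff(pool, g),
                             pool_size = min(length(lnc), length(pool)),
                             n_reps = config$n_null_reps,
                             seed = derive_seed(config$seed, "null", match(g, targets)),
                             k_target = config$k_predictors, folds = config$folds,
                             target_id = g)
      empirical_p[g] <- nn$empirical_p
    }
  }

  cerna <- find_cerna_pairs(bundle$mirna_gene, bundle$mirna_lnc)
  pair_flags <- NULL
  lt <- lnc_models$table[!is.na(lnc_models$table$predictor_id), , drop = FALSE]
  if (nrow(lt)) {
    pair_flags <- classify_pairs(lt$predictor_id, lt$target_id, ann, bundle$tads,
                                 config$proximal_dist)
    key <- paste(pair_flags$lncrna_id, pair_flags$gene_id)
    pair_flags$cerna <- key %in% paste(cerna$pairs$lncrna_id, cerna$pairs$gene_id)
  }
  report$stages$genomics <- c(pairs_classified = if (is.null(pair_flags)) 0 else nrow(pair_flags),
                              cerna_pairs = nrow(cerna$pairs))

  inter_seed <- derive_seed(config$seed, "interactions")
  tf_terms <- list(); rbp_terms <- list()
  rbp_models <- model_class(targets, rbps, expr, response = resid_mat,
                            k_target = config$k_predictors, folds = config$folds,
                            seed = derive_seed(config$seed, "rbp_models"))
  for (g in targets) {
    lsel <- lnc_models$fits[[g]]$predictor_ids
    if (is.null(lsel) || !length(lsel)) next
    tsel <- tf_models$fits[[g]]$predictor_ids
    if (!is.null(tsel) && length(tsel)) {
      st <- step_aic_interactions(resid_mat[g, ], expr[lsel, , drop = FALSE],
                                  expr[tsel, , drop = FALSE], protein_class = "TF")
      if (nrow(st$terms)) tf_terms[[g]] <- data.frame(target_id = g, st$terms)
    }
    rsel <- rbp_models$fits[[g]]$predictor_ids
    if (!is.null(rsel) && length(rsel)) {
      sr <- step_aic_interactions(resid_mat[g, ], expr[lsel, , drop = FALSE],
                                  expr[rsel, , drop = FALSE], protein_class = "RBP")
      if (nrow(sr$terms)) rbp_terms[[g]] <- data.frame(target_id = g, sr$terms)
    }
  }
  bind_terms <- function(x) if (length(x)) do.call(rbind, c(x, list(make.row.names = FALSE))) else
    data.frame(target_id = character(), lncrna_id = character(), protein_id = character(),
               protein_class = character(), bonferroni_p = numeric())
  tf_terms <- bind_terms(tf_terms); rbp_terms <- bind_terms(rbp_terms)
  report$stages$interactions <- c(tf_terms = nrow(tf_terms), rbp_terms = nrow(rbp_terms))

  evidence <- build_evidence_table(lnc_models$table, pair_flags, tf_terms, rbp_terms,
                                   config)
  network <- assemble_network(evidence, expr, response = resid_mat,
                              coef_p_max = config$edge_coef_p, r2_min = config$r2_min,
                              sig_p = config$edge_coef_p)
  report$stages$network <- c(edges = nrow(network$edges),
                             targets = length(unique(network$edges$target_id)))

  list(expr = expr, resid = resid_mat, tf_models = tf_models, lnc_models = lnc_models,
       rbp_models = rbp_models, mean_r2 = mean_r2, empirical_p = empirical_p,
       cerna = cerna, pair_flags = pair_flags,
       tf_terms = tf_terms, rbp_terms = rbp_terms,
       evidence = evidence, network = network, report = report)
}

# Merge per-pair location/ceRNA flags and interaction-term membership into
# the evidence table consumed by assemble_network().
build_evidence_table <- function(lnc_table, pair_flags, tf_terms, rbp_terms, config) {
  lt <- lnc_table[!is.na(lnc_table$predictor_id), , drop = FALSE]
  if (!nrow(lt)) {
    return(data.frame(target_id = character(), lncrna_id = character(), sig_p = numeric()))
  }
  ev <- data.frame(target_id = lt$target_id, lncrna_id = lt$predictor_id,
                   sig_p = lt$coef_p)
  if (!is.null(pair_flags)) {
    m <- match(paste(ev$lncrna_id, ev$target_id),
               paste(pair_flags$lncrna_id, pair_flags$gene_id))
    for (f in c("overlapping", "same_tad", "proximal", "cerna")) {
      ev[[f]] <- !is.na(m) & pair_flags[[f]][m]
    }
  }
  ev$tf_interaction <- paste(ev$lncrna_id, ev$target_id) %in%
    paste(tf_terms$lncrna_id[tf_terms$bonferroni_p <= config$interaction_gate_tf],
          tf_terms$target_id[tf_terms$bonferroni_p <= config$interaction_gate_tf])
  ev$rbp_interaction <- paste(ev$lncrna_id, ev$target_id) %in%
    paste(rbp_terms$lncrna_id[rbp_terms$bonferroni_p <= config$interaction_gate_rbp],
          rbp_terms$target_id[rbp_terms$bonferroni_p <= config$interaction_gate_rbp])
  ev
}

#' Write a JSON run report
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
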