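# Seeded synthetic genomes, regulatory ground truth and count matrices with
# the statistical structure the pipeline assumes: negative-binomial counts
# over a latent log-linear model, TF-driven co-regulation of lncRNA-mRNA pairs
# (the confounding the pipeline must remove), planted cis-located lncRNA
# regulators with predominantly positive effects, ceRNA triplets,
# lncRNA x protein interaction effects, and nuisance covariate effects.

#' Simulation configuration
#'
#' @param n_samples samples to simulate.
#' @param n_mrna,n_lncrna,n_tf,n_rbp,n_enzyme,n_mirna genes per biotype class.
#' @param n_chrom chromosomes. @param chrom_length chromosome length (bp).
#' @param tad_size mean TAD width (bp); TADs tile each chromosome.
#' @param pairs_per_category planted lncRNA-mRNA pairs per geometric category
#'   (named: overlapping, same_tad, proximal, same_chrom, trans).
#' @param frac_cis_regulators fraction of planted lncRNA regulatory edges
#'   drawn from cis-located planted pairs (positive effect sign); the rest are
#'   trans/distal with random sign.
#' @param n_lnc_edges planted direct lncRNA->target edges.
#' @param n_tf_per_target TF parents per coding gene.
#' @param n_tf_per_lnc,beta_tf_lnc TF parents per lncRNA and their effect
#'   size (default: same as coding genes). These control how much of each
#'   lncRNA's variance is TF-driven -- the depth of the confounding the
#'   pipeline must remove from the lncRNA channel itself.
#' @param n_cerna ceRNA triplets planted on trans lncRNA edges.
#' @param n_interactions lncRNA x protein product-effect triplets.
#' @param beta_tf,beta_lnc,beta_interaction effect sizes in SD units of the
#'   latent log-expression.
#' @param nb_dispersion negative-binomial dispersion (> 0; near 0 ~ Poisson).
#' @param libsize_range low/high relative library-size multipliers.
#' @param covariate_effect age-effect size (SD units).
#' @param seed root RNG seed.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 300, n_mrna = 150, n_lncrna = 60, n_tf = 40,
                       n_rbp = 20, n_enzyme = 30, n_mirna = 20,
                       n_chrom = 5, chrom_length = 6e7, tad_size = 1e6,
                       pairs_per_category = c(overlapping = 8, same_tad = 8,
                                              proximal = 8, same_chrom = 8, trans = 8),
                       frac_cis_regulators = 0.5, n_lnc_edges = 24,
                       n_tf_per_target = 2, n_tf_per_lnc = n_tf_per_target,
                       beta_tf_lnc = NULL, n_cerna = 10, n_interactions = 6,
                       beta_tf = 1, beta_lnc = 1, beta_interaction = 1,
                       nb_dispersion = 0.05, libsize_range = c(0.7, 1.3),
                       covariate_effect = 0.3, seed = 1) {
  cfg <- as.list(environment())
  cfg$n_tf_per_lnc <- n_tf_per_lnc  # force promise before validation
  if (is.null(cfg$beta_tf_lnc)) cfg$beta_tf_lnc <- cfg$beta_tf
  counts <- c(cfg$n_samples, cfg$n_mrna, cfg$n_lncrna, cfg$n_tf, cfg$n_rbp,
              cfg$n_enzyme, cfg$n_mirna, cfg$n_chrom)
  if (!all(vapply(counts, is_count, logical(1)))) stopf("counts must be non-negative integers")
  if (cfg$frac_cis_regulators < 0 || cfg$frac_cis_regulators > 1) {
    stopf("frac_cis_regulators must be in [0, 1]")
  }
  if (cfg$nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
  if (length(cfg$libsize_range) != 2 || any(cfg$libsize_range <= 0) ||
      cfg$libsize_range[1] > cfg$libsize_range[2]) {
    stopf("libsize_range must be an increasing pair of positive reals")
  }
  req <- c("overlapping", "same_tad", "proximal", "same_chrom", "trans")
  if (!all(req %in% names(cfg$pairs_per_category))) {
    stopf("pairs_per_category needs entries: %s", paste(req, collapse = ", "))
  }
  npairs <- sum(cfg$pairs_per_category)
  if (npairs > cfg$n_lncrna || npairs > cfg$n_mrna) {
    stopf("planted pairs exceed available lncRNAs or mRNAs")
  }
  if (cfg$pairs_per_category[["trans"]] > 0 && cfg$n_chrom < 2) {
    stopf("trans pairs need at least 2 chromosomes")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic gene annotation and TAD set
#'
#' Genes are placed on `n_chrom` chromosomes. The configured number of
#' lncRNA-mRNA pairs are constructed with exact geometric relations:
#' overlapping (cycling through tandem / convergent / divergent strand
#' arrangements), same-TAD (5' ends in one TAD, no overlap), proximal
#' (< 1 Mbp gap across a TAD boundary), same-chromosome-distal (> 1 Mbp gap)
#' and trans (different chromosomes). TADs tile each chromosome without
#' overlap. Remaining genes are placed with randomized lengths and gaps.
#'
#' @param config a [sim_config()].
#' @return list with `annotation` (data.frame: gene_id, gene_name, class,
#'   chrom, start, end, strand; 0-based half-open) carrying attribute
#'   `planted_pairs`, and `tads` (data.frame: chrom, start, end).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "annotation"), {
    chroms <- paste0("chr", seq_len(config$n_chrom))
    tads <- do.call(rbind, lapply(chroms, function(ch) {
      s <- seq(0, config$chrom_length - 1, by = config$tad_size)
      data.frame(chrom = ch, start = s, end = pmin(s + config$tad_size, config$chrom_length))
    }))
    ids <- list(
      lncRNA = sprintf("LNC%04d", seq_len(config$n_lncrna)),
      mRNA = sprintf("GENE%04d", seq_len(config$n_mrna)),
      TF = sprintf("TF%04d", seq_len(config$n_tf)),
      RBP = sprintf("RBP%04d", seq_len(config$n_rbp)),
      enzyme = sprintf("ENZ%04d", seq_len(config$n_enzyme)),
      miRNA = sprintf("MIR%04d", seq_len(config$n_mirna)))

    ppc <- config$pairs_per_category
    tad <- config$tad_size
    placed <- list()
    add <- function(id, class, chrom, start, end, strand) {
      placed[[length(placed) + 1]] <<- data.frame(
        gene_id = id, gene_name = paste0(id, "_nm"), class = class,
        chrom = chrom, start = start, end = end, strand = strand)
    }
    cursor <- stats::setNames(rep(2 * tad, config$n_chrom), chroms)  # per-chrom placement cursor
    next_chrom <- local({ i <- 0; function() { i <<- i + 1; chroms[(i - 1) %% length(chroms) + 1] } })
    bump <- function(ch, width) {
      if (cursor[ch] + width >= config$chrom_length) {
        stopf("chromosome %s too short for requested planted genes", ch)
      }
      at <- cursor[ch]; cursor[ch] <<- cursor[ch] + width + 2.6e6
      at
    }
    li <- 0; mi <- 0
    pairs <- list()
    plant <- function(category, lnc_fun) {
      for (j in seq_len(ppc[[category]])) {
        li <<- li + 1; mi <<- mi + 1
        lnc_fun(ids$lncRNA[li], ids$mRNA[mi], j)
        pairs[[length(pairs) + 1]] <<- data.frame(
          lncrna_id = ids$lncRNA[li], gene_id = ids$mRNA[mi], category = category)
      }
    }
    plant("overlapping", function(l, m, j) {
      ch <- next_chrom(); at <- bump(ch, 6e4)
      arr <- c("tandem", "convergent", "divergent")[(j - 1) %% 3 + 1]
      st <- switch(arr, tandem = c("+", "+"), convergent = c("+", "-"), divergent = c("-", "+"))
      add(l, "lncRNA", ch, at, at + 3e4, st[1])          # lncRNA left, overlapping by 10 kb
      add(m, "mRNA", ch, at + 2e4, at + 6e4, st[2])
    })
    plant("same_tad", function(l, m, j) {
      ch <- next_chrom()
      at <- ceiling(bump(ch, tad) / tad) * tad           # align to a TAD start
      add(m, "mRNA", ch, at + 5e4, at + 8e4, "+")
      add(l, "lncRNA", ch, at + 2e5, at + 2.3e5, sample(c("+", "-"), 1))
    })
    plant("proximal", function(l, m, j) {
      ch <- next_chrom()
      at <- ceiling(bump(ch, tad + 6e5) / tad) * tad
      add(m, "mRNA", ch, at - 2e5, at - 1.7e5, "+")      # late in previous TAD
      add(l, "lncRNA", ch, at + 3e5, at + 3.3e5, sample(c("+", "-"), 1))  # next TAD, gap 470 kb
    })
    plant("same_chrom", function(l, m, j) {
      ch <- next_chrom(); at <- bump(ch, 5.1e6)
      add(m, "mRNA", ch, at, at + 3e4, "+")
      add(l, "lncRNA", ch, at + 5e6, at + 5.03e6, sample(c("+", "-"), 1))  # > 1 Mbp gap
    })
    plant("trans", function(l, m, j) {
      ch1 <- next_chrom(); ch2 <- chroms[(match(ch1, chroms)) %% length(chroms) + 1]
      at1 <- bump(ch1, 3e4); at2 <- bump(ch2, 3e4)
      add(m, "mRNA", ch1, at1, at1 + 3e4, "+")
      add(l, "lncRNA", ch2, at2, at2 + 3e4, sample(c("+", "-"), 1))
    })
    # fillers: everything not consumed by planted pairs
    filler <- c(ids$lncRNA[seq_len(config$n_lncrna) > li],
                ids$mRNA[seq_len(config$n_mrna) > mi],
                ids$TF, ids$RBP, ids$enzyme, ids$miRNA)
    fclass <- c(rep("lncRNA", config$n_lncrna - li), rep("mRNA", config$n_mrna - mi),
                rep("TF", config$n_tf), rep("RBP", config$n_rbp),
                rep("enzyme", config$n_enzyme), rep("miRNA", config$n_mirna))
    ord <- sample(length(filler))
    for (i in ord) {
      ch <- next_chrom()
      len <- round(stats::runif(1, 5e3, 3e4))
      gap <- round(stats::runif(1, 3e4, 8e4))
      if (cursor[ch] + gap + len >= config$chrom_length) {
        stopf("chromosome %s too short for requested gene count", ch)
      }
      at <- cursor[ch] + gap; cursor[ch] <- at + len
      add(filler[i], fclass[i], ch, at, at + len, sample(c("+", "-"), 1))
    }
    ann <- do.call(rbind, placed)
    rownames(ann) <- NULL
    stopifnot(!anyDuplicated(ann$gene_id), all(ann$start < ann$end))
    attr(ann, "planted_pairs") <- do.call(rbind, pairs)
    list(annotation = ann, tads = tads)
  })
}

#' Plant the regulatory ground truth
#'
#' Every coding gene and lncRNA receives `n_tf_per_target` TF parents with
#' signed effects (TF->TF edges only run from lower to higher index, keeping
#' the graph acyclic); this creates the TF co-regulation confounding the
#' pipeline must remove. `n_lnc_edges` direct lncRNA->mRNA edges are drawn
#' from the planted pairs with bias `frac_cis_regulators` toward cis pairs,
#' whose effects are always positive; trans edges get random sign. ceRNA
#' triplets tag a subset of trans edges with a shared miRNA + cell line, and
#' interaction triplets add a lncRNA x protein product effect on targets that
#' already have the lncRNA as a direct regulator.
#'
#' @param annotation,tads from [generate_annotation()].
#' @param config the same [sim_config()].
#' @return `ground_truth` list: `annotation`, `tads`, `tf_edges`, `lnc_edges`,
#'   `cerna_triplets`, `interaction_triplets`, `mirna_gene`, `mirna_lnc`,
#'   `covariate_betas`.
#' @export
generate_truth <- function(annotation, tads, config) {
  with_seed(derive_seed(config$seed, "truth"), {
    cls <- split(annotation$gene_id, annotation$class)
    tfs <- cls$TF %||% character()
    regulated <- c(cls$mRNA, cls$RBP, cls$enzyme)
    lncs <- cls$lncRNA %||% character()
    tf_edges <- NULL
    if (length(tfs)) {
      tf_edges <- do.call(rbind, lapply(c(regulated, lncs, tfs), function(g) {
        pool <- if (g %in% tfs) tfs[seq_len(match(g, tfs) - 1)] else tfs
        n_par <- if (g %in% lncs) config$n_tf_per_lnc else config$n_tf_per_target
        beta <- if (g %in% lncs) config$beta_tf_lnc else config$beta_tf
        k <- min(n_par, length(pool))
        if (k == 0) return(NULL)
        data.frame(tf_id = sample(pool, k),
                   target_id = g,
                   effect = beta * sample(c(1, -1), k, replace = TRUE, prob = c(0.7, 0.3)))
      }))
      if (!is.null(tf_edges)) tf_edges <- tf_edges[tf_edges$effect != 0, , drop = FALSE]
      if (!is.null(tf_edges) && !nrow(tf_edges)) tf_edges <- NULL
    }
    pp <- attr(annotation, "planted_pairs")
    cis_pool <- pp[pp$category %in% c("overlapping", "same_tad", "proximal"), ]
    trans_pool <- pp[pp$category %in% c("same_chrom", "trans"), ]
    n_cis <- min(round(config$frac_cis_regulators * config$n_lnc_edges), nrow(cis_pool))
    n_trans <- min(config$n_lnc_edges - n_cis, nrow(trans_pool))
    lnc_edges <- NULL
    if (config$beta_lnc != 0 && (n_cis + n_trans) > 0) {
      take_cis <- cis_pool[seq_len(n_cis), , drop = FALSE]
      take_trans <- trans_pool[seq_len(n_trans), , drop = FALSE]
      lnc_edges <- rbind(
        if (n_cis > 0) data.frame(take_cis, effect = config$beta_lnc),
        if (n_trans > 0) data.frame(take_trans,
                                    effect = config$beta_lnc * sample(c(1, -1), n_trans, TRUE)))
      rownames(lnc_edges) <- NULL
    }
    # ceRNA triplets: shared miRNA + cell line on trans lncRNA edges
    mirnas <- cls$miRNA %||% character()
    cell_lines <- c("CL_A", "CL_B", "CL_C")
    cerna <- NULL; mir_gene <- list(); mir_lnc <- list()
    if (!is.null(lnc_edges)) {
      trans_edges <- lnc_edges[lnc_edges$category %in% c("same_chrom", "trans"), , drop = FALSE]
      k <- min(config$n_cerna, nrow(trans_edges), length(mirnas))
      if (k > 0) {
        sel <- trans_edges[seq_len(k), ]
        cerna <- data.frame(mirna_id = mirnas[seq_len(k)], lncrna_id = sel$lncrna_id,
                            gene_id = sel$gene_id,
                            cell_line = sample(cell_lines, k, replace = TRUE))
        mir_gene <- list(data.frame(mirna_id = cerna$mirna_id, partner_id = cerna$gene_id,
                                    partner_class = "mRNA", cell_line = cerna$cell_line))
        mir_lnc <- list(data.frame(mirna_id = cerna$mirna_id, partner_id = cerna$lncrna_id,
                                   partner_class = "lncRNA", cell_line = cerna$cell_line))
      }
    }
    # decoy interactions that must not produce ceRNA pairs: unique cell line per row,
    # plus shared-miRNA rows in mismatched cell lines
    if (length(mirnas)) {
      n_dec <- 50
      dec_g <- data.frame(
        mirna_id = sample(mirnas, n_dec, TRUE),
        partner_id = sample(c(cls$mRNA, cls$RBP %||% character()), n_dec, TRUE),
        partner_class = "mRNA", cell_line = sprintf("decoyG_%03d", seq_len(n_dec)))
      dec_l <- data.frame(
        mirna_id = sample(mirnas, n_dec, TRUE),
        partner_id = sample(cls$lncRNA, n_dec, TRUE),
        partner_class = "lncRNA", cell_line = sprintf("decoyL_%03d", seq_len(n_dec)))
      mir_gene <- c(mir_gene, list(dec_g)); mir_lnc <- c(mir_lnc, list(dec_l))
    }
    # interaction triplets ride on existing direct edges so the lncRNA main
    # effect is recoverable alongside the product term
    inter <- NULL
    if (!is.null(lnc_edges) && config$n_interactions > 0 && config$beta_interaction != 0) {
      k <- min(config$n_interactions, nrow(lnc_edges))
      prot_pool <- c(tfs, cls$RBP %||% character())
      sel <- lnc_edges[seq_len(k), ]
      prot <- sample(prot_pool, k, replace = length(prot_pool) < k)
      inter <- data.frame(lncrna_id = sel$lncrna_id, protein_id = prot,
                          protein_class = ifelse(prot %in% tfs, "TF", "RBP"),
                          target_id = sel$gene_id, effect = config$beta_interaction)
    }
    covariate_betas <- data.frame(
      gene_id = annotation$gene_id,
      age = config$covariate_effect * sample(c(-1, 0, 1), nrow(annotation), TRUE,
                                             prob = c(0.25, 0.5, 0.25)),
      sex_male = config$covariate_effect * sample(c(0, 1), nrow(annotation), TRUE,
                                                  prob = c(0.8, 0.2)))
    truth <- structure(list(
      annotation = annotation, tads = tads,
      tf_edges = tf_edges, lnc_edges = lnc_edges,
      cerna_triplets = cerna, interaction_triplets = inter,
      mirna_gene = do.call(rbind, mir_gene), mirna_lnc = do.call(rbind, mir_lnc),
      covariate_betas = covariate_betas, config = config), class = "ground_truth")
    assert_truth_dag(truth)
    truth
  })
}

# Topological order of the ground-truth graph; errors on cycles.
truth_topo_order <- function(truth) {
  genes <- truth$annotation$gene_id
  edges <- rbind(
    if (!is.null(truth$tf_edges)) truth$tf_edges[, c("tf_id", "target_id")],
    if (!is.null(truth$lnc_edges)) {
      stats::setNames(truth$lnc_edges[, c("lncrna_id", "gene_id")], c("tf_id", "target_id"))
    },
    if (!is.null(truth$interaction_triplets)) {
      rbind(stats::setNames(truth$interaction_triplets[, c("lncrna_id", "target_id")],
                            c("tf_id", "target_id")),
            stats::setNames(truth$interaction_triplets[, c("protein_id", "target_id")],
                            c("tf_id", "target_id")))
    })
  indeg <- stats::setNames(rep(0L, length(genes)), genes)
  if (!is.null(edges) && nrow(edges)) {
    tab <- table(edges$target_id)
    indeg[names(tab)] <- as.integer(tab)
  }
  order_out <- character(0)
  avail <- names(indeg)[indeg == 0]
  while (length(avail)) {
    g <- avail[1]; avail <- avail[-1]
    order_out <- c(order_out, g)
    if (!is.null(edges) && nrow(edges)) {
      kids <- edges$target_id[edges$tf_id == g]
      for (k in kids) {
        indeg[k] <- indeg[k] - 1L
        if (indeg[k] == 0L) avail <- c(avail, k)
      }
    }
  }
  if (length(order_out) < length(genes)) stopf("ground-truth regulatory graph has a cycle")
  order_out
}

assert_truth_dag <- function(truth) invisible(truth_topo_order(truth))

#' Simulate counts and sample covariates from a ground truth
#'
#' Latent per-gene signal x = covariate effects + sum of parent effects + sum
#' of interaction products + standard Gaussian noise, built in topological
#' order. The latent log-expression is a per-gene baseline plus x; counts are
#' negative-binomial around library-size-scaled exp(latent).
#'
#' @param truth a [generate_truth()] result. @param config its [sim_config()].
#' @return list with `counts` (genes x samples integer matrix), `covariates`
#'   (data.frame), `latent` (the x matrix, for test oracles), `lib_factors`.
#' @export
simulate_counts <- function(truth, config) {
  with_seed(derive_seed(config$seed, "counts"), {
    n <- config$n_samples
    genes <- truth$annotation$gene_id
    covariates <- data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      age = sample(30:80, n, replace = TRUE),
      sex = sample(c("female", "male"), n, TRUE, prob = c(0.9, 0.1)),
      ethnicity = sample(c("hispanic", "not_hispanic"), n, TRUE, prob = c(0.15, 0.85)),
      race = sample(c("white", "black", "asian", "other"), n, TRUE,
                    prob = c(0.7, 0.15, 0.1, 0.05)))
    age_std <- as.numeric(scale(covariates$age))
    sex_male <- as.numeric(covariates$sex == "male")
    topo <- truth_topo_order(truth)
    x <- matrix(0, length(genes), n, dimnames = list(genes, covariates$sample_id))
    xs <- x  # per-gene standardized latent; keeps parent effects in SD units
    cb <- truth$covariate_betas
    parents_tf <- if (!is.null(truth$tf_edges)) split(truth$tf_edges, truth$tf_edges$target_id)
    parents_ln <- if (!is.null(truth$lnc_edges)) split(truth$lnc_edges, truth$lnc_edges$gene_id)
    inter <- truth$interaction_triplets
    for (g in topo) {
      mu <- rep(0, n)
      i <- match(g, cb$gene_id)
      if (!is.na(i)) mu <- mu + cb$age[i] * age_std + cb$sex_male[i] * sex_male
      pt <- parents_tf[[g]]
      if (!is.null(pt)) for (j in seq_len(nrow(pt))) mu <- mu + pt$effect[j] * xs[pt$tf_id[j], ]
      pl <- parents_ln[[g]]
      if (!is.null(pl)) for (j in seq_len(nrow(pl))) mu <- mu + pl$effect[j] * xs[pl$lncrna_id[j], ]
      if (!is.null(inter)) {
        it <- inter[inter$target_id == g, , drop = FALSE]
        if (nrow(it)) for (j in seq_len(nrow(it))) {
          mu <- mu + it$effect[j] * xs[it$lncrna_id[j], ] * xs[it$protein_id[j], ]
        }
      }
      x[g, ] <- mu + stats::rnorm(n)
      s <- stats::sd(x[g, ])
      xs[g, ] <- if (s > 0) (x[g, ] - mean(x[g, ])) / s else x[g, ]
    }
    baseline <- stats::runif(length(genes), log(50), log(1500))
    lib <- stats::runif(n, config$libsize_range[1], config$libsize_range[2])
    # 0.6 natural-log units per latent SD keeps the count dynamic range in a
    # realistic bulk RNA-seq regime; being linear in x it leaves correlation
    # structure (and hence all recovery oracles) untouched
    mu_mat <- exp(baseline + 0.6 * x) %*% diag(lib)
    size <- 1 / config$nb_dispersion
    counts <- matrix(stats::rnbinom(length(mu_mat), mu = mu_mat, size = size),
                     nrow = length(genes), dimnames = dimnames(x))
    list(counts = counts, covariates = covariates, latent = x, lib_factors = lib)
  })
}

#' Brute-force pair-relation bookkeeping for a synthetic genome
#'
#' Recomputes overlapping / same-TAD / proximal / same-chromosome flags for
#' every lncRNA x coding-gene pair with a naive double loop and direct
#' arithmetic. This is the generator's own bookkeeping, kept deliberately
#' independent of the genomics module so it can serve as a test oracle.
#'
#' @export
truth_pair_flags <- function(annotation, tads, proximal_dist = 1e6) {
  lnc <- annotation[annotation$class == "lncRNA", ]
  cod <- annotation[annotation$class %in% c("mRNA", "TF", "RBP", "enzyme"), ]
  tad_of <- function(chrom, pos) {
    t <- tads[tads$chrom == chrom & tads$start <= pos & pos < tads$end, ]
    if (nrow(t) == 1) paste0(chrom, ":", t$start) else NA_character_
  }
  rows <- vector("list", nrow(lnc) * nrow(cod)); r <- 0
  for (i in seq_len(nrow(lnc))) for (j in seq_len(nrow(cod))) {
    r <- r + 1
    a <- lnc[i, ]; b <- cod[j, ]
    same_chrom <- a$chrom == b$chrom
    ov <- same_chrom && a$start < b$end && b$start < a$end
    gap <- if (!same_chrom) NA_real_ else if (ov) -1 else max(a$start, b$start) - min(a$end, b$end)
    prox <- same_chrom && (ov || gap < proximal_dist)
    tss_a <- if (a$strand == "+") a$start else a$end - 1
    tss_b <- if (b$strand == "+") b$start else b$end - 1
    st <- same_chrom && identical(tad_of(a$chrom, tss_a), tad_of(b$chrom, tss_b)) &&
      !is.na(tad_of(a$chrom, tss_a))
    rows[[r]] <- data.frame(lncrna_id = a$gene_id, gene_id = b$gene_id,
                            overlapping = ov, same_tad = st, proximal = prox,
                            same_chrom = same_chrom, distance = gap)
  }
  do.call(rbind, rows)
}

#' Simulate a complete analysis bundle
#'
#' Convenience wrapper: annotation + truth + counts from one config.
#' @export
simulate_bundle <- function(config) {
  ann <- generate_annotation(config)
  truth <- generate_truth(ann$annotation, ann$tads, config)
  sim <- simulate_counts(truth, config)
  c(list(annotation = ann$annotation, tads = ann$tads, truth = truth), sim)
}
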