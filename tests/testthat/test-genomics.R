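# Interval categorization, overlap orientation, ceRNA detection and
# candidate restriction.

toy_annotation <- function(rows) {
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r[[1]], gene_name = r[[1]], class = r[[2]], chrom = r[[3]],
               start = as.numeric(r[[4]]), end = as.numeric(r[[5]]), strand = r[[6]])
  }))
}

toy_tads <- data.frame(chrom = "chr1", start = c(0, 1e6, 2e6), end = c(1e6, 2e6, 3e6))

test_that("overlap, distance and proximity follow the published conventions", {
  ann <- toy_annotation(list(
    list("L1", "lncRNA", "chr1", 100, 200, "+"),
    list("G1", "mRNA", "chr1", 150, 300, "+"),
    list("G2", "mRNA", "chr1", 1000200, 1000300, "+"),  # gap from L1: exactly 1 Mbp
    list("G3", "mRNA", "chr2", 100, 200, "+")))
  p1 <- classify_pair("L1", "G1", ann, toy_tads)
  expect_true(p1$overlapping); expect_true(p1$proximal); expect_true(p1$same_chrom)
  expect_equal(p1$distance, -1)
  p2 <- classify_pair("L1", "G2", ann, toy_tads)
  expect_equal(p2$distance, 1e6)
  expect_false(p2$proximal)  # strict < 1 Mbp
  p3 <- classify_pair("L1", "G3", ann, toy_tads)
  expect_false(p3$same_chrom); expect_true(is.na(p3$distance))
  expect_equal(format_pair_table(p3)$dist, "X")
  expect_error(classify_pair("L1", "missing", ann, toy_tads), "unknown gene")
})

test_that("overlap orientation matches the 8-case strand/position truth table", {
  # hand-drawn truth table over strand pairs x left/right position of the
  # lncRNA; the two genes always overlap by 50 bp
  cases <- list(
    #    lnc strand, gene strand, lnc side, expected
    list("+", "+", "left",  "tandem"),
    list("+", "+", "right", "tandem"),
    list("-", "-", "left",  "tandem"),
    list("-", "-", "right", "tandem"),
    list("+", "-", "left",  "convergent"),  # --> <--
    list("+", "-", "right", "divergent"),   # <-- -->
    list("-", "+", "left",  "divergent"),
    list("-", "+", "right", "convergent"))
  for (cc in cases) {
    lnc_start <- if (cc[[3]] == "left") 1000 else 1150
    ann <- toy_annotation(list(
      list("L", "lncRNA", "chr1", lnc_start, lnc_start + 200, cc[[1]]),
      list("G", "mRNA", "chr1", 1100, 1300, cc[[2]])))
    got <- classify_pair("L", "G", ann, toy_tads)$orientation
    expect_equal(got, cc[[4]], info = paste(unlist(cc), collapse = " "))
  }
  # the derived example: lncRNA on +, gene on -, lncRNA upstream, 10 bp overlap
  ann <- toy_annotation(list(
    list("L", "lncRNA", "chr1", 100, 210, "+"),
    list("G", "mRNA", "chr1", 200, 400, "-")))
  expect_equal(classify_pair("L", "G", ann, toy_tads)$orientation, "convergent")
  # non-overlapping pairs carry no orientation
  ann2 <- toy_annotation(list(
    list("L", "lncRNA", "chr1", 100, 200, "+"),
    list("G", "mRNA", "chr1", 500, 700, "-")))
  expect_true(is.na(classify_pair("L", "G", ann2, toy_tads)$orientation))
})

test_that("same-TAD uses 5' end containment and rejects overlapping TADs", {
  ann <- toy_annotation(list(
    # minus-strand gene straddling a boundary: 5' end (end-1) is in TAD 2
    list("L1", "lncRNA", "chr1", 0.9e6, 1.1e6, "-"),
    list("G1", "mRNA", "chr1", 1.5e6, 1.6e6, "+"),    # TAD 2
    list("G2", "mRNA", "chr1", 0.2e6, 0.3e6, "+")))   # TAD 1
  expect_true(classify_pair("L1", "G1", ann, toy_tads)$same_tad)
  expect_false(classify_pair("L1", "G2", ann, toy_tads)$same_tad)
  bad <- rbind(toy_tads, data.frame(chrom = "chr1", start = 5e5, end = 1.5e6))
  expect_error(classify_pair("L1", "G1", ann, bad), "overlapping TADs")
  expect_error(lncregnet:::validate_tads(data.frame(chrom = "chr1", start = 10, end = 10)),
               "start >= end")
})

test_that("category flags nest and are symmetric on a synthetic genome", {
  ga <- generate_annotation(small_config(seed = 33))
  ann <- ga$annotation
  lnc <- ann$gene_id[ann$class == "lncRNA"][1:12]
  genes <- ann$gene_id[ann$class == "mRNA"][1:12]
  grid <- expand.grid(l = lnc, g = genes, stringsAsFactors = FALSE)
  fl <- classify_pairs(grid$l, grid$g, ann, ga$tads)
  expect_true(all(!fl$overlapping | fl$proximal))
  expect_true(all(!fl$proximal | fl$same_chrom))
  expect_true(all(!fl$same_tad | fl$same_chrom))
  expect_true(all(is.na(fl$orientation) == !fl$overlapping))
  rev <- classify_pairs(grid$g, grid$l, ann, ga$tads)
  for (col in c("overlapping", "same_tad", "proximal", "same_chrom", "distance")) {
    expect_equal(fl[[col]], rev[[col]])
  }
})

test_that("classification agrees with GenomicRanges and the generator's books", {
  ga <- generate_annotation(small_config(seed = 61))
  ann <- ga$annotation
  lnc <- ann$gene_id[ann$class == "lncRNA"]
  genes <- ann$gene_id[ann$class == "mRNA"]
  grid <- expand.grid(l = lnc, g = genes, stringsAsFactors = FALSE)
  fl <- classify_pairs(grid$l, grid$g, ann, ga$tads)
  # independent oracle 1: the generator's naive double-loop bookkeeping
  books <- truth_pair_flags(ann, ga$tads)
  key <- paste(books$lncrna_id, books$gene_id)
  m <- match(paste(fl$lncrna_id, fl$gene_id), key)
  expect_equal(fl$overlapping, books$overlapping[m])
  expect_equal(fl$same_tad, books$same_tad[m])
  expect_equal(fl$proximal, books$proximal[m])
  expect_equal(fl$distance, books$distance[m])
  skip_if_not_installed("GenomicRanges")
  # independent oracle 2: GRanges pairwise overlap on the same intervals
  gr <- GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(ann$start + 1, ann$end))
  names(gr) <- ann$gene_id
  ov_gr <- as.logical(IRanges::poverlaps(gr[grid$l], gr[grid$g]))
  expect_equal(fl$overlapping, ov_gr)
})

test_that("ceRNA pairs require a shared miRNA in the same cell line", {
  mg <- data.frame(mirna_id = c("m1", "m1", "m2"),
                   partner_id = c("G1", "G2", "G3"),
                   cell_line = c("A", "B", "A"))
  ml <- data.frame(mirna_id = c("m1", "m2"),
                   partner_id = c("L1", "L2"),
                   cell_line = c("A", "B"))
  out <- find_cerna_pairs(mg, ml)
  # m1/A shared by G1 and L1 -> pair; m1/B (G2) has no lncRNA in B; m2
  # appears in different cell lines only
  expect_equal(out$pairs$lncrna_id, "L1")
  expect_equal(out$pairs$gene_id, "G1")
  expect_equal(out$pairs$n_support, 1)
})

test_that("planted ceRNA triplets are recovered exactly among decoys", {
  cfg <- small_config(seed = 77)
  tr <- with(generate_annotation(cfg), generate_truth(annotation, tads, cfg))
  out <- find_cerna_pairs(tr$mirna_gene, tr$mirna_lnc)
  want <- unique(tr$cerna_triplets[, c("lncrna_id", "gene_id")])
  got <- out$pairs[, c("lncrna_id", "gene_id")]
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got$lncrna_id, got$gene_id), paste(want$lncrna_id, want$gene_id))
})

test_that("candidates_for restricts and sorts deterministically", {
  ga <- generate_annotation(small_config(seed = 52))
  ann <- ga$annotation
  books <- truth_pair_flags(ann, ga$tads)
  genes <- ann$gene_id[ann$class == "mRNA"]
  all_lnc <- sort(ann$gene_id[ann$class == "lncRNA"])
  for (g in genes[c(1, 5, 20)]) {
    expect_equal(candidates_for(g, "all", ann), setdiff(all_lnc, g))
    for (cat in c("overlapping", "same_tad", "proximal", "same_chrom")) {
      want <- sort(books$lncrna_id[books$gene_id == g & books[[cat]]])
      expect_equal(candidates_for(g, cat, ann, ga$tads), want,
                   info = paste(g, cat))
    }
  }
  # no overlapping lncRNA: empty, gene unmodeled for that category
  no_ov <- genes[!genes %in% books$gene_id[books$overlapping]][1]
  expect_length(candidates_for(no_ov, "overlapping", ann, ga$tads), 0)
  expect_error(candidates_for(genes[1], "bogus", ann, ga$tads), "unknown category")
  expect_error(candidates_for(genes[1], "cerna", ann, ga$tads), "requires")
})
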