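# Location and mechanism categorization of lncRNA-gene pairs: interval
# overlap, TAD co-membership, proximity, overlap orientation, and ceRNA
# detection from miRNA interaction tables. Coordinates are 0-based half-open
# (BED convention) throughout.

validate_tads <- function(tads) {
  if (any(tads$start >= tads$end)) stopf("TAD with start >= end")
  for (ch in unique(tads$chrom)) {
    t <- tads[tads$chrom == ch, ]
    t <- t[order(t$start), ]
    if (nrow(t) > 1 && any(t$start[-1] < t$end[-nrow(t)])) {
      stopf("overlapping TADs on %s", ch)
    }
  }
  invisible(tads)
}

# TAD index (or NA) containing each position, by strict half-open containment.
tad_index <- function(tads, chrom, pos) {
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    t <- which(tads$chrom == ch)
    if (!length(t)) next
    t <- t[order(tads$start[t])]
    i <- findInterval(pos[sel], tads$start[t])
    ok <- i >= 1 & ifelse(i >= 1, pos[sel] < tads$end[t[pmax(i, 1)]], FALSE)
    out[sel][ok] <- t[i[ok]]
  }
  out
}

# 5' end position of a gene interval (0-based): start for +, end - 1 for -.
five_prime <- function(start, end, strand) ifelse(strand == "+", start, end - 1)

#' Classify the genomic relationship of lncRNA-gene pairs
#'
#' Vectorized over pairs. Overlapping means the intervals intersect on the
#' same chromosome regardless of strand; distance is the gap between closest
#' interval ends when disjoint on one chromosome (-1 sentinel for overlap, NA
#' for different chromosomes, rendered 'X' on write); proximal means same
#' chromosome and distance strictly below `proximal_dist` (overlap counts);
#' same-TAD means both 5' ends fall in the same TAD. Orientation is defined
#' exactly for overlapping pairs: same strand = tandem; opposite strands with
#' the 3' ends facing each other = convergent, 5' ends facing = divergent.
#'
#' @param lncrna_ids,gene_ids equal-length id vectors (recycled if length 1).
#' @param annotation gene annotation data.frame.
#' @param tads TAD data.frame (chrom, start, end), non-overlapping.
#' @param proximal_dist proximity cutoff in bp (strict <).
#' @return data.frame with one row per pair: flags `overlapping`, `same_tad`,
#'   `proximal`, `same_chrom`, `distance`, `orientation`.
#' @export
classify_pairs <- function(lncrna_ids, gene_ids, annotation, tads, proximal_dist = 1e6) {
  n <- max(length(lncrna_ids), length(gene_ids))
  lncrna_ids <- rep_len(lncrna_ids, n); gene_ids <- rep_len(gene_ids, n)
  ia <- match(lncrna_ids, annotation$gene_id)
  ib <- match(gene_ids, annotation$gene_id)
  if (anyNA(ia) || anyNA(ib)) {
    stopf("unknown gene id(s): %s",
          paste(unique(c(lncrna_ids[is.na(ia)], gene_ids[is.na(ib)])), collapse = ", "))
  }
  validate_tads(tads)
  a <- annotation[ia, ]; b <- annotation[ib, ]
  same_chrom <- a$chrom == b$chrom
  overlapping <- same_chrom & a$start < b$end & b$start < a$end
  gap <- ifelse(same_chrom, pmax(a$start, b$start) - pmin(a$end, b$end), NA_real_)
  distance <- ifelse(overlapping, -1, gap)
  proximal <- same_chrom & (overlapping | gap < proximal_dist)
  ta <- tad_index(tads, a$chrom, five_prime(a$start, a$end, a$strand))
  tb <- tad_index(tads, b$chrom, five_prime(b$start, b$end, b$strand))
  same_tad <- !is.na(ta) & !is.na(tb) & ta == tb
  orientation <- rep(NA_character_, n)
  tand <- overlapping & a$strand == b$strand
  orientation[tand] <- "tandem"
  opp <- overlapping & a$strand != b$strand
  if (any(opp)) {
    # order the two genes along the chromosome; the plus-strand gene leading
    # means the 3' ends point at each other (convergent), else divergent
    plus_start <- ifelse(a$strand == "+", a$start, b$start)
    plus_end <- ifelse(a$strand == "+", a$end, b$end)
    minus_start <- ifelse(a$strand == "-", a$start, b$start)
    minus_end <- ifelse(a$strand == "-", a$end, b$end)
    plus_first <- plus_start < minus_start | (plus_start == minus_start & plus_end <= minus_end)
    orientation[opp] <- ifelse(plus_first[opp], "convergent", "divergent")
  }
  data.frame(lncrna_id = lncrna_ids, gene_id = gene_ids,
             overlapping = overlapping, same_tad = same_tad, proximal = proximal,
             same_chrom = same_chrom,
             cerna = FALSE,  # filled by callers holding ceRNA evidence
             distance = distance, orientation = orientation)
}

#' Classify one lncRNA-gene pair
#' @rdname classify_pairs
#' @export
classify_pair <- function(lncrna, gene, annotation, tads, proximal_dist = 1e6) {
  classify_pairs(lncrna, gene, annotation, tads, proximal_dist)
}

#' Detect competing-endogenous-RNA pairs from miRNA interaction tables
#'
#' A (lncRNA, gene) pair is emitted iff some miRNA targets both the gene and
#' the lncRNA in the same cell line.
#'
#' @param mirna_gene,mirna_lnc data.frames with columns `mirna_id`,
#'   `partner_id`, `cell_line` (and optionally `partner_class`).
#' @return list with `pairs` (unique lncrna_id / gene_id / n_support) and
#'   `evidence` (one row per supporting miRNA + cell line).
#' @export
find_cerna_pairs <- function(mirna_gene, mirna_lnc) {
  need <- c("mirna_id", "partner_id", "cell_line")
  if (!all(need %in% names(mirna_gene)) || !all(need %in% names(mirna_lnc))) {
    stopf("interaction tables need columns: %s", paste(need, collapse = ", "))
  }
  ev <- merge(
    data.frame(mirna_id = mirna_lnc$mirna_id, cell_line = mirna_lnc$cell_line,
               lncrna_id = mirna_lnc$partner_id),
    data.frame(mirna_id = mirna_gene$mirna_id, cell_line = mirna_gene$cell_line,
               gene_id = mirna_gene$partner_id),
    by = c("mirna_id", "cell_line"))
  ev <- unique(ev[, c("lncrna_id", "gene_id", "mirna_id", "cell_line")])
  if (!nrow(ev)) {
    return(list(pairs = data.frame(lncrna_id = character(), gene_id = character(),
                                   n_support = integer()),
                evidence = ev))
  }
  agg <- stats::aggregate(list(n_support = ev$mirna_id),
                          by = list(lncrna_id = ev$lncrna_id, gene_id = ev$gene_id), length)
  agg <- agg[order(agg$lncrna_id, agg$gene_id), ]
  rownames(agg) <- NULL
  list(pairs = agg, evidence = ev)
}

#' Candidate lncRNA regulators for a gene under a category restriction
#'
#' @param gene target gene id.
#' @param category one of overlapping, same_tad, proximal, same_chrom, cerna,
#'   all.
#' @param annotation,tads genome context. @param cerna_pairs output of
#'   [find_cerna_pairs()] (`$pairs`), required for category "cerna".
#' @param proximal_dist proximity cutoff.
#' @return sorted character vector of candidate lncRNA ids (deterministic;
#'   empty means the gene is unmodeled for that category).
#' @export
candidates_for <- function(gene, category, annotation, tads = NULL, cerna_pairs = NULL,
                           proximal_dist = 1e6) {
  lnc <- sort(setdiff(annotation$gene_id[annotation$class == "lncRNA"], gene))
  if (category == "all") return(lnc)
  if (category == "cerna") {
    if (is.null(cerna_pairs)) stopf("cerna category requires cerna_pairs")
    return(sort(intersect(lnc, cerna_pairs$lncrna_id[cerna_pairs$gene_id == gene])))
  }
  if (!category %in% c("overlapping", "same_tad", "proximal", "same_chrom")) {
    stopf("unknown category '%s'", category)
  }
  if (!length(lnc)) return(character())
  fl <- classify_pairs(lnc, gene, annotation, tads, proximal_dist)
  sort(fl$lncrna_id[fl[[category]]])
}

#' Render a pair-category table with the published sentinel conventions
#'
#' Distance -1 marks overlap and 'X' marks pairs on different chromosomes;
#' orientation flags are expanded into tandem/convergent/divergent columns.
#' @export
format_pair_table <- function(pairs) {
  data.frame(
    lncrna_id = pairs$lncrna_id, gene_id = pairs$gene_id,
    overlapping = pairs$overlapping, same_tad = pairs$same_tad,
    proximal = pairs$proximal, same_chrom = pairs$same_chrom, cerna = pairs$cerna,
    tandem = !is.na(pairs$orientation) & pairs$orientation == "tandem",
    convergent = !is.na(pairs$orientation) & pairs$orientation == "convergent",
    divergent = !is.na(pairs$orientation) & pairs$orientation == "divergent",
    dist = ifelse(is.na(pairs$distance), "X", as.character(pairs$distance)))
}
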