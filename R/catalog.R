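# Antisense catalog construction: sense assignment, antisense calling and
# tiering, deterministic curation of fragmented calls, catalog comparison,
# and the strand-specificity QC metric.

# 0-based half-open data.frame intervals -> GRanges (1-based closed)
.as_granges <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = start + 1, end = end),
                         strand = strand)
}

# All (unit, gene-span) index pairs with >= 1 bp overlap and the given
# strand relation; returns integer overlap widths.
.overlap_pairs <- function(units, spans, relation = c("same", "opposite")) {
  relation <- match.arg(relation)
  if (nrow(units) == 0L || nrow(spans) == 0L)
    return(data.frame(u = integer(0), g = integer(0), overlap = numeric(0)))
  sp_strand <- if (relation == "same") spans$strand else
    ifelse(spans$strand == "+", "-", "+")
  ugr <- .as_granges(units$chrom, units$start, units$end, units$strand)
  ggr <- .as_granges(spans$chrom, spans$start, spans$end, sp_strand)
  hits <- GenomicRanges::findOverlaps(ugr, ggr)
  u <- S4Vectors::queryHits(hits)
  g <- S4Vectors::subjectHits(hits)
  ov <- pmin(units$end[u], spans$end[g]) - pmax(units$start[u], spans$start[g])
  data.frame(u = u, g = g, overlap = ov)
}

#' Assign transcribed units to sense genes
#'
#' A unit is assigned to a gene when both are on the same strand and the
#' unit overlaps the gene's UTR-extended transcript span by at least one
#' base. A unit overlapping several genes yields one assignment per
#' gene.
#'
#' @param units data.frame of units (see [call_units()]).
#' @param ann an [annotation()].
#' @return data.frame with columns `unit_id`, `gene_id`, `overlap_bp`.
#' @export
assign_sense <- function(units, ann) {
  spans <- transcript_spans(ann)
  p <- .overlap_pairs(units, spans, "same")
  out <- data.frame(unit_id = units$unit_id[p$u], gene_id = spans$gene_id[p$g],
                    overlap_bp = p$overlap, stringsAsFactors = FALSE)
  out[order(out$unit_id, out$gene_id), , drop = FALSE]
}

#' Detect expressed genes from unit coverage
#'
#' A gene counts as expressed when the union of same-strand units covers
#' at least `min_frac` of its span — by default the UTR-extended
#' transcript span; set `against = "orf"` to measure against the ORF
#' only.
#'
#' @param units data.frame of units.
#' @param ann an [annotation()].
#' @param min_frac minimum covered fraction (default 0.8).
#' @param against `"transcript"` (default) or `"orf"`.
#' @return character vector of detected gene ids (sorted).
#' @export
detect_expressed_genes <- function(units, ann, min_frac = 0.8,
                                   against = c("transcript", "orf")) {
  stopifnot(min_frac > 0, min_frac <= 1)
  against <- match.arg(against)
  spans <- transcript_spans(ann)
  if (against == "orf") {
    spans$start <- ann$genes$orf_start
    spans$end <- ann$genes$orf_end
  }
  p <- .overlap_pairs(units, spans, "same")
  if (nrow(p) == 0L) return(character(0))
  detected <- character(0)
  for (g in unique(p$g)) {
    uu <- p$u[p$g == g]
    ir <- IRanges::reduce(IRanges::IRanges(start = units$start[uu] + 1,
                                           end = units$end[uu]))
    ir <- IRanges::restrict(ir, start = spans$start[g] + 1, end = spans$end[g])
    covered <- sum(IRanges::width(ir))
    if (covered >= min_frac * (spans$end[g] - spans$start[g]))
      detected <- c(detected, spans$gene_id[g])
  }
  sort(detected)
}

#' Select the top fraction of expressed genes
#'
#' Genes are ranked by fragment count (descending, ties broken by
#' gene_id) and the highest `ceiling(top_frac * N)` genes are returned.
#'
#' @param gene_counts named numeric vector of per-gene fragment counts.
#' @param top_frac fraction of genes to keep (default 0.85).
#' @return character vector of selected gene ids.
#' @export
select_expressed <- function(gene_counts, top_frac = 0.85) {
  stopifnot(top_frac > 0, top_frac <= 1)
  if (length(gene_counts) == 0L) return(character(0))
  ids <- names(gene_counts)
  ord <- order(-gene_counts, ids)
  ids[ord][seq_len(ceiling(top_frac * length(gene_counts)))]
}

# ORF-coverage tier from exact integer overlaps
.tier <- function(ov_orf, orf_len) {
  ifelse(ov_orf == 0, "UTR_ONLY",
  ifelse(ov_orf == orf_len, "FULL",
  ifelse(4 * ov_orf >= 3 * orf_len, "GE75",
  ifelse(2 * ov_orf >= orf_len, "GE50", "GE25"))))
}

#' Call antisense units against annotated transcripts
#'
#' For every (unit, gene) pair on opposite strands with at least one
#' base of overlap between the unit and the gene's UTR-extended
#' transcript span, the covered fraction of the transcript is computed;
#' a call is emitted when it reaches `min_transcript_frac` (default
#' 0.25). The covered fraction of the ORF alone places the call in a
#' tier: `UTR_ONLY` (no ORF overlap), `GE25`, `GE50`, `GE75` (closed
#' lower bounds) or `FULL` (entire ORF covered). A unit antisense to
#' several genes yields one call per qualifying gene.
#'
#' @param units data.frame of units.
#' @param ann an [annotation()].
#' @param min_transcript_frac minimum transcript fraction for a call.
#' @return data.frame with columns `unit_id`, `gene_id`,
#'   `frac_transcript`, `frac_orf`, `tier`.
#' @export
call_antisense <- function(units, ann, min_transcript_frac = 0.25) {
  stopifnot(min_transcript_frac >= 0, min_transcript_frac <= 1)
  spans <- transcript_spans(ann)
  p <- .overlap_pairs(units, spans, "opposite")
  empty <- data.frame(unit_id = character(0), gene_id = character(0),
                      frac_transcript = numeric(0), frac_orf = numeric(0),
                      tier = character(0), stringsAsFactors = FALSE)
  if (nrow(p) == 0L) return(empty)
  t_len <- spans$end[p$g] - spans$start[p$g]
  keep <- p$overlap / t_len >= min_transcript_frac
  p <- p[keep, , drop = FALSE]
  if (nrow(p) == 0L) return(empty)
  t_len <- t_len[keep]
  orf_start <- ann$genes$orf_start[p$g]
  orf_end <- ann$genes$orf_end[p$g]
  ov_orf <- pmax(0, pmin(units$end[p$u], orf_end) -
                    pmax(units$start[p$u], orf_start))
  orf_len <- orf_end - orf_start
  out <- data.frame(unit_id = units$unit_id[p$u], gene_id = spans$gene_id[p$g],
                    frac_transcript = p$overlap / t_len,
                    frac_orf = ov_orf / orf_len,
                    tier = .tier(ov_orf, orf_len), stringsAsFactors = FALSE)
  out <- out[order(out$unit_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge fragmented antisense units (automatic curation)
#'
#' Low antisense coverage over-segments single transcripts into several
#' units. Same-strand units that each overlap the same gene in antisense
#' orientation and whose consecutive gaps are at most `merge_gap` bp are
#' merged into one curated unit spanning `min(start)..max(end)`;
#' antisense fractions and tiers are recomputed on the merged spans.
#'
#' @param units data.frame of units.
#' @param ann an [annotation()].
#' @param merge_gap maximum gap bridged between members (default 200 bp,
#'   an order of magnitude above the segmentation gap and below typical
#'   yeast gene length).
#' @param min_centers units supported by fewer fragment centers are
#'   dropped before merging (default 5). Strand leak occasionally piles
#'   two flipped centers on one base, producing 1-bp pseudo-units that
#'   would otherwise chain-merge into genuine units; this filter is the
#'   deterministic stand-in for the manual screening of spurious calls.
#'   Units without an `n_centers` column (e.g. re-read from BED) are
#'   kept.
#' @return data.frame with columns `curated_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `members` (comma-separated unit ids),
#'   `frac_transcript`, `frac_orf`, `tier`.
#' @export
curate_units <- function(units, ann, merge_gap = 200, min_centers = 5) {
  stopifnot(merge_gap >= 0, min_centers >= 0)
  if (!is.null(units$n_centers))
    units <- units[is.na(units$n_centers) | units$n_centers >= min_centers, ,
                   drop = FALSE]
  spans <- transcript_spans(ann)
  p <- .overlap_pairs(units, spans, "opposite")
  empty <- data.frame(curated_id = character(0), gene_id = character(0),
                      chrom = character(0), strand = character(0),
                      start = numeric(0), end = numeric(0),
                      members = character(0), frac_transcript = numeric(0),
                      frac_orf = numeric(0), tier = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(p) == 0L) return(empty)
  merged <- list()
  for (g in unique(p$g)) {
    uu <- p$u[p$g == g]
    sub <- units[uu, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    brk <- c(TRUE, sub$start[-1] - cummax(sub$end[-nrow(sub)]) > merge_gap)
    run <- cumsum(brk)
    for (r in unique(run)) {
      grp <- sub[run == r, , drop = FALSE]
      merged[[length(merged) + 1L]] <- data.frame(
        gene_id = spans$gene_id[g], chrom = grp$chrom[1],
        strand = grp$strand[1], start = min(grp$start), end = max(grp$end),
        members = paste(grp$unit_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$strand, out$start, out$gene_id), , drop = FALSE]
  out <- cbind(curated_id = paste0("Curated", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  out$curated_id <- as.character(out$curated_id)
  # recompute fractions on the merged spans
  gi <- match(out$gene_id, spans$gene_id)
  t_len <- spans$end[gi] - spans$start[gi]
  ov_t <- pmax(0, pmin(out$end, spans$end[gi]) - pmax(out$start, spans$start[gi]))
  orf_start <- ann$genes$orf_start[gi]
  orf_end <- ann$genes$orf_end[gi]
  ov_orf <- pmax(0, pmin(out$end, orf_end) - pmax(out$start, orf_start))
  out$frac_transcript <- ov_t / t_len
  out$frac_orf <- ov_orf / (orf_end - orf_start)
  out$tier <- .tier(ov_orf, orf_end - orf_start)
  rownames(out) <- NULL
  out
}

#' Compare an antisense catalog to an external catalog
#'
#' For each unit, among same-strand overlapping external units the one
#' maximizing `|intersection| / |unit|` is chosen (ties go to the larger
#' external unit, then to the lexicographically smaller id). A unit is
#' `matched` when that fraction reaches `min_overlap` and `covered80`
#' when it reaches `covered_frac`.
#'
#' @param units data.frame of units.
#' @param external data.frame of external units (columns `chrom`,
#'   `start`, `end`, `name`, `strand`; e.g. from [read_bed6()]).
#' @param min_overlap match threshold (default 0.5).
#' @param covered_frac high-coverage threshold (default 0.8).
#' @return data.frame with columns `unit_id`, `best_external_id`,
#'   `overlap_frac`, `matched`, `covered80`.
#' @export
compare_catalogs <- function(units, external, min_overlap = 0.5,
                             covered_frac = 0.8) {
  stopifnot(min_overlap > 0, min_overlap <= 1,
            covered_frac > 0, covered_frac <= 1)
  ext <- data.frame(chrom = external$chrom, start = external$start,
                    end = external$end, strand = external$strand,
                    gene_id = external$name, stringsAsFactors = FALSE)
  p <- .overlap_pairs(units, ext, "same")
  out <- data.frame(unit_id = units$unit_id, best_external_id = NA_character_,
                    overlap_frac = 0, stringsAsFactors = FALSE)
  if (nrow(p) > 0L) {
    frac <- p$overlap / (units$end[p$u] - units$start[p$u])
    ext_w <- ext$end[p$g] - ext$start[p$g]
    ord <- order(p$u, -frac, -ext_w, ext$gene_id[p$g])
    best <- p[ord, , drop = FALSE][!duplicated(p$u[ord]), , drop = FALSE]
    bfrac <- frac[ord][!duplicated(p$u[ord])]
    out$best_external_id[best$u] <- ext$gene_id[best$g]
    out$overlap_frac[best$u] <- bfrac
  }
  out$matched <- out$overlap_frac >= min_overlap
  out$covered80 <- out$overlap_frac >= covered_frac
  out
}

#' Strand-specificity QC: antisense read fraction
#'
#' Among fragments whose center falls inside exactly one gene's
#' UTR-extended transcript span (positions covered by transcripts of
#' more than one gene — in particular on both strands — are excluded as
#' ambiguous), the fraction whose strand is opposite to that gene's
#' measures the library's strand flip ("leak") rate.
#'
#' @param frags data.frame of fragments (`chrom`, `strand`, `start`,
#'   `end`).
#' @param ann an [annotation()].
#' @return list with `antisense_read_fraction` and `n_informative` (the
#'   denominator).
#' @export
antisense_read_fraction <- function(frags, ann) {
  if (nrow(ann$genes) == 0L)
    stop("antisense_read_fraction: empty annotation")
  spans <- transcript_spans(ann)
  pos <- fragment_center(frags$start, frags$end)
  cgr <- .as_granges(frags$chrom, pos, pos + 1, "*")
  ggr <- .as_granges(spans$chrom, spans$start, spans$end, "*")
  nhit <- GenomicRanges::countOverlaps(cgr, ggr)
  keep <- which(nhit == 1L)
  if (length(keep) == 0L)
    stop("antisense_read_fraction: no fragment center falls in exactly one transcript span")
  hits <- GenomicRanges::findOverlaps(cgr[keep], ggr)
  gene_strand <- spans$strand[S4Vectors::subjectHits(hits)]
  anti <- frags$strand[keep][S4Vectors::queryHits(hits)] != gene_strand
  list(antisense_read_fraction = mean(anti), n_informative = length(keep))
}
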