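#' Gene-model annotations
#'
#' An annotation bundles a table of gene models with chromosome lengths.
#' Each gene model is an ORF interval on a strand plus 5' and 3' UTR
#' extensions; together these define the "known transcript boundaries"
#' used by every downstream operation. Coordinates are 0-based half-open.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `orf_start`, `orf_end` (0-based half-open),
#'   `utr5_len`, `utr3_len` (non-negative bp).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#'   When `NULL`, each chromosome's length is taken as the furthest
#'   UTR-extended coordinate of any gene on it.
#' @return An object of class `asu_annotation`: a list with elements
#'   `genes` and `chrom_lengths`.
#' @export
annotation <- function(genes, chrom_lengths = NULL) {
  req <- c("gene_id", "chrom", "strand", "orf_start", "orf_end",
           "utr5_len", "utr3_len")
  missing_cols <- setdiff(req, names(genes))
  if (length(missing_cols) > 0L)
    stop("annotation: missing columns: ", paste(missing_cols, collapse = ", "))
  genes <- as.data.frame(genes)[, req]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$strand <- as.character(genes$strand)
  if (anyDuplicated(genes$gene_id))
    stop("annotation: duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("annotation: strand must be '+' or '-'")
  if (any(genes$orf_start >= genes$orf_end))
    stop("annotation: orf_start must be < orf_end")
  if (any(genes$utr5_len < 0) || any(genes$utr3_len < 0))
    stop("annotation: UTR lengths must be non-negative")
  if (is.null(chrom_lengths)) {
    if (nrow(genes) > 0L) {
      far <- pmax(genes$orf_end + genes$utr3_len, genes$orf_end + genes$utr5_len)
      chrom_lengths <- tapply(far, genes$chrom, max)
      chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
    } else {
      chrom_lengths <- setNames(numeric(0), character(0))
    }
  }
  bad <- setdiff(genes$chrom, names(chrom_lengths))
  if (length(bad) > 0L)
    stop("annotation: chromosome(s) not in chrom_lengths: ",
         paste(unique(bad), collapse = ", "))
  structure(list(genes = genes, chrom_lengths = chrom_lengths),
            class = "asu_annotation")
}

#' @export
print.asu_annotation <- function(x, ...) {
  cat("asu_annotation:", nrow(x$genes), "gene(s) on",
      length(x$chrom_lengths), "chromosome(s)\n")
  if (nrow(x$genes) > 0L) print(head(x$genes, 6L))
  invisible(x)
}

#' UTR-extended transcript spans
#'
#' Extend each ORF by its UTR lengths, strand-aware: on `+` the 5' UTR
#' extends the start and the 3' UTR the end; on `-` the reverse. Spans
#' are clipped to `[0, chromosome length)` because published UTR
#' estimates can overrun contig ends.
#'
#' @param ann an [annotation()].
#' @return data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open transcript span).
#' @export
transcript_spans <- function(ann) {
  g <- ann$genes
  plus <- g$strand == "+"
  start <- ifelse(plus, g$orf_start - g$utr5_len, g$orf_start - g$utr3_len)
  end <- ifelse(plus, g$orf_end + g$utr3_len, g$orf_end + g$utr5_len)
  len <- unname(ann$chrom_lengths[g$chrom])
  data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             start = pmax(0, start), end = pmin(len, end),
             stringsAsFactors = FALSE)
}

#' Transcript span of a single gene model
#'
#' @param gene one-row data.frame (or list) with the gene-model fields.
#' @param chrom_length chromosome length used for clipping (default
#'   `Inf`, i.e. clip only at 0).
#' @return list with `chrom`, `strand`, `start`, `end`.
#' @export
transcript_span <- function(gene, chrom_length = Inf) {
  gene <- as.list(gene)
  if (gene$strand == "+") {
    s <- gene$orf_start - gene$utr5_len
    e <- gene$orf_end + gene$utr3_len
  } else {
    s <- gene$orf_start - gene$utr3_len
    e <- gene$orf_end + gene$utr5_len
  }
  list(chrom = gene$chrom, strand = gene$strand,
       start = max(0, s), end = min(chrom_length, e))
}

#' Genes near a genomic interval
#'
#' Returns every gene whose UTR-extended transcript span lies within
#' `margin` bp of the query interval (overlap counts as distance 0),
#' regardless of strand, sorted by distance with ties broken by
#' `gene_id`.
#'
#' @param ann an [annotation()].
#' @param interval list or one-row data.frame with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param margin maximum gap in bp (>= 0).
#' @return data.frame with the gene-model columns plus `distance`
#'   (non-negative gap in bp) and `side` (`"left"`, `"right"`,
#'   `"overlap"` relative to the query).
#' @export
neighbors <- function(ann, interval, margin) {
  stopifnot(margin >= 0)
  interval <- as.list(interval)
  if (!interval$chrom %in% names(ann$chrom_lengths))
    stop("neighbors: unknown chromosome: ", interval$chrom)
  spans <- transcript_spans(ann)
  spans <- spans[spans$chrom == interval$chrom, , drop = FALSE]
  empty <- merge(ann$genes[0, ], data.frame(distance = numeric(0),
                                            side = character(0)))
  if (nrow(spans) == 0L) return(empty)
  # gap between [start,end) intervals; 0 on overlap
  d_left <- interval$start - spans$end   # > 0 when gene entirely left
  d_right <- spans$start - interval$end  # > 0 when gene entirely right
  dist <- pmax(d_left, d_right, 0)
  side <- ifelse(d_left > 0, "left", ifelse(d_right > 0, "right", "overlap"))
  keep <- dist <= margin
  if (!any(keep)) return(empty)
  out <- merge(data.frame(gene_id = spans$gene_id[keep],
                          distance = dist[keep], side = side[keep],
                          stringsAsFactors = FALSE),
               ann$genes, by = "gene_id", sort = FALSE)
  out <- out[order(abs(out$distance), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c(names(ann$genes), "distance", "side")]
}
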