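#' Read a gene annotation from GFF3 or BED
#'
#' Gene models come from `gene` features of a GFF3 file (1-based closed
#' coordinates, converted to 0-based half-open on read) or from a BED6
#' file (already 0-based half-open). UTR lengths are taken, in order of
#' precedence, from the UTR table, from `utr5_len`/`utr3_len` GFF3
#' attributes (the package's own dialect), or from `default_utr` — the
#' fallback used when no measured UTR estimate exists.
#'
#' @param path GFF3 or BED6 file.
#' @param utr_table optional TSV with columns (gene_id, utr5_len,
#'   utr3_len); `#` comment lines allowed.
#' @param default_utr UTR length in bp assigned to genes with no UTR
#'   information (default 100).
#' @param chrom_lengths optional named vector of chromosome lengths;
#'   overrides lengths found in the file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return An [annotation()].
#' @export
read_annotation <- function(path, utr_table = NULL, default_utr = 100,
                            chrom_lengths = NULL,
                            format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (format == "gff3") {
    gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                   error = function(e) stop("read_annotation: parse error in ",
                                            path, ": ", conditionMessage(e)))
    gr <- gr[as.character(gr$type) == "gene"]
    ids <- as.character(gr$ID)
    if (anyNA(ids) || any(ids == ""))
      stop("read_annotation: gene record without ID attribute")
    genes <- data.frame(
      gene_id = ids,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      orf_start = GenomicRanges::start(gr) - 1L,
      orf_end = GenomicRanges::end(gr),
      utr5_len = if (!is.null(gr$utr5_len)) as.numeric(as.character(gr$utr5_len)) else NA_real_,
      utr3_len = if (!is.null(gr$utr3_len)) as.numeric(as.character(gr$utr3_len)) else NA_real_,
      stringsAsFactors = FALSE)
    if (is.null(chrom_lengths)) {
      # prefer explicit ##sequence-region pragmas, fall back to seqinfo
      prag <- grep("^##sequence-region\\b", readLines(path), value = TRUE)
      if (length(prag) > 0L) {
        parts <- strsplit(trimws(prag), "[ \t]+")
        chrom_lengths <- vapply(parts, function(p) as.numeric(p[4]),
                                numeric(1))
        names(chrom_lengths) <- vapply(parts, `[`, character(1), 2)
      } else {
        sl <- GenomeInfoDb::seqlengths(gr)
        if (!all(is.na(sl))) chrom_lengths <- sl[!is.na(sl)]
      }
    }
  } else {
    bed <- read_bed6(path)
    genes <- data.frame(
      gene_id = bed$name, chrom = bed$chrom, strand = bed$strand,
      orf_start = bed$start, orf_end = bed$end,
      utr5_len = NA_real_, utr3_len = NA_real_, stringsAsFactors = FALSE)
  }
  if (anyDuplicated(genes$gene_id))
    stop("read_annotation: duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (!is.null(utr_table)) {
    utr <- if (is.character(utr_table)) read_utr_table(utr_table) else utr_table
    m <- match(genes$gene_id, utr$gene_id)
    genes$utr5_len <- ifelse(!is.na(m), utr$utr5_len[m], genes$utr5_len)
    genes$utr3_len <- ifelse(!is.na(m), utr$utr3_len[m], genes$utr3_len)
  }
  genes$utr5_len[is.na(genes$utr5_len)] <- default_utr
  genes$utr3_len[is.na(genes$utr3_len)] <- default_utr
  annotation(genes, chrom_lengths = chrom_lengths)
}

#' Read a UTR-length table
#'
#' Tab-separated columns (gene_id, utr5_len, utr3_len); `#` comments.
#' @param path TSV file.
#' @return data.frame with columns `gene_id`, `utr5_len`, `utr3_len`.
#' @export
read_utr_table <- function(path) {
  tab <- read.table(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3L)
    stop("read_utr_table: expected 3 tab-separated columns in ", path)
  names(tab)[1:3] <- c("gene_id", "utr5_len", "utr3_len")
  if (any(tab$utr5_len < 0) || any(tab$utr3_len < 0))
    stop("read_utr_table: negative UTR length")
  tab[, 1:3]
}

#' @rdname read_utr_table
#' @param ann an [annotation()].
#' @export
write_utr_table <- function(ann, path) {
  g <- ann$genes
  writeLines("# gene_id\tutr5_len\tutr3_len", path)
  write.table(g[, c("gene_id", "utr5_len", "utr3_len")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Write an annotation
#'
#' `write_annotation_gff3()` writes `gene` records with `utr5_len` /
#' `utr3_len` attributes and sequence-region pragmas (the package's own
#' GFF3 dialect, lossless on re-read). `write_annotation_bed()` echoes
#' the ORF intervals as BED6 with name = gene_id and score = 0.
#'
#' @param ann an [annotation()].
#' @param path output file.
#' @export
write_annotation_gff3 <- function(ann, path) {
  g <- ann$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$orf_start + 1L, end = g$orf_end),
    strand = g$strand,
    type = "gene", ID = g$gene_id,
    utr5_len = g$utr5_len, utr3_len = g$utr3_len,
    seqlengths = ann$chrom_lengths[sort(unique(g$chrom))])
  rtracklayer::export(gr, path, format = "gff3")
  # rtracklayer does not always emit sequence-region pragmas; add them
  # right after the version line so the lengths survive a round trip
  lines <- readLines(path)
  prag <- sprintf("##sequence-region %s 1 %d", names(ann$chrom_lengths),
                  as.integer(ann$chrom_lengths))
  v <- grep("^##gff-version", lines)[1]
  if (is.na(v)) v <- 0L
  writeLines(c(lines[seq_len(v)], prag, lines[-seq_len(v)]), path)
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
write_annotation_bed <- function(ann, path) {
  g <- ann$genes
  write_bed6(data.frame(chrom = g$chrom, start = g$orf_start,
                        end = g$orf_end, name = g$gene_id, score = 0,
                        strand = g$strand, stringsAsFactors = FALSE),
             path)
}

#' Read/write BED6 interval files
#'
#' Minimal strict BED6 support used across the package: intervals are
#' returned 0-based half-open with `chrom`, `start`, `end`, `name`,
#' `score`, `strand` columns. Malformed lines raise errors with the
#' offending line number.
#'
#' @param path BED6 file.
#' @return data.frame with the six BED columns.
#' @export
read_bed6 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 6L))
    stop("read_bed6: line ", lineno[which(n < 6L)[1]],
         ": expected >= 6 tab-separated fields")
  mat <- t(vapply(fields, function(f) f[1:6], character(6)))
  start <- suppressWarnings(as.numeric(mat[, 2]))
  end <- suppressWarnings(as.numeric(mat[, 3]))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad) > 0L)
    stop("read_bed6: line ", lineno[bad[1]],
         ": invalid interval (need numeric start < end)")
  badstr <- which(!mat[, 6] %in% c("+", "-", "."))
  if (length(badstr) > 0L)
    stop("read_bed6: line ", lineno[badstr[1]], ": invalid strand")
  data.frame(chrom = mat[, 1], start = start, end = end, name = mat[, 4],
             score = suppressWarnings(as.numeric(mat[, 5])),
             strand = mat[, 6], stringsAsFactors = FALSE)
}

#' @rdname read_bed6
#' @param bed data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
write_bed6 <- function(bed, path) {
  stopifnot(all(c("chrom", "start", "end", "name", "score", "strand")
                %in% names(bed)))
  write.table(bed[, c("chrom", "start", "end", "name", "score", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
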