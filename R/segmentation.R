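#' Fragment centers
#'
#' The center of a paired-end fragment `[start, end)` is
#' `floor((start + end) / 2)`; even-length fragments take the lower
#' median so the result is deterministic.
#'
#' @param start,end numeric vectors of 0-based half-open fragment
#'   coordinates (`start < end`).
#' @return integer-valued vector of center positions.
#' @export
fragment_center <- function(start, end) {
  stopifnot(all(start < end))
  floor((start + end) / 2)
}

#' Strand-specific fragment-center coverage
#'
#' Counts fragment centers per base, separately per chromosome and
#' strand. The total mass equals the number of fragments.
#'
#' @param frags data.frame with columns `chrom`, `strand` (`+`/`-`),
#'   `start`, `end` (0-based half-open outer span of the read pair).
#' @return data.frame with columns `chrom`, `strand`, `pos`, `count`,
#'   sorted by (chrom, strand, pos); only positions with `count >= 1`
#'   are stored.
#' @export
compute_center_coverage <- function(frags) {
  empty <- data.frame(chrom = character(0), strand = character(0),
                      pos = numeric(0), count = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(frags) || nrow(frags) == 0L) return(empty)
  stopifnot(all(frags$start < frags$end), all(frags$strand %in% c("+", "-")))
  pos <- fragment_center(frags$start, frags$end)
  key <- paste(frags$chrom, frags$strand, sep = "\r")
  groups <- split(pos, key)
  keys <- names(groups)
  ord <- order(keys)
  res <- vector("list", length(groups))
  for (i in seq_along(ord)) {
    k <- keys[ord[i]]
    cs <- strsplit(k, "\r", fixed = TRUE)[[1]]
    r <- rle(sort(groups[[k]]))
    res[[i]] <- data.frame(chrom = cs[1], strand = cs[2],
                           pos = as.numeric(r$values),
                           count = as.numeric(r$lengths),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Segment center coverage into transcribed units
#'
#' A position is "signal" when its center count is at least `min_cov`;
#' maximal runs of signal positions whose internal gaps of consecutive
#' non-signal positions are each at most `max_gap` bp form one unit.
#' The default `min_cov = 2` reads "coverage greater than one"
#' literally; `max_gap = 20` tolerates short drop-outs in sparsely
#' covered transcripts. Unit boundaries are defined by signal positions
#' only — there is no extension by fragment length.
#'
#' @param cov center coverage from [compute_center_coverage()].
#' @param min_cov minimum center count for a signal position (>= 1).
#' @param max_gap maximum run of non-signal positions bridged within a
#'   unit (>= 0).
#' @return data.frame of units with columns `unit_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open), `n_centers` (total
#'   center count within the span) and `peak_coverage`, sorted by
#'   (chrom, strand, start) with ids `Unit1`, `Unit2`, ... in that
#'   order.
#' @export
call_units <- function(cov, min_cov = 2, max_gap = 20) {
  if (min_cov < 1) stop("call_units: min_cov must be >= 1")
  if (max_gap < 0) stop("call_units: max_gap must be >= 0")
  empty <- data.frame(unit_id = character(0), chrom = character(0),
                      strand = character(0), start = numeric(0),
                      end = numeric(0), n_centers = numeric(0),
                      peak_coverage = numeric(0), stringsAsFactors = FALSE)
  if (is.null(cov) || nrow(cov) == 0L) return(empty)
  cov <- cov[order(cov$chrom, cov$strand, cov$pos), , drop = FALSE]
  res <- list()
  for (grp in split(cov, list(cov$chrom, cov$strand), drop = TRUE)) {
    sig <- grp[grp$count >= min_cov, , drop = FALSE]
    if (nrow(sig) == 0L) next
    # gap between consecutive signal positions p, q is q - p - 1
    brk <- c(TRUE, diff(sig$pos) - 1 > max_gap)
    run <- cumsum(brk)
    starts <- as.numeric(tapply(sig$pos, run, min))
    ends <- as.numeric(tapply(sig$pos, run, max)) + 1
    # assign every stored position (signal or not) to its covering unit
    idx <- findInterval(grp$pos, starts)
    inside <- idx >= 1L & grp$pos < ends[pmax(idx, 1L)]
    n_centers <- as.numeric(rowsum(grp$count[inside], idx[inside]))
    peak <- as.numeric(tapply(grp$count[inside], idx[inside], max))
    res[[length(res) + 1L]] <- data.frame(
      chrom = grp$chrom[1], strand = grp$strand[1],
      start = as.numeric(starts), end = as.numeric(ends),
      n_centers = n_centers, peak_coverage = peak,
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) return(empty)
  units <- do.call(rbind, res)
  units <- units[order(units$chrom, units$strand, units$start), , drop = FALSE]
  units <- cbind(unit_id = paste0("Unit", seq_len(nrow(units))), units,
                 stringsAsFactors = FALSE)
  units$unit_id <- as.character(units$unit_id)
  rownames(units) <- NULL
  units
}

#' Read/write transcribed units as BED6
#'
#' Units are exchanged as BED6 with name = unit_id and score =
#' peak coverage.
#'
#' @param units data.frame from [call_units()].
#' @param path BED6 file.
#' @export
write_units <- function(units, path) {
  write_bed6(data.frame(chrom = units$chrom, start = units$start,
                        end = units$end, name = units$unit_id,
                        score = units$peak_coverage, strand = units$strand,
                        stringsAsFactors = FALSE), path)
}

#' @rdname write_units
#' @export
read_units <- function(path) {
  bed <- read_bed6(path)
  data.frame(unit_id = bed$name, chrom = bed$chrom, strand = bed$strand,
             start = bed$start, end = bed$end, n_centers = NA_real_,
             peak_coverage = bed$score, stringsAsFactors = FALSE)
}

#' Write per-strand center coverage as bedGraph
#'
#' Produces `<prefix>.plus.bedgraph` and `<prefix>.minus.bedgraph`
#' (0-based half-open single-base records).
#'
#' @param cov center coverage from [compute_center_coverage()].
#' @param out_prefix path prefix for the two files.
#' @return character vector of the two file paths, invisibly.
#' @export
write_center_bedgraph <- function(cov, out_prefix) {
  paths <- c(paste0(out_prefix, ".plus.bedgraph"),
             paste0(out_prefix, ".minus.bedgraph"))
  for (i in 1:2) {
    s <- c("+", "-")[i]
    sub <- cov[cov$strand == s, , drop = FALSE]
    write.table(data.frame(sub$chrom, sub$pos, sub$pos + 1, sub$count),
                paths[i], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}
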