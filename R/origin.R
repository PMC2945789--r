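# Leaky-transcription origin taxonomy for antisense units, runthrough
# flagging, and the supporting statistics.

# 5'/3' boundary coordinates of a half-open interval by strand
.five_prime <- function(strand, start, end) ifelse(strand == "+", start, end)
.three_prime <- function(strand, start, end) ifelse(strand == "+", end, start)

#' Classify the plausible transcriptional origin of an antisense unit
#'
#' Each antisense unit receives exactly one label, tested in strict
#' precedence order (first hit wins), following an order of successive
#' elimination:
#' \enumerate{
#'   \item `SENSE_3UTR_EXTENSION` — a same-strand gene's transcript 3'
#'     end lies at most `margin` bp upstream of the unit's 5' end, so
#'     the unit could be that gene's long 3' UTR;
#'   \item `SENSE_5UTR_EXTENSION` — a same-strand gene's transcript 5'
#'     end lies at most `margin` bp downstream of the unit's 3' end
#'     (the unit could be a long 5' UTR);
#'   \item `DIVERGENT_PROMOTER` — an opposite-strand gene's 5' end lies
#'     at most `margin` bp from the unit's 5' end with the gene
#'     transcribed away from the unit (5'-to-5' configuration;
#'     head-on proximity does not qualify);
#'   \item `ADJACENT_3NFR` — any gene's transcript 3' end lies at most
#'     `margin` bp from the unit's 5' end (transcription from a
#'     nucleosome-free region in an adjacent 3' UTR; either strand);
#'   \item `UNEXPLAINED` otherwise.
#' }
#' Distances are boundary-to-boundary in bp; for the directional rules
#' (1)-(3) an overlap in the implied configuration counts as distance 0.
#'
#' @param unit list or one-row data.frame with `chrom`, `strand`,
#'   `start`, `end`.
#' @param ann an [annotation()].
#' @param margin distance margin in bp (default 400).
#' @return list with `origin_class`, `gene_id` (supporting gene or
#'   `NA`), `distance` (bp or `NA`).
#' @export
classify_origin <- function(unit, ann, margin = 400) {
  stopifnot(margin >= 0)
  unit <- as.list(unit)
  if (!unit$chrom %in% names(ann$chrom_lengths))
    stop("classify_origin: unknown chromosome: ", unit$chrom)
  spans <- transcript_spans(ann)
  spans <- spans[spans$chrom == unit$chrom, , drop = FALSE]
  dir <- if (unit$strand == "+") 1 else -1
  u5 <- .five_prime(unit$strand, unit$start, unit$end)
  u3 <- .three_prime(unit$strand, unit$start, unit$end)
  result <- function(class, dist) {
    if (all(!is.finite(dist))) return(NULL)
    ord <- order(dist, spans$gene_id)
    i <- ord[1]
    if (!is.finite(dist[i]) || dist[i] > margin) return(NULL)
    list(origin_class = class, gene_id = spans$gene_id[i],
         distance = dist[i])
  }
  if (nrow(spans) > 0L) {
    g5 <- .five_prime(spans$strand, spans$start, spans$end)
    g3 <- .three_prime(spans$strand, spans$start, spans$end)
    same <- spans$strand == unit$strand
    # a gene boundary overlapping the unit counts as distance 0, but
    # only the boundary each rule is about: otherwise a unit embedded
    # deep inside an opposite-strand gene body would read as divergent
    g5_in <- g5 >= unit$start & g5 <= unit$end
    g3_in <- g3 >= unit$start & g3 <= unit$end
    # directional distance: the boundary-to-boundary gap when the
    # configuration is open, 0 when the gene boundary of interest lies
    # inside the unit with an overhang still within the margin, closed
    # (Inf) otherwise
    ddist <- function(raw, b_in) {
      ifelse(raw >= 0, raw, ifelse(b_in & raw >= -margin, 0, Inf))
    }
    # (1) unit as a long 3' UTR of an upstream same-strand gene
    d1 <- ifelse(same, ddist((u5 - g3) * dir, g3_in), Inf)
    r <- result("SENSE_3UTR_EXTENSION", d1)
    if (!is.null(r)) return(r)
    # (2) unit as a long 5' UTR of a downstream same-strand gene
    d2 <- ifelse(same, ddist((g5 - u3) * dir, g5_in), Inf)
    r <- result("SENSE_5UTR_EXTENSION", d2)
    if (!is.null(r)) return(r)
    # (3) shared divergent promoter with an opposite-strand gene
    # (5'-to-5' configuration; head-on or embedded does not qualify)
    d3 <- ifelse(!same, ddist((u5 - g5) * dir, g5_in), Inf)
    r <- result("DIVERGENT_PROMOTER", d3)
    if (!is.null(r)) return(r)
    # (4) potential NFR in the 3' UTR of an adjacent transcript
    d4 <- abs(g3 - u5)
    r <- result("ADJACENT_3NFR", d4)
    if (!is.null(r)) return(r)
  }
  list(origin_class = "UNEXPLAINED", gene_id = NA_character_,
       distance = NA_real_)
}

#' @rdname classify_origin
#' @param units data.frame of (curated) antisense units with an id in
#'   the first column.
#' @return For `classify_origins()`: data.frame with columns `unit_id`,
#'   `origin_class`, `gene_id`, `distance`.
#' @export
classify_origins <- function(units, ann, margin = 400) {
  rows <- lapply(seq_len(nrow(units)), function(i) {
    r <- classify_origin(units[i, , drop = FALSE], ann, margin = margin)
    data.frame(unit_id = units[[1]][i], origin_class = r$origin_class,
               gene_id = r$gene_id, distance = r$distance,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(unit_id = character(0), origin_class = character(0),
                      gene_id = character(0), distance = numeric(0))
  out
}

#' Flag antisense units that may block runthrough transcription
#'
#' A unit is flagged when its 3' end lies within `max_dist` bp
#' (strictly) of the transcript 3' end of an opposite-strand
#' (convergent) gene; the nearest such gene is reported.
#'
#' @param unit list or one-row data.frame with `chrom`, `strand`,
#'   `start`, `end`.
#' @param ann an [annotation()].
#' @param max_dist flagging distance in bp (default 200; strict `<`).
#' @return list with `flagged`, `blocked_gene_id` (or `NA`),
#'   `distance_bp` (or `NA`).
#' @export
flag_runthrough <- function(unit, ann, max_dist = 200) {
  stopifnot(max_dist >= 0)
  unit <- as.list(unit)
  spans <- transcript_spans(ann)
  spans <- spans[spans$chrom == unit$chrom & spans$strand != unit$strand, ,
                 drop = FALSE]
  if (nrow(spans) == 0L)
    return(list(flagged = FALSE, blocked_gene_id = NA_character_,
                distance_bp = NA_real_))
  u3 <- .three_prime(unit$strand, unit$start, unit$end)
  g3 <- .three_prime(spans$strand, spans$start, spans$end)
  d <- abs(g3 - u3)
  i <- order(d, spans$gene_id)[1]
  list(flagged = d[i] < max_dist,
       blocked_gene_id = if (d[i] < max_dist) spans$gene_id[i] else NA_character_,
       distance_bp = d[i])
}

#' @rdname flag_runthrough
#' @param units data.frame of units with an id in the first column.
#' @return For `flag_runthroughs()`: data.frame with columns `unit_id`,
#'   `flagged`, `blocked_gene_id`, `distance_bp`.
#' @export
flag_runthroughs <- function(units, ann, max_dist = 200) {
  rows <- lapply(seq_len(nrow(units)), function(i) {
    r <- flag_runthrough(units[i, , drop = FALSE], ann, max_dist = max_dist)
    data.frame(unit_id = units[[1]][i], flagged = r$flagged,
               blocked_gene_id = r$blocked_gene_id,
               distance_bp = r$distance_bp, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Wilcoxon rank-sum test with an exact small-sample path
#'
#' The statistic is the sum of the midranks of `group_a` in the pooled
#' sample. With `n_a + n_b <= exact_max` (default 12) the p-value is
#' computed by exact enumeration of all rank assignments (valid under
#' ties because midranks are permuted); otherwise by the normal
#' approximation with tie correction and continuity correction.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @param alternative `"two_sided"` (default), `"less"` or `"greater"`
#'   (location of `group_a` relative to `group_b`).
#' @param exact_max combined sample size at or below which the exact
#'   path is used.
#' @return list with `statistic` (rank sum of `group_a`), `p_value`,
#'   and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(group_a, group_b,
                              alternative = c("two_sided", "less", "greater"),
                              exact_max = 12) {
  alternative <- match.arg(alternative)
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("wilcoxon_rank_sum: both groups must be non-empty")
  pooled <- c(group_a, group_b)
  stopifnot(all(is.finite(pooled)))
  n_a <- length(group_a)
  n_b <- length(group_b)
  N <- n_a + n_b
  r <- rank(pooled)  # midranks
  w <- sum(r[seq_len(n_a)])
  if (N <= exact_max) {
    sets <- combn(N, n_a)
    ws <- colSums(matrix(r[sets], nrow = n_a))
    eps <- 1e-9
    p_less <- mean(ws <= w + eps)
    p_greater <- mean(ws >= w - eps)
    method <- "exact"
  } else {
    mu <- n_a * (N + 1) / 2
    ties <- table(r)
    sigma2 <- n_a * n_b / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p_less <- p_greater <- 1
    } else {
      sigma <- sqrt(sigma2)
      p_less <- pnorm((w - mu + 0.5) / sigma)
      p_greater <- pnorm((w - mu - 0.5) / sigma, lower.tail = FALSE)
    }
    method <- "normal"
  }
  p <- switch(alternative,
              less = p_less,
              greater = p_greater,
              two_sided = min(1, 2 * min(p_less, p_greater)))
  list(statistic = w, p_value = p, method = method)
}

#' Correlation between antisense and neighbor-gene expression changes
#'
#' Pearson correlation (and its square) between the differential
#' expression of antisense units and that of the neighboring genes they
#' could be co-regulated with; a high value would indicate leaky
#' co-transcription.
#'
#' @param x,y numeric vectors of paired log-ratios (>= 3 finite pairs).
#' @return list with `r` and `r_squared`.
#' @export
neighbor_expression_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (sd(x) == 0 || sd(y) == 0)
    stop("neighbor_expression_correlation: zero variance")
  r <- cor(x, y)
  list(r = r, r_squared = r^2)
}
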