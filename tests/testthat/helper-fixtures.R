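# Shared in-code fixtures for the unit tests.

# A small two-chromosome annotation with genes on both strands.
toy_annotation <- function() {
  annotation(data.frame(
    gene_id = c("YA1", "YA2", "YB1"),
    chrom = c("chrI", "chrI", "chrII"),
    strand = c("+", "-", "+"),
    orf_start = c(1000, 5000, 300),
    orf_end = c(2000, 6200, 900),
    utr5_len = c(100, 150, 50),
    utr3_len = c(200, 100, 50),
    stringsAsFactors = FALSE),
    chrom_lengths = c(chrI = 10000, chrII = 2000))
}

# Units data.frame in the shape produced by call_units().
make_units <- function(chrom, strand, start, end, ids = NULL) {
  n <- length(start)
  data.frame(unit_id = if (is.null(ids)) paste0("U", seq_len(n)) else ids,
             chrom = chrom, strand = strand, start = start, end = end,
             n_centers = NA_real_, peak_coverage = NA_real_,
             stringsAsFactors = FALSE)
}

# Brute-force position-scan segmentation reference.
segment_oracle <- function(cov, min_cov = 2, max_gap = 20) {
  out <- list()
  for (grp in split(cov, list(cov$chrom, cov$strand), drop = TRUE)) {
    v <- numeric(max(grp$pos) + 1)
    v[grp$pos + 1] <- grp$count
    sig <- which(v >= min_cov) - 1
    if (length(sig) == 0L) next
    runs <- split(sig, cumsum(c(TRUE, diff(sig) - 1 > max_gap)))
    for (r in runs) {
      s <- min(r); e <- max(r) + 1
      w <- grp$pos >= s & grp$pos < e
      out[[length(out) + 1L]] <- data.frame(
        chrom = grp$chrom[1], strand = grp$strand[1], start = s, end = e,
        n_centers = sum(grp$count[w]), peak_coverage = max(grp$count[w]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  o <- do.call(rbind, out)
  o <- o[order(o$chrom, o$strand, o$start), , drop = FALSE]
  rownames(o) <- NULL
  o
}

# Per-base counting reference for overlap fractions of a unit against a
# gene's transcript span and ORF.
overlap_oracle <- function(unit_start, unit_end, t_start, t_end,
                           orf_start, orf_end) {
  unit_bases <- seq(unit_start, unit_end - 1)
  ov_t <- sum(unit_bases >= t_start & unit_bases < t_end)
  ov_o <- sum(unit_bases >= orf_start & unit_bases < orf_end)
  list(frac_transcript = ov_t / (t_end - t_start),
       frac_orf = ov_o / (orf_end - orf_start), ov_orf = ov_o)
}

# A tiny expression table with known structure.
toy_expression <- function() {
  counts <- rbind(T1_S = c(100, 200, 400, 800),
                  T1_A = c(80, 40, 20, 10),
                  POS_A = c(500, 1000, 250, 500),
                  POS_B = c(100, 200, 50, 100),
                  CTRL_1 = c(300, 600, 150, 300),
                  CTRL_2 = c(1200, 2400, 600, 1200))
  colnames(counts) <- c("midlog_r1", "midlog_r2", "shift_r1", "shift_r2")
  expression_table(counts,
                   c(T1_S = "target_sense", T1_A = "target_antisense",
                     POS_A = "positive_spike", POS_B = "positive_spike",
                     CTRL_1 = "control_gene", CTRL_2 = "control_gene"),
                   samples = data.frame(
                     sample = colnames(counts),
                     condition = c("midlog", "midlog", "shift", "shift"),
                     replicate = c(1, 2, 1, 2)))
}
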