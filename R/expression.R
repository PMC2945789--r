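# Sense-antisense differential expression: qPCR log-ratios, two-step
# nCounter-style normalization, regulation calls and discordance counts.

#' nCounter-style expression table
#'
#' A probes-by-samples count matrix with a probe class for every probe
#' (`target_sense`, `target_antisense`, `positive_spike`,
#' `control_gene`) and per-sample metadata.
#'
#' @param counts numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids); counts >= 0.
#' @param probe_class character vector (named by probe, or in row
#'   order) with values `target_sense`, `target_antisense`,
#'   `positive_spike`, `control_gene`.
#' @param samples optional data.frame of sample metadata with a
#'   `sample` column matching the matrix columns (e.g. `condition`,
#'   `replicate`).
#' @return An object of class `asu_expression`.
#' @export
expression_table <- function(counts, probe_class, samples = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("expression_table: counts must have row and column names")
  if (any(counts < 0)) stop("expression_table: negative counts")
  if (is.null(names(probe_class))) names(probe_class) <- rownames(counts)
  probe_class <- probe_class[rownames(counts)]
  valid <- c("target_sense", "target_antisense", "positive_spike",
             "control_gene")
  if (anyNA(probe_class) || !all(probe_class %in% valid))
    stop("expression_table: every probe needs a valid class")
  if (!any(probe_class == "positive_spike") ||
      !any(probe_class == "control_gene"))
    stop("expression_table: need >= 1 positive_spike and >= 1 control_gene probe")
  if (!is.null(samples)) {
    samples <- as.data.frame(samples)
    if (!all(colnames(counts) %in% samples$sample))
      stop("expression_table: sample metadata must cover all columns")
    samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
    rownames(samples) <- NULL
  }
  structure(list(counts = counts, probe_class = probe_class,
                 samples = samples), class = "asu_expression")
}

#' @export
print.asu_expression <- function(x, ...) {
  cat("asu_expression:", nrow(x$counts), "probes x", ncol(x$counts),
      "samples\n")
  print(table(x$probe_class))
  invisible(x)
}

#' Two-step normalization of an nCounter-style table
#'
#' Step 1 scales every sample to the reference sample's total of
#' positive spike-in probes (run-to-run processing efficiency). Step 2
#' further scales every sample so that the geometric mean of the
#' control-gene probes matches the reference (sample-to-sample input
#' variation; the geometric mean is robust to a single dominant
#' control). The reference sample is unchanged overall and the
#' operation is idempotent.
#'
#' @param tab an [expression_table()].
#' @param ref_sample reference sample id (default: first column).
#' @return A normalized `asu_expression` with attributes
#'   `spike_factors` and `control_factors`.
#' @export
ncounter_normalize <- function(tab, ref_sample = colnames(tab$counts)[1]) {
  stopifnot(inherits(tab, "asu_expression"))
  counts <- tab$counts
  if (!ref_sample %in% colnames(counts))
    stop("ncounter_normalize: unknown reference sample: ", ref_sample)
  spikes <- tab$probe_class == "positive_spike"
  ctrls <- tab$probe_class == "control_gene"
  spike_sum <- colSums(counts[spikes, , drop = FALSE])
  if (any(spike_sum <= 0))
    stop("ncounter_normalize: zero spike-in sum in sample(s): ",
         paste(colnames(counts)[spike_sum <= 0], collapse = ", "))
  f1 <- spike_sum[ref_sample] / spike_sum
  step1 <- sweep(counts, 2, f1, "*")
  geo <- exp(colMeans(log(step1[ctrls, , drop = FALSE])))
  if (any(!is.finite(geo)) || any(geo <= 0))
    stop("ncounter_normalize: zero control-gene value in sample(s): ",
         paste(colnames(counts)[!is.finite(geo) | geo <= 0], collapse = ", "))
  f2 <- geo[ref_sample] / geo
  out <- tab
  out$counts <- sweep(step1, 2, f2, "*")
  attr(out, "spike_factors") <- f1
  attr(out, "control_factors") <- f2
  out
}

#' Per-probe log2 expression ratios between conditions
#'
#' Averages (normalized) counts over replicates of each condition and
#' returns `log2(cond_num / cond_den)` per probe.
#'
#' @param tab a (normalized) [expression_table()] whose sample metadata
#'   has a `condition` column.
#' @param cond_num,cond_den condition labels (numerator, denominator).
#' @return named numeric vector of log2 ratios, one per probe.
#' @export
expression_log2_ratios <- function(tab, cond_num, cond_den) {
  stopifnot(inherits(tab, "asu_expression"), !is.null(tab$samples),
            "condition" %in% names(tab$samples))
  pick <- function(cond) {
    cols <- tab$samples$condition == cond
    if (!any(cols)) stop("expression_log2_ratios: no samples in condition ", cond)
    rowMeans(tab$counts[, cols, drop = FALSE])
  }
  log2(pick(cond_num) / pick(cond_den))
}

#' Strand-specific qPCR log2 ratio between two conditions
#'
#' For every (primer_set, replicate) stratum the target quantity is
#' normalized by the control gene measured in the same replicate and
#' condition, and the log2 ratio of the two conditions is formed;
#' the mean and standard deviation across strata are returned (the
#' error-bar contract: variation between biological replicates and
#' primer sets is pooled).
#'
#' @param meas data.frame with columns `target_id`, `orientation`,
#'   `primer_set`, `replicate`, `condition`, `quantity` (> 0).
#' @param target target id to evaluate.
#' @param orientation `"sense"` or `"antisense"`.
#' @param control_target control gene id (default `"PDA1"`).
#' @param cond_num,cond_den condition labels (numerator, denominator).
#' @return list with `mean`, `sd`, `n_strata` and the per-stratum
#'   ratios in `per_stratum`.
#' @export
qpcr_log_ratio <- function(meas, target, orientation = "antisense",
                           control_target = "PDA1", cond_num, cond_den) {
  stopifnot(all(meas$quantity > 0))
  tm <- meas[meas$target_id == target & meas$orientation == orientation, ,
             drop = FALSE]
  if (nrow(tm) == 0L)
    stop("qpcr_log_ratio: no measurements for target ", target,
         " (", orientation, ")")
  cm <- meas[meas$target_id == control_target, , drop = FALSE]
  strata <- unique(tm[, c("primer_set", "replicate")])
  get1 <- function(df, ps, rep, cond, what, match_primer = TRUE) {
    rows <- df[df$replicate == rep & df$condition == cond, , drop = FALSE]
    if (match_primer && any(rows$primer_set == ps))
      rows <- rows[rows$primer_set == ps, , drop = FALSE]
    if (nrow(rows) == 0L)
      stop("qpcr_log_ratio: missing ", what, " in stratum (primer_set=", ps,
           ", replicate=", rep, ", condition=", cond, ")")
    mean(rows$quantity)
  }
  ratios <- vapply(seq_len(nrow(strata)), function(i) {
    ps <- strata$primer_set[i]
    rep <- strata$replicate[i]
    t_num <- get1(tm, ps, rep, cond_num, "target")
    t_den <- get1(tm, ps, rep, cond_den, "target")
    c_num <- get1(cm, ps, rep, cond_num, "control")
    c_den <- get1(cm, ps, rep, cond_den, "control")
    log2((t_num / c_num) / (t_den / c_den))
  }, numeric(1))
  list(mean = mean(ratios),
       sd = if (length(ratios) > 1L) sd(ratios) else NA_real_,
       n_strata = length(ratios),
       per_stratum = cbind(strata, log2_ratio = ratios))
}

#' Call induction/repression from a log2 ratio
#'
#' `induced` when `log2_ratio >= threshold`, `repressed` when
#' `<= -threshold`, otherwise `no_change`. The default threshold of 1
#' (two-fold) is a configurable choice and is recorded in output
#' metadata by the analysis drivers.
#'
#' @param log2_ratio numeric vector of finite log2 ratios.
#' @param threshold call threshold (> 0).
#' @return character vector of calls.
#' @export
call_regulation <- function(log2_ratio, threshold = 1.0) {
  stopifnot(all(is.finite(log2_ratio)), threshold > 0)
  ifelse(log2_ratio >= threshold, "induced",
         ifelse(log2_ratio <= -threshold, "repressed", "no_change"))
}

#' Count discordant sense-antisense regulation pairs
#'
#' Counts, per condition, targets whose sense transcript is induced
#' while the antisense is repressed (`sense_up_as_down`) and the mirror
#' class (`sense_down_as_up`), and the sizes of the union ("either")
#' and intersection ("both") of those target sets across conditions.
#'
#' @param calls data.frame with columns `target_id`, `condition`,
#'   `sense` and `antisense` (regulation calls from
#'   [call_regulation()]). Every target must be present in every
#'   condition.
#' @return list with `per_condition` (data.frame), `either` and `both`
#'   (named counts per discordance class), and the underlying target
#'   sets in `targets`.
#' @export
count_discordant_pairs <- function(calls) {
  req <- c("target_id", "condition", "sense", "antisense")
  stopifnot(all(req %in% names(calls)))
  conds <- unique(calls$condition)
  tabs <- table(calls$target_id, calls$condition)
  incomplete <- rownames(tabs)[apply(tabs, 1, function(x) any(x != 1))]
  if (length(incomplete) > 0L)
    stop("count_discordant_pairs: unpaired target(s): ",
         paste(incomplete, collapse = ", "))
  up_down <- lapply(conds, function(cc) {
    sub <- calls[calls$condition == cc, ]
    sub$target_id[sub$sense == "induced" & sub$antisense == "repressed"]
  })
  down_up <- lapply(conds, function(cc) {
    sub <- calls[calls$condition == cc, ]
    sub$target_id[sub$sense == "repressed" & sub$antisense == "induced"]
  })
  per_condition <- data.frame(
    condition = conds,
    sense_up_as_down = vapply(up_down, length, integer(1)),
    sense_down_as_up = vapply(down_up, length, integer(1)),
    stringsAsFactors = FALSE)
  list(per_condition = per_condition,
       either = c(sense_up_as_down = length(unique(unlist(up_down))),
                  sense_down_as_up = length(unique(unlist(down_up)))),
       both = c(sense_up_as_down = length(Reduce(intersect, up_down)),
                sense_down_as_up = length(Reduce(intersect, down_up))),
       targets = list(sense_up_as_down = up_down,
                      sense_down_as_up = down_up))
}

#' Correlation between sense and antisense expression changes
#'
#' Pearson correlation of paired log2 ratios (a rank-based alternative
#' is available via `method = "spearman"`).
#'
#' @param delta_sense,delta_antisense numeric vectors of paired log2
#'   ratios (>= 3 finite pairs).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return the correlation coefficient.
#' @export
sense_antisense_correlation <- function(delta_sense, delta_antisense,
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(delta_sense) == length(delta_antisense),
            length(delta_sense) >= 3,
            all(is.finite(delta_sense)), all(is.finite(delta_antisense)))
  if (sd(delta_sense) == 0 || sd(delta_antisense) == 0)
    stop("sense_antisense_correlation: zero variance")
  cor(delta_sense, delta_antisense, method = method)
}
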