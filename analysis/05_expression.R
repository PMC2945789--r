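#!/usr/bin/env Rscript
# Step 5: expression analysis of sense-antisense pairs.
#
# nCounter-style counts are normalized in two steps (positive spike-in
# sums, then control-gene geometric means), log2 condition ratios are
# formed against the mid-log reference, induction/repression is called
# at a two-fold threshold, discordant pairs are counted, and the
# sense-antisense fold-change correlation is estimated. A strand-
# specific qPCR ratio is computed for one target as a cross-check.

suppressMessages(library(asunit))

raw <- read.table("results/simdata/ncounter_counts.tsv", sep = "\t",
                  header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE)
counts <- as.matrix(raw[, -(1:2)])
rownames(counts) <- raw$probe
samples <- data.frame(sample = colnames(counts),
                      condition = sub("_r[0-9]+$", "", colnames(counts)),
                      replicate = as.integer(sub("^.*_r", "",
                                                 colnames(counts))))
tab <- expression_table(counts, setNames(raw$probe_class, raw$probe),
                        samples = samples)
nt <- ncounter_normalize(tab)

pairs <- sub("_S$", "", raw$probe[raw$probe_class == "target_sense"])
conds <- setdiff(unique(samples$condition), "midlog")
ratios <- NULL
calls <- NULL
for (cond in conds) {
  lr <- expression_log2_ratios(nt, cond, "midlog")
  s <- unname(lr[paste0(pairs, "_S")])
  a <- unname(lr[paste0(pairs, "_A")])
  ratios <- rbind(ratios, data.frame(target_id = pairs, condition = cond,
                                     log2_sense = s, log2_antisense = a))
  calls <- rbind(calls, data.frame(target_id = pairs, condition = cond,
                                   sense = call_regulation(s),
                                   antisense = call_regulation(a)))
}
write.table(ratios, "results/expression_ratios.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(calls, "results/regulation_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

disc <- count_discordant_pairs(calls)
r <- sense_antisense_correlation(ratios$log2_sense, ratios$log2_antisense)
anti_up <- calls$antisense == "induced"
w <- wilcoxon_rank_sum(ratios$log2_sense[anti_up],
                       ratios$log2_sense[!anti_up])

qpcr <- read.table("results/simdata/qpcr.tsv", sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
qr <- qpcr_log_ratio(qpcr, pairs[1], "antisense",
                     cond_num = conds[1], cond_den = "midlog")

jsonlite::write_json(list(
  sense_antisense_correlation = r,
  r_squared = r^2,
  wilcoxon_p_sense_by_antisense_induction = w$p_value,
  n_discordant_either_condition = unname(disc$either[2]),
  n_discordant_both_conditions = unname(disc$both[1]),
  qpcr_target = pairs[1],
  qpcr_antisense_log2_ratio_mean = qr$mean,
  qpcr_antisense_log2_ratio_sd = qr$sd),
  "results/expression_summary.json", auto_unbox = TRUE, digits = NA)

cat("sense-antisense correlation:", signif(r, 4),
    "  discordant pairs (either condition):", unname(disc$either[2]), "\n")
cat("wrote results/expression_ratios.tsv, results/regulation_calls.tsv,",
    "results/expression_summary.json\n")
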