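small_cfg <- function(n_antisense = 8, ...) {
  sim_config(n_genes = 40, chrom_length = 2.5e5, n_antisense = n_antisense,
             depth = 4, ...)
}

test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "asu_sim_config")
  expect_error(sim_config(tier_mix = c(UTR_ONLY = 0.5, GE25 = 0.2, GE50 = 0.1,
                                       GE75 = 0.1, FULL = 0.05)))
  expect_error(sim_config(leak_rate = 1.5))
  expect_error(sim_config(sa_correlation = -2))
  expect_error(sim_config(ref_condition = "nope"))
})

test_that("simulated annotations are a pure function of (config, seed)", {
  cfg <- small_cfg()
  a1 <- simulate_annotation(cfg, seed = 5)
  a2 <- simulate_annotation(cfg, seed = 5)
  expect_identical(a1, a2)
  a3 <- simulate_annotation(cfg, seed = 6)
  expect_false(identical(a1$annotation$genes, a3$annotation$genes))
})

test_that("edge configurations are handled", {
  cfg0 <- sim_config(n_genes = 0, n_antisense = 0)
  s0 <- simulate_annotation(cfg0, seed = 1)
  expect_equal(nrow(s0$annotation$genes), 0)
  expect_equal(nrow(s0$truth$units), 0)
  expect_error(simulate_annotation(sim_config(n_genes = 200,
                                              chrom_length = 5e4), seed = 1),
               "too short")
  expect_error(simulate_annotation(sim_config(n_genes = 10, n_antisense = 10),
                                   seed = 1), "n_genes too small")
})

test_that("planted genes are within bounds and planted units match their tier", {
  sim <- simulate_annotation(small_cfg(), seed = 9)
  ann <- sim$annotation
  tr <- sim$truth$units
  sp <- transcript_spans(ann)
  expect_true(all(sp$start >= 0 & sp$end <= ann$chrom_lengths))
  expect_equal(nrow(tr), 8)
  # the planted tier is exactly what call_antisense computes for the
  # planted span against the target gene
  calls <- call_antisense(data.frame(unit_id = tr$unit_id, chrom = tr$chrom,
                                     strand = tr$strand, start = tr$start,
                                     end = tr$end), ann)
  m <- merge(tr, calls, by = "unit_id")
  m <- m[m$gene_id.x == m$gene_id.y, ]
  expect_equal(nrow(m), nrow(tr))
  expect_equal(m$tier.y, m$tier.x)
})

test_that("planted origin geometry is recovered by the classifier", {
  sim <- simulate_annotation(small_cfg(), seed = 13)
  oc <- classify_origins(sim$truth$units, sim$annotation)
  expect_equal(oc$origin_class, sim$truth$units$origin_class)
})

test_that("fragments respect transcript bounds, counts and lengths", {
  cfg <- small_cfg()
  sim <- simulate_annotation(cfg, seed = 2)
  fr <- simulate_fragments(sim$annotation, sim$truth, cfg, seed = 2)
  fr2 <- simulate_fragments(sim$annotation, sim$truth, cfg, seed = 2)
  expect_identical(fr, fr2)
  sp <- transcript_spans(sim$annotation)
  tx <- rbind(data.frame(id = sp$gene_id, start = sp$start, end = sp$end),
              data.frame(id = sim$truth$units$unit_id,
                         start = sim$truth$units$start,
                         end = sim$truth$units$end))
  m <- match(fr$source, tx$id)
  expect_true(all(fr$start >= tx$start[m] & fr$end <= tx$end[m]))
  len <- fr$end - fr$start
  expect_true(all(len >= cfg$frag_len_min))
  # deterministic per-transcript counts: depth x usable span
  n_by_src <- table(fr$source)
  want <- round(cfg$depth * pmax(1, (tx$end - tx$start) - cfg$frag_len_mean))
  expect_equal(as.numeric(n_by_src[tx$id]), want)
})

test_that("strand flips occur at the configured leak rate", {
  cfg <- small_cfg(leak_rate = 0.05, n_antisense = 0)
  sim <- simulate_annotation(cfg, seed = 3)
  fr <- simulate_fragments(sim$annotation, sim$truth, cfg, seed = 3)
  sp <- transcript_spans(sim$annotation)
  flipped <- fr$strand != sp$strand[match(fr$source, sp$gene_id)]
  expect_gt(mean(flipped), 0.03)
  expect_lt(mean(flipped), 0.07)
  # leak 0: no flips
  cfg0 <- small_cfg(leak_rate = 0, n_antisense = 0)
  sim0 <- simulate_annotation(cfg0, seed = 3)
  fr0 <- simulate_fragments(sim0$annotation, sim0$truth, cfg0, seed = 3)
  expect_true(all(fr0$strand ==
                  sp$strand[match(fr0$source, sp$gene_id)]))
})

test_that("fold changes carry the planted correlation structure", {
  cfg <- sim_config(n_pairs = 2000, sa_correlation = -0.8)
  fc <- simulate_fold_changes(cfg, seed = 4)
  expect_identical(fc, simulate_fold_changes(cfg, seed = 4))
  expect_equal(nrow(fc), 2000 * 2)  # two non-reference conditions
  expect_equal(cor(fc$fc_sense, fc$fc_antisense), -0.8, tolerance = 0.05)
  expect_equal(sd(fc$fc_sense), cfg$fc_sd, tolerance = 0.1)
})

test_that("expression tables have the declared structure", {
  cfg <- sim_config(n_pairs = 5, noise_sd = 0.2)
  fc <- simulate_fold_changes(cfg, seed = 5)
  ex <- simulate_expression_tables(fc, cfg, seed = 5)
  tab <- ex$table
  expect_s3_class(tab, "asu_expression")
  expect_equal(sum(tab$probe_class == "target_sense"), 5)
  expect_equal(sum(tab$probe_class == "target_antisense"), 5)
  expect_equal(sum(tab$probe_class == "positive_spike"), cfg$n_spikes)
  expect_equal(ncol(tab$counts),
               length(cfg$conditions) * cfg$n_replicates)
  expect_true(all(ex$qpcr$quantity > 0))
  expect_true("PDA1" %in% ex$qpcr$target_id)
})

test_that("zero-noise expression simulation recovers planted fold changes", {
  cfg <- sim_config(n_pairs = 4, noise_sd = 0)
  fc <- simulate_fold_changes(cfg, seed = 6)
  ex <- simulate_expression_tables(fc, cfg, seed = 6)
  nt <- ncounter_normalize(ex$table)
  lr <- expression_log2_ratios(nt, "heat_shock", "midlog")
  hs <- fc[fc$condition == "heat_shock", ]
  expect_equal(unname(lr[paste0(hs$pair_id, "_S")]), hs$fc_sense,
               tolerance = 1e-10)
  expect_equal(unname(lr[paste0(hs$pair_id, "_A")]), hs$fc_antisense,
               tolerance = 1e-10)
  qr <- qpcr_log_ratio(ex$qpcr, "T001", "sense",
                       cond_num = "heat_shock", cond_den = "midlog")
  expect_equal(qr$mean, hs$fc_sense[hs$pair_id == "T001"], tolerance = 1e-10)
})

test_that("write_simulation produces the on-disk bundle", {
  cfg <- small_cfg()
  sim <- simulate_annotation(cfg, seed = 7)
  fr <- simulate_fragments(sim$annotation, sim$truth, cfg, seed = 7)
  fc <- simulate_fold_changes(cfg, seed = 7)
  ex <- simulate_expression_tables(fc, cfg, seed = 7)
  dir <- withr::local_tempdir()
  write_simulation(list(annotation = sim$annotation, truth = sim$truth,
                        fragments = fr, expression = ex), dir)
  expect_true(all(file.exists(file.path(dir,
    c("annotation.gff3", "utr_lengths.tsv", "fragments.bed", "truth.json",
      "ncounter_counts.tsv", "qpcr.tsv")))))
  back <- read_annotation(file.path(dir, "annotation.gff3"))
  expect_equal(nrow(back$genes), nrow(sim$annotation$genes))
})
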