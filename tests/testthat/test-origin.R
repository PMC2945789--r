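# Annotations here use zero-length UTRs so transcript spans equal the
# stated intervals.
bare_ann <- function(gene_id, strand, start, end, chrom_len = 20000) {
  annotation(data.frame(gene_id = gene_id, chrom = "c", strand = strand,
                        orf_start = start, orf_end = end,
                        utr5_len = 0, utr3_len = 0),
             chrom_lengths = c(c = chrom_len))
}

test_that("a unit just downstream of a same-strand gene reads as its 3' UTR", {
  ann <- bare_ann("G", "+", 2000, 3050)
  r <- classify_origin(list(chrom = "c", strand = "+", start = 3100,
                            end = 3600), ann)
  expect_equal(r$origin_class, "SENSE_3UTR_EXTENSION")
  expect_equal(r$gene_id, "G")
  expect_equal(r$distance, 50)
})

test_that("a unit just upstream of a same-strand gene reads as its 5' UTR", {
  ann <- bare_ann("G", "+", 4000, 5000)
  r <- classify_origin(list(chrom = "c", strand = "+", start = 3500,
                            end = 3900), ann)
  expect_equal(r$origin_class, "SENSE_5UTR_EXTENSION")
  expect_equal(r$distance, 100)
})

test_that("5'-to-5' proximity with an away-reading gene is divergent", {
  # '-' unit [4300,4900): 5' end 4900; '+' gene starts at 5000, reads away
  ann <- bare_ann("G", "+", 5000, 6000)
  r <- classify_origin(list(chrom = "c", strand = "-", start = 4300,
                            end = 4900), ann)
  expect_equal(r$origin_class, "DIVERGENT_PROMOTER")
  expect_equal(r$distance, 100)
})

test_that("head-on or embedded opposite-strand proximity is not divergent", {
  # unit embedded deep inside the gene body: the gene's 5' end is far
  # away, even though the whole unit overlaps the gene
  ann <- bare_ann("G", "+", 1000, 4000)
  r <- classify_origin(list(chrom = "c", strand = "-", start = 2000,
                            end = 2800), ann)
  expect_equal(r$origin_class, "UNEXPLAINED")
  # convergent (3'-to-5' head-on) gene within margin: rule (4) applies,
  # not divergent: '-' unit's 5' end 8400 vs '+' gene ending at 8500
  ann2 <- bare_ann("G", "+", 7000, 8500)
  r2 <- classify_origin(list(chrom = "c", strand = "-", start = 8000,
                             end = 8400), ann2)
  expect_equal(r2$origin_class, "ADJACENT_3NFR")
  expect_equal(r2$distance, 100)
})

test_that("a unit overhanging an away-reading gene's 5' end is divergent at 0", {
  ann <- bare_ann("G", "+", 5000, 6000)
  r <- classify_origin(list(chrom = "c", strand = "-", start = 4300,
                            end = 5100), ann)
  expect_equal(r$origin_class, "DIVERGENT_PROMOTER")
  expect_equal(r$distance, 0)
})

test_that("an isolated unit is unexplained", {
  ann <- bare_ann("G", "+", 10000, 11000)
  r <- classify_origin(list(chrom = "c", strand = "+", start = 1000,
                            end = 1500), ann)
  expect_equal(r$origin_class, "UNEXPLAINED")
  expect_true(is.na(r$gene_id))
})

test_that("precedence: a 3' UTR explanation wins over an NFR explanation", {
  # same-strand gene upstream (rule 1, d = 50) and the same gene's 3'
  # end also satisfies rule (4); the first rule must label the unit
  ann <- bare_ann("G", "+", 2000, 3050)
  unit <- list(chrom = "c", strand = "+", start = 3100, end = 3600)
  expect_equal(classify_origin(unit, ann)$origin_class,
               "SENSE_3UTR_EXTENSION")
  # with the same-strand gene out of range, rule (4) takes over via an
  # opposite-strand 3' end: H is '-' over [3000, 4500), so its 3' end
  # (3000) lies 100 bp from the unit's 5' end (3100) while its 5' end
  # (4500) is outside the unit and reads into it (not divergent)
  ann2 <- bare_ann(c("G", "H"), c("+", "-"), c(10000, 3000), c(11000, 4500),
                   chrom_len = 20000)
  unit2 <- list(chrom = "c", strand = "+", start = 3100, end = 3600)
  r2 <- classify_origin(unit2, ann2)
  expect_equal(r2$origin_class, "ADJACENT_3NFR")
  expect_equal(r2$gene_id, "H")
  expect_equal(r2$distance, 100)
})

test_that("every unit receives exactly one label and the margin is respected", {
  ann <- bare_ann("G", "+", 2000, 3050)
  units <- make_units("c", "+", c(3100, 3500), c(3400, 3700))
  oc <- classify_origins(units, ann)
  expect_equal(nrow(oc), 2)
  valid <- c("SENSE_3UTR_EXTENSION", "SENSE_5UTR_EXTENSION",
             "DIVERGENT_PROMOTER", "ADJACENT_3NFR", "UNEXPLAINED")
  expect_true(all(oc$origin_class %in% valid))
  # distance 450 > margin 400: unexplained
  r <- classify_origin(list(chrom = "c", strand = "+", start = 3500,
                            end = 3700), ann, margin = 400)
  expect_equal(r$origin_class, "UNEXPLAINED")
  expect_error(classify_origin(list(chrom = "cX", strand = "+", start = 0,
                                    end = 10), ann), "unknown chromosome")
})

test_that("runthrough flags use a strict distance to convergent 3' ends", {
  # '+' gene [1000, 2000): 3' end 2000; '-' unit with 3' end (start) 2150
  ann <- bare_ann("G", "+", 1000, 2000)
  f <- flag_runthrough(list(chrom = "c", strand = "-", start = 2150,
                            end = 2600), ann, max_dist = 200)
  expect_true(f$flagged)
  expect_equal(f$blocked_gene_id, "G")
  expect_equal(f$distance_bp, 150)
  # exactly at max_dist: not flagged (strict <)
  f2 <- flag_runthrough(list(chrom = "c", strand = "-", start = 2200,
                             end = 2600), ann, max_dist = 200)
  expect_false(f2$flagged)
  # same-strand genes are ignored
  f3 <- flag_runthrough(list(chrom = "c", strand = "+", start = 2150,
                             end = 2600), ann, max_dist = 200)
  expect_false(f3$flagged)
  units <- make_units("c", "-", 2150, 2600)
  ft <- flag_runthroughs(units, ann)
  expect_equal(ft$flagged, TRUE)
})

test_that("wilcoxon rank-sum reproduces reference p-values", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 6)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  expect_equal(wilcoxon_rank_sum(1, 2, alternative = "less")$p_value, 0.5)
  expect_equal(wilcoxon_rank_sum(1, 2, alternative = "greater")$p_value, 1)
})

test_that("wilcoxon handles ties via midranks and matches wilcox.test", {
  a <- c(1, 2, 2, 3); b <- c(2, 4, 5, 6)
  r <- wilcoxon_rank_sum(a, b)
  # statistic equals midrank sum
  expect_equal(r$statistic, sum(rank(c(a, b))[1:4]))
  # large-sample path matches stats::wilcox.test with correction
  set.seed(8)
  x <- rnorm(15); y <- rnorm(18, 0.5)
  rn <- wilcoxon_rank_sum(x, y)
  expect_equal(rn$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                             exact = FALSE))
  expect_equal(rn$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("neighbor expression correlation returns r and r squared", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  r <- neighbor_expression_correlation(x, y)
  expect_equal(r$r, cor(x, y))
  expect_equal(r$r_squared, cor(x, y)^2)
  expect_error(neighbor_expression_correlation(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
  expect_error(neighbor_expression_correlation(1:2, 1:2))
})
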