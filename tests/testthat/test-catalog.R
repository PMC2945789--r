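test_that("sense assignment requires same strand and >= 1 bp overlap", {
  ann <- toy_annotation()
  units <- make_units("chrI", c("+", "-", "+"), c(950, 5000, 2200),
                      c(1500, 5500, 2300))
  sa <- assign_sense(units, ann)
  # U1 overlaps YA1 (same strand), U2 overlaps YA2; U3 ends exactly at
  # YA1's transcript end (2200) with zero overlap
  expect_equal(sa$gene_id[sa$unit_id == "U1"], "YA1")
  expect_equal(sa$gene_id[sa$unit_id == "U2"], "YA2")
  expect_false("U3" %in% sa$unit_id)
  expect_equal(sa$overlap_bp[sa$unit_id == "U1"], 1500 - 950)
})

test_that("antisense calls apply the transcript-fraction threshold inclusively", {
  # gene '+' transcript [900, 2200), length 1300; ORF [1000, 2000)
  ann <- toy_annotation()
  # overlap exactly 25% of the transcript: 325 bp
  u <- make_units("chrI", "-", 900, 1225)
  calls <- call_antisense(u, ann)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$frac_transcript, 325 / 1300)
  # one base less: no call
  u2 <- make_units("chrI", "-", 900, 1224)
  expect_equal(nrow(call_antisense(u2, ann)), 0)
})

test_that("ORF-coverage tiers use exact arithmetic at the boundaries", {
  # ORF [1000, 2000), length 1000
  ann <- toy_annotation()
  tier_of <- function(s, e) call_antisense(make_units("chrI", "-", s, e),
                                           ann)$tier
  expect_equal(tier_of(900, 1000 + 750), "GE75")   # exactly 75%
  expect_equal(tier_of(900, 1000 + 749), "GE50")
  expect_equal(tier_of(900, 1000 + 500), "GE50")   # exactly 50%
  expect_equal(tier_of(900, 1000 + 499), "GE25")
  expect_equal(tier_of(900, 2000), "FULL")         # whole ORF
  expect_equal(tier_of(900, 1999), "GE75")
  # UTR only: overlap confined to the 3' UTR [2000, 2200), no ORF overlap
  utr_call <- call_antisense(make_units("chrI", "-", 2000, 2700), ann,
                             min_transcript_frac = 0)
  expect_equal(utr_call$tier, "UTR_ONLY")
  expect_equal(utr_call$frac_orf, 0)
})

test_that("overlap fractions match a per-base counting oracle", {
  set.seed(3)
  for (i in 1:200) {
    orf_start <- sample(500:1500, 1)
    orf_len <- sample(50:800, 1)
    u5 <- sample(0:150, 1); u3 <- sample(0:150, 1)
    g <- data.frame(gene_id = "G", chrom = "c", strand = "+",
                    orf_start = orf_start, orf_end = orf_start + orf_len,
                    utr5_len = u5, utr3_len = u3)
    ann <- annotation(g, chrom_lengths = c(c = 5000))
    us <- sample(0:2500, 1); ue <- us + sample(20:900, 1)
    calls <- call_antisense(make_units("c", "-", us, ue), ann,
                            min_transcript_frac = 0)
    o <- overlap_oracle(us, ue, orf_start - u5, orf_start + orf_len + u3,
                        orf_start, orf_start + orf_len)
    if (nrow(calls) == 0) {
      expect_equal(o$frac_transcript, 0)
    } else {
      expect_identical(calls$frac_transcript, o$frac_transcript)
      expect_identical(calls$frac_orf, o$frac_orf)
    }
  }
})

test_that("curation merges fragmented antisense units across small gaps", {
  ann <- toy_annotation()
  # two '-' units antisense to YA1 separated by a 200 bp gap: merged
  u <- make_units("chrI", "-", c(950, 1500), c(1300, 1900))
  u$n_centers <- 50
  cur <- curate_units(u, ann, merge_gap = 200)
  expect_equal(nrow(cur), 1)
  expect_equal(c(cur$start, cur$end), c(950, 1900))
  expect_equal(cur$members, "U1,U2")
  expect_equal(cur$gene_id, "YA1")
  # 201 bp gap: not merged
  u2 <- make_units("chrI", "-", c(950, 1501), c(1300, 1900))
  u2$n_centers <- 50
  expect_equal(nrow(curate_units(u2, ann, merge_gap = 200)), 2)
  # fractions/tier recomputed on the merged span
  expect_equal(cur$frac_orf, 900 / 1000)
  expect_equal(cur$tier, "GE75")
})

test_that("curation drops units with too few supporting centers", {
  ann <- toy_annotation()
  u <- make_units("chrI", "-", c(950, 1350), c(1300, 1352))
  u$n_centers <- c(60, 2)  # the second is a 2-center leak artifact
  cur <- curate_units(u, ann, merge_gap = 200, min_centers = 5)
  expect_equal(nrow(cur), 1)
  expect_equal(cur$end, 1300)
  # units without center counts (e.g. re-read from BED) are kept
  u$n_centers <- NA_real_
  expect_equal(nrow(curate_units(u, ann, merge_gap = 200)), 1)
})

test_that("curating a single unit is the identity on its span", {
  ann <- toy_annotation()
  u <- make_units("chrI", "-", 950, 1900)
  cur <- curate_units(u, ann)
  expect_equal(nrow(cur), 1)
  expect_equal(c(cur$start, cur$end), c(950, 1900))
  expect_equal(cur$members, "U1")
})

test_that("catalog comparison picks the best same-strand external unit", {
  u <- make_units("c", "+", 1000, 2000)
  ext <- data.frame(chrom = "c", start = c(900, 1600, 1000),
                    end = c(1500, 2100, 2000),
                    name = c("e1", "e2", "e3"),
                    strand = c("+", "+", "-"))
  cmp <- compare_catalogs(u, ext)
  expect_equal(cmp$best_external_id, "e1")  # 500/1000 beats 400/1000; e3 wrong strand
  expect_equal(cmp$overlap_frac, 0.5)
  expect_true(cmp$matched)        # >= 0.5 inclusive
  expect_false(cmp$covered80)
  # no overlap at all
  cmp2 <- compare_catalogs(make_units("c", "+", 5000, 5100), ext)
  expect_false(cmp2$matched)
  expect_true(is.na(cmp2$best_external_id))
  # tie on fraction: larger external wins, then lexicographic id
  ext3 <- data.frame(chrom = "c", start = c(1000, 1000), end = c(1500, 1600),
                     name = c("small", "big"), strand = "+")
  u3 <- make_units("c", "+", 1000, 1500)
  expect_equal(compare_catalogs(u3, ext3)$best_external_id, "big")
})

test_that("expressed-gene detection measures union coverage of the span", {
  ann <- toy_annotation()
  # YA1 transcript [900, 2200): two units covering 80% in union
  u <- make_units("chrI", "+", c(900, 1800), c(1740, 2100))
  expect_equal(detect_expressed_genes(u, ann, min_frac = 0.8), "YA1")
  expect_equal(detect_expressed_genes(u[1, ], ann, min_frac = 0.8),
               character(0))
  # against the ORF only
  u2 <- make_units("chrI", "+", 1000, 1800)
  expect_equal(detect_expressed_genes(u2, ann, min_frac = 0.8,
                                      against = "orf"), "YA1")
})

test_that("select_expressed keeps the top fraction with deterministic ties", {
  counts <- c(g1 = 100, g2 = 50, g3 = 50, g4 = 10)
  expect_equal(select_expressed(counts, 0.5), c("g1", "g2"))
  expect_equal(select_expressed(counts, 0.85), c("g1", "g2", "g3", "g4"))
  expect_equal(select_expressed(numeric(0)), character(0))
})

test_that("antisense read fraction uses unambiguous centers only", {
  g <- data.frame(gene_id = c("A", "B"), chrom = "c", strand = c("+", "-"),
                  orf_start = c(100, 150), orf_end = c(200, 400),
                  utr5_len = 0, utr3_len = 0)
  ann <- annotation(g, chrom_lengths = c(c = 1000))
  frags <- data.frame(chrom = "c", strand = c("+", "-", "+", "+"),
                      start = c(110, 300, 300, 170), end = c(130, 320, 320, 180))
  # centers: 120 (in A only, sense), 310 (B only, antisense to B... strand
  # '-' equals B's: sense), 310 ('+': antisense to B), 175 (in both: dropped)
  qc <- antisense_read_fraction(frags, ann)
  expect_equal(qc$n_informative, 3)
  expect_equal(qc$antisense_read_fraction, 1 / 3)
  expect_error(antisense_read_fraction(frags, annotation(g[0, ],
               chrom_lengths = c(c = 1000))), "empty annotation")
  far <- data.frame(chrom = "c", strand = "+", start = 900, end = 950)
  expect_error(antisense_read_fraction(far, ann), "exactly one")
})
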