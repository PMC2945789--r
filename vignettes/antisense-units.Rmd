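---
title: "Calling and characterising antisense transcription units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterising antisense transcription units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asunit)
```

## Scientific problem

Strand-specific RNA-seq of mid-log budding yeast reveals transcription
on the strand opposite many protein-coding genes. Three questions drive
the analysis implemented here:

1. **Which intervals are transcribed, per strand?** Paired-end fragments
   are reduced to their center positions; intervals where center
   coverage is sustained define *transcribed units* on each strand.
2. **Which units are antisense to a gene, and how far do they reach?**
   A unit on the strand opposite a gene that covers at least 25% of the
   gene's UTR-extended transcript is an *antisense unit*, tiered by how
   much of the ORF it covers (`UTR_ONLY`, `GE25`, `GE50`, `GE75`,
   `FULL`).
3. **Where could each antisense unit originate, and what does it do?**
   Each unit is assigned the most parsimonious transcriptional origin
   (UTR extension of a neighbour, divergent promoter, 3'-adjacent
   nucleosome-free region, or unexplained), and sense–antisense pairs
   are followed across conditions with nCounter-style counts and
   strand-specific qPCR.

All genomic coordinates in the package are **0-based, half-open**
`[start, end)`. On the `-` strand the 5' end of an interval is its
`end` coordinate and the 3' end its `start`.

## Segmentation model

For a fragment `[s, e)` the center is `floor((s + e) / 2)` (lower
median, so even-length fragments are deterministic). Per chromosome and
strand, a position is *signal* when its center count is at least
`min_cov = 2` — the study's "coverage greater than one" read literally —
and maximal runs of signal positions whose internal gaps are each at
most `max_gap = 20` bp form one unit. Boundaries are defined by signal
positions only; there is no extension by fragment length, so a called
unit starts roughly half a fragment length inside the true transcript
on each side (~`frag_len_mean/2 + max_gap` ≈ 145 bp at the defaults).

```{r segmentation-example}
frags <- data.frame(chrom = "chrI", strand = "+",
                    start = c(100, 104, 108, 400, 404),
                    end   = c(300, 304, 308, 600, 604))
cov <- compute_center_coverage(frags)
call_units(cov, min_cov = 2, max_gap = 20)
```

## Antisense calls, tiers, and curation

`call_antisense()` computes, in exact integer arithmetic, the fraction
of each gene's UTR-extended transcript and of its ORF covered by every
opposite-strand unit. The 25% transcript threshold and the tier cut
points (25/50/75/100% of the ORF) are all **inclusive**.

Real catalogs fragment sparse transcripts into pieces. The study
resolved this manually; `curate_units()` replaces that step with a
deterministic rule: same-strand units antisense to the same gene are
merged when their gap is at most 200 bp, and units supported by fewer
than `min_centers = 5` fragment centers are dropped. The support filter
matters because a ~0.6% strand-flip leak over deeply covered genes
produces genuine-looking two-center "units" on the opposite strand;
without it they chain through the 200-bp merge into spurious calls.

## Origin taxonomy

`classify_origin()` tests, in strict precedence order within a 400-bp
margin, whether a unit could be (1) a 3' UTR extension of a same-strand
gene upstream, (2) a 5' UTR extension of a same-strand gene downstream,
(3) the product of a divergent promoter — an opposite-strand gene whose
5' end is near the unit's 5' end and reads *away* from it, or (4)
initiation in the nucleosome-free region downstream of *any* annotated
3' end near the unit's 5' end. Everything else is `UNEXPLAINED`.
Directional distances treat a gene boundary lying inside the unit
(within the margin) as distance 0, so a slightly overhanging unit still
matches, but a unit embedded deep in an opposite-strand gene body does
not spuriously read as "divergent". Separately, `flag_runthrough()`
marks units whose 3' end stops within 200 bp of a convergent gene's 3'
end, where termination read-through is an alternative explanation.

```{r origin-example}
ann <- annotation(data.frame(gene_id = "G", chrom = "c", strand = "+",
                             orf_start = 2000, orf_end = 3050,
                             utr5_len = 0, utr3_len = 0),
                  chrom_lengths = c(c = 20000))
classify_origin(list(chrom = "c", strand = "+", start = 3100, end = 3600),
                ann)
```

## Expression arm

nCounter-style counts are normalized in two steps: per-sample factors
first equalize the positive spike-in sums, then the geometric means of
the control genes. The procedure is idempotent and leaves the reference
sample untouched. Log2 condition ratios average replicates after
normalization; regulation is called at an inclusive two-fold threshold;
discordant sense–antisense pairs (one up, the other down) are counted
per condition and across conditions. Strand-specific qPCR quantities
are normalized per (primer set, replicate) stratum by the control gene
(PDA1) measured in the same stratum, and the log2 condition ratio is
averaged across strata.

Group comparisons use a Wilcoxon rank-sum test with midranks for ties:
exact enumeration of all `choose(n, n1)` assignments up to a combined
n of 12, and a tie-corrected normal approximation with continuity
correction beyond. For continuous data at `n = 6 + 6` the two paths
agree to within 0.02; with heavily tied small samples the normal
approximation can drift further, which is inherent to the
approximation, not a defect of the implementation.

## Cross-species projection

`project_antisense()` transfers a unit into an ortholog's coordinate
system through offsets *relative to the ORF's 5' end*, scaled by the
length ratio and rounded toward the interval interior; strand-flipped
orthologs mirror the coordinates. The round trip
project → inverse-project is exact for equal-length ORFs and within 1 bp
when ortholog lengths differ by up to ~10%, the regime relevant for
closely related yeasts.

## The synthetic-data generator

`sim_config()` defaults *are* the study conditions: 200 genes on a
1-Mbp chromosome, 50 antisense units spread over all five tiers and
five origin classes, mean center depth 20, leak rate 0.006, fragment
lengths ~N(250, 30) truncated at 100.

Design decisions worth knowing when interpreting results:

* **Depth semantics.** `depth` is mean per-base *center coverage*; a
  transcript of length L receives `round(depth * (L - frag_len_mean))`
  fragments, because centers can only fall in the inner
  `L - frag_len_mean` bases on average. This is what makes the
  boundary-inset arithmetic above come out right.
* **Planted geometry.** Origin classes are planted unambiguously: each
  target gene block contains the helper gene (or deliberate absence of
  one) that makes exactly one taxonomy rule fire, blocks are mirrored
  onto the `-` strand with probability 0.5, and isolation gaps of
  700–1100 bp prevent cross-talk between blocks.
* **Infeasible combinations.** A planted `UNEXPLAINED` unit must sit
  deep inside the ORF, which caps its coverage tier; the generator
  reassigns infeasible tier/origin draws to `GE50`.
* **Expression tables.** Counts are
  `baseline * 2^fc * sample_scale * noise` with log-normal noise;
  spike-ins share the sample scale (so step 1 of the normalization
  removes it) and control genes are constant (so step 2 calibrates
  residual drift). At `noise_sd = 0` the planted fold changes are
  recovered exactly.

## Limitations

* The generator plants one antisense unit per target gene and no
  overlapping gene models, so it does not exercise nested or
  bidirectionally overlapping gene architectures.
* The deterministic curation rule stands in for manual annotation; on
  deeply covered simulations a tail of leak-derived calls survives the
  `min_centers` filter, which mirrors — but does not resolve — the
  real-data question of how much apparent antisense signal is leak.
* The Wilcoxon normal approximation is only guaranteed close to the
  exact test for continuous data.
* Projection assumes a single colinear ortholog per gene; rearranged or
  duplicated loci must be filtered out upstream via the synteny flag.

## Reproducing the study-scale analysis

The repository's `analysis/` scripts run the whole workflow
(`01_simulate.R` → `06_conservation.R`), writing tables under
`results/`; `scripts/acceptance.R --seed <int> --out <path>` runs the
main computation end to end and writes the headline numbers as JSON.
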