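# Synthetic-data generator: annotations with planted antisense units
# (tiered, with geometrically unambiguous origin classes), strand-specific
# fragment sets with a configurable strand-flip leak, and expression
# tables with planted sense-antisense anticorrelation.

# deterministic sub-seed per purpose, kept below 2^31
.subseed <- function(seed, k) {
  (as.numeric(seed) * 7919 + k * 104729) %% 2147483647
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator with defaults
#' that emulate a mid-log yeast strand-specific RNA-seq study at desk
#' scale.
#'
#' @param n_genes total number of genes placed (antisense-target and
#'   helper genes included).
#' @param chrom_length chromosome length in bp.
#' @param chrom chromosome name.
#' @param n_antisense number of planted antisense units.
#' @param tier_mix named proportions (summing to 1) over tiers
#'   `UTR_ONLY`, `GE25`, `GE50`, `GE75`, `FULL`.
#' @param origin_mix named proportions over origin classes
#'   `SENSE_3UTR_EXTENSION`, `SENSE_5UTR_EXTENSION`,
#'   `DIVERGENT_PROMOTER`, `ADJACENT_3NFR`, `UNEXPLAINED` (defaults
#'   follow the relative abundance seen in curated yeast antisense
#'   catalogs).
#' @param margin origin-classification margin emulated by the planted
#'   geometry (bp).
#' @param utr_mean,utr_sd UTR length distribution (bp; clamped to
#'   [30, 250]).
#' @param depth mean per-base fragment-center coverage within each
#'   expressed transcript (sense genes); the fragment count of a
#'   transcript is `round(depth * (length - frag_len_mean))`.
#' @param antisense_depth coverage for planted antisense units
#'   (default: same as `depth`).
#' @param leak_rate probability that a fragment is assigned to the
#'   wrong strand (the dUTP-protocol leak; default 0.006, the order of
#'   the 0.6 percent observed for such libraries).
#' @param frag_len_mean,frag_len_sd,frag_len_min fragment length
#'   distribution (normal, truncated at `[frag_len_min, transcript
#'   length]`; defaults 250/30/100, echoing a 180-480 bp size-selected
#'   library).
#' @param n_pairs,conditions,ref_condition,n_replicates expression
#'   design: number of sense-antisense probe pairs, condition labels,
#'   reference condition, biological replicates per condition.
#' @param fc_sd marginal standard deviation of planted log2 fold
#'   changes (default 2; stress-response genes commonly change more
#'   than four-fold).
#' @param sa_correlation planted correlation between sense and
#'   antisense log2 fold changes (default -0.8).
#' @param noise_sd multiplicative measurement noise, sd in log2 units.
#' @param sample_scale_sd sample-to-sample scale variation, sd in log2
#'   units (removed by normalization).
#' @param n_spikes,n_controls number of positive spike-in and
#'   control-gene probes.
#' @return list of class `asu_sim_config`.
#' @export
sim_config <- function(n_genes = 200, chrom_length = 1e6, chrom = "chrSim",
                       n_antisense = 50,
                       tier_mix = c(UTR_ONLY = 0.10, GE25 = 0.20,
                                    GE50 = 0.25, GE75 = 0.25, FULL = 0.20),
                       origin_mix = c(SENSE_3UTR_EXTENSION = 0.12,
                                      SENSE_5UTR_EXTENSION = 0.07,
                                      DIVERGENT_PROMOTER = 0.37,
                                      ADJACENT_3NFR = 0.10,
                                      UNEXPLAINED = 0.34),
                       margin = 400, utr_mean = 100, utr_sd = 30,
                       depth = 20, antisense_depth = NULL,
                       leak_rate = 0.006, frag_len_mean = 250,
                       frag_len_sd = 30, frag_len_min = 100,
                       n_pairs = 67,
                       conditions = c("midlog", "early_stationary",
                                      "heat_shock"),
                       ref_condition = "midlog", n_replicates = 2,
                       fc_sd = 2, sa_correlation = -0.8, noise_sd = 0.3,
                       sample_scale_sd = 0.25, n_spikes = 6,
                       n_controls = 3) {
  stopifnot(abs(sum(tier_mix) - 1) < 1e-9, abs(sum(origin_mix) - 1) < 1e-9,
            leak_rate >= 0, leak_rate <= 1, depth >= 0,
            n_antisense >= 0, n_genes >= 0,
            abs(sa_correlation) <= 1, ref_condition %in% conditions)
  if (is.null(antisense_depth)) antisense_depth <- depth
  structure(as.list(environment()), class = "asu_sim_config")
}

# exact integer allocation of n items to classes with given proportions
.allocate <- function(n, mix) {
  counts <- diff(c(0, round(cumsum(mix) * n)))
  rep(names(mix), times = counts)
}

# clamp-and-round helper
.clampi <- function(x, lo, hi) pmin(hi, pmax(lo, round(x)))

#' Simulate an annotation with planted antisense units
#'
#' Genes are placed left to right along one chromosome in isolated
#' blocks separated by gaps larger than the classification margin, so
#' each planted configuration is geometrically unambiguous. Antisense
#' target genes carry one planted unit each, built to satisfy its
#' assigned ORF-coverage tier with enough overhang that boundary
#' shrinkage by half a fragment length at segmentation cannot change
#' the tier, and its assigned origin class via a helper gene at a
#' distance inside the margin (UTR-extension and divergent-promoter
#' classes) or via the target's own 3' end (adjacent-NFR class).
#' Blocks are mirrored with probability 1/2 so both strands occur.
#' Tier/origin combinations that are geometrically impossible
#' (`UNEXPLAINED` with `FULL`, `UTR_ONLY` or `GE75`) fall back to
#' `GE50`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the output is a pure function of
#'   (config, seed).
#' @return list with `annotation` (an [annotation()]) and `truth`
#'   (list with `units`: data.frame of planted units carrying
#'   `unit_id`, `chrom`, `strand`, `start`, `end`, `gene_id`, `tier`,
#'   `origin_class`, `runthrough`, `helper_gene`).
#' @export
simulate_annotation <- function(config, seed) {
  stopifnot(inherits(config, "asu_sim_config"))
  cfg <- config
  empty_truth <- data.frame(unit_id = character(0), chrom = character(0),
                            strand = character(0), start = numeric(0),
                            end = numeric(0), gene_id = character(0),
                            tier = character(0), origin_class = character(0),
                            runthrough = logical(0),
                            helper_gene = character(0),
                            stringsAsFactors = FALSE)
  if (cfg$n_genes == 0L) {
    ann <- annotation(data.frame(gene_id = character(0), chrom = character(0),
                                 strand = character(0), orf_start = numeric(0),
                                 orf_end = numeric(0), utr5_len = numeric(0),
                                 utr3_len = numeric(0)),
                      chrom_lengths = setNames(cfg$chrom_length, cfg$chrom))
    return(list(annotation = ann, truth = list(units = empty_truth)))
  }

  n_as <- cfg$n_antisense
  # stream C: class assignment and block orientation
  set.seed(.subseed(seed, 3))
  tiers <- sample(.allocate(n_as, cfg$tier_mix))
  origins <- sample(.allocate(n_as, cfg$origin_mix))
  # infeasible combinations: an unexplained unit must end deep inside
  # the ORF, which rules out full/UTR-only coverage
  fix <- origins == "UNEXPLAINED" & tiers %in% c("FULL", "UTR_ONLY", "GE75")
  tiers[fix] <- "GE50"
  n_help <- sum(origins %in% c("SENSE_3UTR_EXTENSION", "SENSE_5UTR_EXTENSION",
                               "DIVERGENT_PROMOTER"))
  n_plain <- cfg$n_genes - n_as - n_help
  if (n_plain < 0)
    stop("simulate_annotation: n_genes too small for n_antisense plus ",
         n_help, " helper gene(s)")
  n_blocks <- n_plain + n_as
  flip <- runif(n_blocks) < 0.5
  # interleave target blocks among plain blocks deterministically
  is_target <- rep(FALSE, n_blocks)
  if (n_as > 0)
    is_target[round(seq(1, n_blocks, length.out = n_as))] <- TRUE

  # stream A: lengths
  set.seed(.subseed(seed, 1))
  plain_len <- .clampi(exp(rnorm(n_blocks, log(1250), 0.28)), 500, 2600)
  target_len <- .clampi(runif(n_as, 1800, 2800), 1800, 2800)
  target_len[origins == "UNEXPLAINED"] <-
    .clampi(runif(sum(origins == "UNEXPLAINED"), 2400, 3200), 2400, 3200)
  utr5 <- .clampi(rnorm(n_blocks, cfg$utr_mean, cfg$utr_sd), 30, 250)
  utr3 <- .clampi(rnorm(n_blocks, cfg$utr_mean, cfg$utr_sd), 30, 250)
  helper_len <- .clampi(runif(n_as, 900, 1400), 900, 1400)

  # stream B: gaps and helper distances
  set.seed(.subseed(seed, 2))
  gaps <- .clampi(runif(n_blocks, 700, 1100), 700, 1100)
  d_help <- .clampi(runif(n_as, 60, cfg$margin - 60), 60, cfg$margin - 60)
  d_help5 <- .clampi(runif(n_as, 210, cfg$margin - 60), 210, cfg$margin - 60)

  pad <- 300  # unit overhang past the ORF/transcript where the tier allows
  genes <- list()
  units <- list()
  cursor <- 0
  gi <- 0L       # gene counter
  ti <- 0L       # target counter
  for (b in seq_len(n_blocks)) {
    if (!is_target[b]) {
      L <- plain_len[b]
      u5 <- utr5[b]; u3 <- utr3[b]
      block <- list(genes = data.frame(
        strand = "+", orf_start = u5, orf_end = u5 + L,
        utr5_len = u5, utr3_len = u3, role = "plain",
        stringsAsFactors = FALSE), units = NULL)
    } else {
      ti <- ti + 1L
      block <- .build_target_block(L = target_len[ti], utr5 = utr5[b],
                                   utr3 = utr3[b], tier = tiers[ti],
                                   origin = origins[ti], pad = pad,
                                   helper_len = helper_len[ti],
                                   d = d_help[ti], d5 = d_help5[ti])
    }
    # shift block so its leftmost coordinate is 0, then mirror if flipped
    allv <- c(block$genes$orf_start - block$genes$utr5_len,
              block$genes$orf_start - block$genes$utr3_len,
              if (!is.null(block$units)) block$units$start)
    allv2 <- c(block$genes$orf_end + block$genes$utr3_len,
               block$genes$orf_end + block$genes$utr5_len,
               if (!is.null(block$units)) block$units$end)
    shift <- -min(allv)
    span <- max(allv2) + shift
    mirror <- function(df, scol, ecol) {
      s <- df[[scol]] + shift; e <- df[[ecol]] + shift
      if (flip[b]) {
        ns <- span - e; ne <- span - s
        df[[scol]] <- ns; df[[ecol]] <- ne
        df$strand <- ifelse(df$strand == "+", "-", "+")
      } else {
        df[[scol]] <- s; df[[ecol]] <- e
      }
      df
    }
    # UTR lengths are defined relative to the strand, so mirroring the
    # block (which also flips strands) needs no utr5/utr3 swap
    bg <- mirror(block$genes, "orf_start", "orf_end")
    bg$orf_start <- bg$orf_start + cursor
    bg$orf_end <- bg$orf_end + cursor
    ids <- character(nrow(bg))
    for (k in seq_len(nrow(bg))) {
      gi <- gi + 1L
      ids[k] <- sprintf("G%04d", gi)
    }
    bg$gene_id <- ids
    genes[[length(genes) + 1L]] <- bg
    if (!is.null(block$units)) {
      bu <- mirror(block$units, "start", "end")
      bu$start <- bu$start + cursor
      bu$end <- bu$end + cursor
      bu$gene_id <- ids[block$units$gene_index]
      bu$helper_gene <- if (is.na(block$units$helper_index)) NA_character_
                        else ids[block$units$helper_index]
      bu$tier <- tiers[ti]; bu$origin_class <- origins[ti]
      units[[length(units) + 1L]] <- bu
    }
    cursor <- cursor + span + gaps[b]
    if (cursor > cfg$chrom_length)
      stop("simulate_annotation: chromosome too short for n_genes")
  }
  genes <- do.call(rbind, genes)
  genes <- data.frame(gene_id = genes$gene_id, chrom = cfg$chrom,
                      strand = genes$strand, orf_start = genes$orf_start,
                      orf_end = genes$orf_end, utr5_len = genes$utr5_len,
                      utr3_len = genes$utr3_len, stringsAsFactors = FALSE)
  ann <- annotation(genes,
                    chrom_lengths = setNames(cfg$chrom_length, cfg$chrom))
  if (length(units) > 0L) {
    units <- do.call(rbind, units)
    truth <- data.frame(unit_id = sprintf("AS%03d", seq_len(nrow(units))),
                        chrom = cfg$chrom, strand = units$strand,
                        start = units$start, end = units$end,
                        gene_id = units$gene_id, tier = units$tier,
                        origin_class = units$origin_class,
                        stringsAsFactors = FALSE)
    truth$runthrough <- vapply(seq_len(nrow(truth)), function(i) {
      flag_runthrough(truth[i, ], ann)$flagged
    }, logical(1))
    truth$helper_gene <- units$helper_gene
  } else {
    truth <- empty_truth
  }
  list(annotation = ann, truth = list(units = truth))
}

# One antisense configuration in local coordinates, target gene on '+'.
# Unit is on '-': its 5' end is the right (end) coordinate, its 3' end
# the left (start) coordinate.
.build_target_block <- function(L, utr5, utr3, tier, origin, pad,
                                helper_len, d, d5) {
  if (tier == "UTR_ONLY")  # 3' UTR must hold >= 25% of the transcript
    utr3 <- ceiling((L + utr5) / 3) + 250
  gs <- utr5; ge <- gs + L; t_end <- ge + utr3
  unit <- switch(tier,
    FULL = c(gs - pad, ge + pad),
    GE75 = c(ge - round(0.88 * L), ge + pad),
    GE50 = c(ge - round(0.62 * L), ge + pad),
    GE25 = c(ge - round(0.35 * L), ge + pad),
    UTR_ONLY = c(ge + 10, t_end + pad))
  if (origin == "UNEXPLAINED") {
    frac <- if (tier == "GE50") 0.65 else 0.42
    u_end <- ge - 460
    unit <- c(u_end - round(frac * L), u_end)
  }
  u3 <- unit[1]; u5 <- unit[2]  # '-' strand unit
  helper <- NULL
  if (origin == "SENSE_3UTR_EXTENSION") {
    # same-strand ('-') gene whose 3' end (transcript start) sits d bp
    # upstream (to the right) of the unit's 5' end
    ts <- u5 + d; te <- ts + helper_len
    helper <- data.frame(strand = "-", orf_start = ts + 100,
                         orf_end = te - 100, utr5_len = 100, utr3_len = 100,
                         role = "helper", stringsAsFactors = FALSE)
  } else if (origin == "SENSE_5UTR_EXTENSION") {
    # same-strand ('-') gene whose 5' end (transcript end) sits d5 bp
    # downstream (to the left) of the unit's 3' end
    te <- u3 - d5; ts <- te - helper_len
    helper <- data.frame(strand = "-", orf_start = ts + 100,
                         orf_end = te - 100, utr5_len = 100, utr3_len = 100,
                         role = "helper", stringsAsFactors = FALSE)
  } else if (origin == "DIVERGENT_PROMOTER") {
    # opposite-strand ('+') gene starting d bp beyond the unit's 5' end,
    # transcribed away (5'-to-5' configuration)
    ts <- u5 + d; te <- ts + helper_len
    helper <- data.frame(strand = "+", orf_start = ts + 100,
                         orf_end = te - 100, utr5_len = 100, utr3_len = 100,
                         role = "helper", stringsAsFactors = FALSE)
  }
  target <- data.frame(strand = "+", orf_start = gs, orf_end = ge,
                       utr5_len = utr5, utr3_len = utr3, role = "target",
                       stringsAsFactors = FALSE)
  genes <- rbind(target, helper)
  list(genes = genes,
       units = data.frame(strand = "-", start = unit[1], end = unit[2],
                          gene_index = 1L,
                          helper_index = if (is.null(helper)) NA_integer_ else 2L,
                          stringsAsFactors = FALSE))
}

#' Simulate strand-specific paired-end fragments
#'
#' Every expressed transcript — the UTR-extended span of each gene and
#' every planted antisense unit — receives
#' `round(depth * (length - frag_len_mean))` fragments with normal
#' lengths truncated to `[frag_len_min, transcript length]` (redrawn up
#' to 100 times), placed uniformly within the transcript. Each
#' fragment's strand is flipped independently with probability
#' `leak_rate`.
#'
#' @param ann an [annotation()] (typically from
#'   [simulate_annotation()]).
#' @param truth the matching truth list (planted units); may be `NULL`
#'   to simulate sense transcription only.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return data.frame of fragments with columns `chrom`, `strand`,
#'   `start`, `end`, `source` (transcript of origin).
#' @export
simulate_fragments <- function(ann, truth, config, seed) {
  stopifnot(inherits(config, "asu_sim_config"))
  sp <- transcript_spans(ann)
  tx <- data.frame(id = sp$gene_id, chrom = sp$chrom, strand = sp$strand,
                   start = sp$start, end = sp$end,
                   depth = config$depth, stringsAsFactors = FALSE)
  if (!is.null(truth) && nrow(truth$units) > 0L) {
    u <- truth$units
    tx <- rbind(tx, data.frame(id = u$unit_id, chrom = u$chrom,
                               strand = u$strand, start = u$start,
                               end = u$end, depth = config$antisense_depth,
                               stringsAsFactors = FALSE))
  }
  span_len <- tx$end - tx$start
  n <- pmax(0, round(tx$depth * pmax(1, span_len - config$frag_len_mean)))
  if (sum(n) == 0L)
    return(data.frame(chrom = character(0), strand = character(0),
                      start = numeric(0), end = numeric(0),
                      source = character(0), stringsAsFactors = FALSE))
  idx <- rep(seq_len(nrow(tx)), times = n)
  max_len <- span_len[idx]

  set.seed(.subseed(seed, 11))  # lengths
  len <- round(rnorm(length(idx), config$frag_len_mean, config$frag_len_sd))
  bad <- which(len < config$frag_len_min | len > max_len)
  tries <- 0L
  while (length(bad) > 0L) {
    tries <- tries + 1L
    if (tries > 100L)
      stop("simulate_fragments: fragment length exceeds transcript length ",
           "after 100 attempts")
    len[bad] <- round(rnorm(length(bad), config$frag_len_mean,
                            config$frag_len_sd))
    bad <- bad[len[bad] < config$frag_len_min | len[bad] > max_len[bad]]
  }

  set.seed(.subseed(seed, 12))  # placement
  start <- tx$start[idx] + floor(runif(length(idx)) * (max_len - len + 1))

  set.seed(.subseed(seed, 13))  # strand flips
  flip <- runif(length(idx)) < config$leak_rate
  strand <- ifelse(xor(tx$strand[idx] == "-", flip), "-", "+")
  data.frame(chrom = tx$chrom[idx], strand = strand, start = start,
             end = start + len, source = tx$id[idx],
             stringsAsFactors = FALSE)
}

#' Simulate planted sense/antisense log2 fold changes
#'
#' For every probe pair and non-reference condition, sense and
#' antisense log2 fold changes are drawn from a bivariate normal with
#' marginal sd `fc_sd` and correlation `sa_correlation` — the planted
#' anticorrelation.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return data.frame with columns `pair_id`, `condition`, `fc_sense`,
#'   `fc_antisense`.
#' @export
simulate_fold_changes <- function(config, seed) {
  stopifnot(inherits(config, "asu_sim_config"))
  conds <- setdiff(config$conditions, config$ref_condition)
  n <- config$n_pairs * length(conds)
  set.seed(.subseed(seed, 21))
  z1 <- rnorm(n)
  z2 <- config$sa_correlation * z1 +
    sqrt(1 - config$sa_correlation^2) * rnorm(n)
  data.frame(pair_id = rep(sprintf("T%03d", seq_len(config$n_pairs)),
                           times = length(conds)),
             condition = rep(conds, each = config$n_pairs),
             fc_sense = config$fc_sd * z1,
             fc_antisense = config$fc_sd * z2,
             stringsAsFactors = FALSE)
}

#' Simulate nCounter-style and qPCR expression measurements
#'
#' nCounter-style counts are `baseline * 2^fc * sample_scale *
#' 2^N(0, noise_sd)` for target probes, with positive spike-in probes
#' at fixed ladder levels and control-gene probes at constant true
#' levels (both times the sample scale and noise). qPCR quantities are
#' analogous, with a constant per-(pair, orientation, primer) offset
#' and a per-(replicate, condition) scale that cancel in the log-ratio
#' contract, plus control-gene rows (`PDA1`).
#'
#' @param fc planted fold changes from [simulate_fold_changes()] (or a
#'   truth list containing `$fc`).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `table` (an [expression_table()]), `qpcr`
#'   (data.frame of measurements) and `fc` (the planted fold changes).
#' @export
simulate_expression_tables <- function(fc, config, seed) {
  stopifnot(inherits(config, "asu_sim_config"))
  if (is.list(fc) && !is.data.frame(fc) && !is.null(fc$fc)) fc <- fc$fc
  pairs <- sprintf("T%03d", seq_len(config$n_pairs))
  conds <- config$conditions
  fc_of <- function(pair, orient, cond) {
    if (cond == config$ref_condition) return(0)
    row <- fc$pair_id == pair & fc$condition == cond
    if (!any(row)) return(0)
    if (orient == "sense") fc$fc_sense[row][1] else fc$fc_antisense[row][1]
  }
  set.seed(.subseed(seed, 22))  # baselines and scales
  base_s <- exp(rnorm(config$n_pairs, log(600), 0.6))
  base_a <- exp(rnorm(config$n_pairs, log(150), 0.6))
  ctrl_base <- exp(rnorm(config$n_controls, log(800), 0.3))
  spike_lvl <- c(50, 100, 200, 400, 800, 1600, 3200,
                 6400)[seq_len(config$n_spikes)]
  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         condition = conds, stringsAsFactors = FALSE)
  samples$sample <- paste0(samples$condition, "_r", samples$replicate)
  scale <- 2^rnorm(nrow(samples), 0, config$sample_scale_sd)

  probes <- c(paste0(pairs, "_S"), paste0(pairs, "_A"),
              paste0("POS_", LETTERS[seq_len(config$n_spikes)]),
              sprintf("CTRL_%d", seq_len(config$n_controls)))
  probe_class <- c(rep("target_sense", config$n_pairs),
                   rep("target_antisense", config$n_pairs),
                   rep("positive_spike", config$n_spikes),
                   rep("control_gene", config$n_controls))
  names(probe_class) <- probes
  expected <- matrix(0, nrow = length(probes), ncol = nrow(samples),
                     dimnames = list(probes, samples$sample))
  for (j in seq_len(nrow(samples))) {
    cond <- samples$condition[j]
    fs <- vapply(pairs, fc_of, numeric(1), orient = "sense", cond = cond)
    fa <- vapply(pairs, fc_of, numeric(1), orient = "antisense", cond = cond)
    expected[, j] <- c(base_s * 2^fs, base_a * 2^fa, spike_lvl, ctrl_base) *
      scale[j]
  }
  set.seed(.subseed(seed, 23))  # measurement noise
  noise <- 2^matrix(rnorm(length(expected), 0, config$noise_sd),
                    nrow = nrow(expected))
  tab <- expression_table(expected * noise, probe_class, samples)

  # qPCR arm: both orientations, two primer sets, with PDA1 control rows
  set.seed(.subseed(seed, 24))
  qgrid <- expand.grid(pair = pairs, orientation = c("sense", "antisense"),
                       primer_set = c("p1", "p2"),
                       replicate = seq_len(config$n_replicates),
                       condition = conds, stringsAsFactors = FALSE)
  primer_key <- paste(qgrid$pair, qgrid$orientation, qgrid$primer_set)
  primer_off <- 2^rnorm(length(unique(primer_key)), 0, 0.2)
  names(primer_off) <- unique(primer_key)
  rep_key <- paste(qgrid$replicate, qgrid$condition)
  rep_scale <- 2^rnorm(length(unique(rep_key)), 0, 0.2)
  names(rep_scale) <- unique(rep_key)
  qbase <- setNames(c(exp(rnorm(config$n_pairs, log(10), 0.5)),
                      exp(rnorm(config$n_pairs, log(2), 0.5))),
                    c(paste(pairs, "sense"), paste(pairs, "antisense")))
  fcv <- mapply(fc_of, qgrid$pair, qgrid$orientation, qgrid$condition)
  qnoise <- 2^rnorm(nrow(qgrid), 0, config$noise_sd)
  q <- data.frame(target_id = qgrid$pair, orientation = qgrid$orientation,
                  primer_set = qgrid$primer_set, replicate = qgrid$replicate,
                  condition = qgrid$condition,
                  quantity = qbase[paste(qgrid$pair, qgrid$orientation)] *
                    2^fcv * primer_off[primer_key] * rep_scale[rep_key] *
                    qnoise,
                  stringsAsFactors = FALSE)
  cgrid <- expand.grid(replicate = seq_len(config$n_replicates),
                       condition = conds, stringsAsFactors = FALSE)
  cnoise <- 2^rnorm(nrow(cgrid), 0, config$noise_sd)
  ctrl <- data.frame(target_id = "PDA1", orientation = "sense",
                     primer_set = "ctrl", replicate = cgrid$replicate,
                     condition = cgrid$condition,
                     quantity = 5 * rep_scale[paste(cgrid$replicate,
                                                    cgrid$condition)] *
                       cnoise,
                     stringsAsFactors = FALSE)
  q <- rbind(q, ctrl)
  rownames(q) <- NULL
  list(table = tab, qpcr = q, fc = fc)
}

#' Write a simulated data set to disk
#'
#' Writes the annotation (GFF3 + UTR table), fragments (BED6), planted
#' truth (JSON), the expression table (TSV with a probe-class column)
#' and the qPCR measurements (TSV).
#'
#' @param sim list with elements among `annotation`, `truth`,
#'   `fragments`, `expression` (as returned by the `simulate_*`
#'   functions).
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sim$annotation)) {
    write_annotation_gff3(sim$annotation, file.path(dir, "annotation.gff3"))
    write_utr_table(sim$annotation, file.path(dir, "utr_lengths.tsv"))
  }
  if (!is.null(sim$fragments)) {
    f <- sim$fragments
    write_bed6(data.frame(chrom = f$chrom, start = f$start, end = f$end,
                          name = f$source, score = 0, strand = f$strand),
               file.path(dir, "fragments.bed"))
  }
  if (!is.null(sim$truth))
    jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(sim$expression)) {
    tab <- sim$expression$table
    out <- data.frame(probe = rownames(tab$counts),
                      probe_class = unname(tab$probe_class),
                      tab$counts, check.names = FALSE)
    write.table(out, file.path(dir, "ncounter_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sim$expression$qpcr, file.path(dir, "qpcr.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
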