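# Cross-species projection of antisense loci through ortholog maps using
# ORF-relative coordinates, and the presence/regulation summary matrix.

#' Project an antisense unit onto an ortholog
#'
#' The unit's endpoints are expressed as fractional offsets along the
#' sense ORF measured from its 5' end (offsets may fall outside [0, 1]
#' for UTR overhangs) and the same fractions are applied to the
#' ortholog ORF from its 5' end, strand-aware. The projected region is
#' placed on the strand opposite the ortholog. Fractional endpoints are
#' rounded to the nearest base with ties toward the interval interior.
#' UTR overhangs project linearly beyond the ortholog ORF by default;
#' `restrict_to_orf = TRUE` clips them to the ORF instead.
#'
#' @param unit list or one-row data.frame with `start`, `end` (and
#'   optionally `unit_id`); must be antisense to `sense_gene`.
#' @param sense_gene,ortholog gene models (lists or one-row data.frames
#'   with `chrom`, `strand`, `orf_start`, `orf_end`).
#' @param chrom_length length of the ortholog chromosome for clipping
#'   (default `Inf`).
#' @param restrict_to_orf clip the projection to the ortholog ORF.
#' @return list with `chrom`, `strand`, `start`, `end`,
#'   `source_unit_id`, `clipped`; or `NULL` when the projection is
#'   empty after clipping.
#' @export
project_antisense <- function(unit, sense_gene, ortholog,
                              chrom_length = Inf, restrict_to_orf = FALSE) {
  unit <- as.list(unit)
  sg <- as.list(sense_gene)
  og <- as.list(ortholog)
  L <- sg$orf_end - sg$orf_start
  Lo <- og$orf_end - og$orf_start
  if (L <= 0 || Lo <= 0) stop("project_antisense: zero-length ORF")
  # fractional offsets along the sense ORF from its 5' end
  if (sg$strand == "+") {
    f1 <- (unit$start - sg$orf_start) / L
    f2 <- (unit$end - sg$orf_start) / L
  } else {
    f1 <- (sg$orf_end - unit$end) / L
    f2 <- (sg$orf_end - unit$start) / L
  }
  if (og$strand == "+") {
    raw_start <- og$orf_start + f1 * Lo
    raw_end <- og$orf_start + f2 * Lo
  } else {
    raw_start <- og$orf_end - f2 * Lo
    raw_end <- og$orf_end - f1 * Lo
  }
  start <- floor(raw_start + 0.5)   # ties round up, toward the interior
  end <- ceiling(raw_end - 0.5)     # ties round down, toward the interior
  lo <- if (restrict_to_orf) og$orf_start else 0
  hi <- if (restrict_to_orf) og$orf_end else chrom_length
  cstart <- max(lo, start)
  cend <- min(hi, end)
  if (cstart >= cend) return(NULL)
  list(chrom = og$chrom, strand = if (og$strand == "+") "-" else "+",
       start = cstart, end = cend,
       source_unit_id = if (!is.null(unit$unit_id)) unit$unit_id else NA_character_,
       clipped = cstart != start || cend != end)
}

#' Read an ortholog/synteny table
#'
#' Tab-separated columns (source_gene_id, species, ortholog_gene_id,
#' synteny_ok); `#` comments allowed. An ortholog of `none` (or empty)
#' means no projection is allowed for that species.
#'
#' @param path TSV file.
#' @return data.frame with columns `source_gene_id`, `species`,
#'   `ortholog_gene_id` (`NA` when none) and `synteny_ok` (logical).
#' @export
read_ortholog_table <- function(path) {
  tab <- read.table(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 4L)
    stop("read_ortholog_table: expected 4 tab-separated columns in ", path)
  names(tab)[1:4] <- c("source_gene_id", "species", "ortholog_gene_id",
                       "synteny_ok")
  tab$ortholog_gene_id[tab$ortholog_gene_id %in% c("none", "NA", "")] <- NA
  tab$synteny_ok <- as.logical(tab$synteny_ok)
  tab[, 1:4]
}

#' Project an antisense catalog across species
#'
#' Applies [project_antisense()] to every (unit, species) combination
#' allowed by the ortholog table. Records without a clear ortholog or
#' with broken synteny yield no candidate region.
#'
#' @param calls data.frame linking units to sense genes (columns with a
#'   unit id in the first column, plus `gene_id`, `start`, `end`; e.g.
#'   curated units from [curate_units()]).
#' @param ann the source-species [annotation()].
#' @param orthologs data.frame from [read_ortholog_table()].
#' @param species_ann named list of [annotation()] objects, one per
#'   species appearing in `orthologs`.
#' @param restrict_to_orf see [project_antisense()].
#' @return data.frame of projected regions with columns `species`,
#'   `source_unit_id`, `gene_id`, `ortholog_gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `clipped`.
#' @export
project_antisense_set <- function(calls, ann, orthologs, species_ann,
                                  restrict_to_orf = FALSE) {
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    gene_id <- calls$gene_id[i]
    sg <- ann$genes[ann$genes$gene_id == gene_id, , drop = FALSE]
    if (nrow(sg) == 0L) stop("project_antisense_set: unknown gene ", gene_id)
    recs <- orthologs[orthologs$source_gene_id == gene_id, , drop = FALSE]
    for (j in seq_len(nrow(recs))) {
      if (is.na(recs$ortholog_gene_id[j]) || !recs$synteny_ok[j]) next
      sp <- recs$species[j]
      spann <- species_ann[[sp]]
      if (is.null(spann))
        stop("project_antisense_set: no annotation for species ", sp)
      og <- spann$genes[spann$genes$gene_id == recs$ortholog_gene_id[j], ,
                        drop = FALSE]
      if (nrow(og) == 0L)
        stop("project_antisense_set: unknown ortholog ",
             recs$ortholog_gene_id[j], " in species ", sp)
      pr <- project_antisense(
        list(unit_id = calls[[1]][i], start = calls$start[i],
             end = calls$end[i]),
        sg, og, chrom_length = unname(spann$chrom_lengths[og$chrom]),
        restrict_to_orf = restrict_to_orf)
      if (is.null(pr)) next
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, source_unit_id = calls[[1]][i], gene_id = gene_id,
        ortholog_gene_id = recs$ortholog_gene_id[j], chrom = pr$chrom,
        strand = pr$strand, start = pr$start, end = pr$end,
        clipped = pr$clipped, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(species = character(0), source_unit_id = character(0),
                      gene_id = character(0), ortholog_gene_id = character(0),
                      chrom = character(0), strand = character(0),
                      start = numeric(0), end = numeric(0),
                      clipped = logical(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Cross-species conservation matrix
#'
#' Summarizes, per (species, gene), whether an antisense candidate
#' exists and whether its regulation anticorrelates with the sense
#' gene: `concordant_anti` when sense and antisense change in opposite
#' directions between the two conditions, `present_no_anticorr` when
#' antisense is detected without anticorrelation, `absent` when no
#' antisense transcription was detected, and `no_candidate` when no
#' orthologous region exists.
#'
#' @param records data.frame with one row per (species, gene):
#'   columns `species`, `gene_id`, `has_ortholog` (logical),
#'   `antisense_detected` (logical), `sense_call`, `antisense_call`
#'   (regulation calls; ignored when not detected).
#' @return data.frame in wide form: one row per gene, one column per
#'   species, entries from the four categories.
#' @export
conservation_matrix <- function(records) {
  req <- c("species", "gene_id", "has_ortholog", "antisense_detected",
           "sense_call", "antisense_call")
  stopifnot(all(req %in% names(records)))
  if (anyDuplicated(records[, c("species", "gene_id")]))
    stop("conservation_matrix: duplicate (species, gene) record")
  cls <- ifelse(!records$has_ortholog, "no_candidate",
         ifelse(!records$antisense_detected, "absent",
         ifelse((records$sense_call == "induced" &
                 records$antisense_call == "repressed") |
                (records$sense_call == "repressed" &
                 records$antisense_call == "induced"),
                "concordant_anti", "present_no_anticorr")))
  genes <- unique(records$gene_id)
  species <- unique(records$species)
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (sp in species) {
    m <- match(paste(sp, genes), paste(records$species, records$gene_id))
    out[[sp]] <- cls[m]
  }
  out
}
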