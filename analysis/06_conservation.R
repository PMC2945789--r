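#!/usr/bin/env Rscript
# Step 6: project curated antisense units into related species.
#
# Each target gene is given an ortholog in two fictional relatives whose
# ORFs differ in length by up to +/-10% and sometimes lie on the other
# strand; antisense units are transferred through ORF-relative
# coordinates, giving candidate regions that could be tested in those
# species. Orthology is incomplete (~10% of genes have none) and a few
# assignments break synteny and are skipped.

suppressMessages(library(asunit))

ann <- read_annotation("results/simdata/annotation.gff3",
                       utr_table = "results/simdata/utr_lengths.tsv")
curated <- read.table("results/antisense_catalog.tsv", sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)

# deterministic fictional relatives derived from the source annotation
make_species <- function(ann, prefix, seed) {
  set.seed(seed)
  g <- ann$genes[order(ann$genes$orf_start), ]
  len <- round((g$orf_end - g$orf_start) * runif(nrow(g), 0.9, 1.1))
  flip <- runif(nrow(g)) < 0.2
  starts <- cumsum(c(1000, head(len, -1) + 500))
  genes <- data.frame(gene_id = paste0(prefix, "_", g$gene_id),
                      chrom = paste0(tolower(prefix), "_chr1"),
                      strand = ifelse(flip,
                                      ifelse(g$strand == "+", "-", "+"),
                                      g$strand),
                      orf_start = starts, orf_end = starts + len,
                      utr5_len = g$utr5_len, utr3_len = g$utr3_len)
  chrom_len <- max(genes$orf_end) + 1000
  names(chrom_len) <- genes$chrom[1]
  list(annotation = annotation(genes, chrom_lengths = chrom_len),
       map = data.frame(source_gene_id = g$gene_id,
                        ortholog_gene_id = genes$gene_id))
}

species <- list(Spar = make_species(ann, "SPAR", 101),
                Smik = make_species(ann, "SMIK", 102))

orth <- NULL
for (sp in names(species)) {
  set.seed(match(sp, names(species)) + 200)
  m <- species[[sp]]$map
  drop <- runif(nrow(m)) < 0.10       # gene has no ortholog
  broken <- runif(nrow(m)) < 0.05     # synteny violated: skip
  orth <- rbind(orth, data.frame(
    source_gene_id = m$source_gene_id, species = sp,
    ortholog_gene_id = ifelse(drop, NA, m$ortholog_gene_id),
    synteny_ok = !broken))
}
write.table(orth, "results/ortholog_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

proj <- project_antisense_set(curated, ann, orth,
                              lapply(species, `[[`, "annotation"))
write.table(proj, "results/projected_candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (sp in names(species))
  cat(sp, ": ", sum(proj$species == sp), " candidate regions (",
      sum(proj$species == sp & !proj$clipped), " unclipped)\n", sep = "")
cat("wrote results/ortholog_table.tsv, results/projected_candidates.tsv\n")
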