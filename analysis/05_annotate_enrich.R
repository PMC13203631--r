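#!/usr/bin/env Rscript
# Stage 5 — gene annotation of the candidate regions by interval overlap
# (half-open coordinates, strand ignored) and hypergeometric gene-set
# enrichment with Benjamini-Hochberg FDR over the annotation universe.
# Writes region-gene tables, per-direction gene lists and enrichment
# tables under results/enrichment/.

suppressPackageStartupMessages(library(sweepscan))

out <- "results/enrichment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genes <- read_gene_annotation("results/data/annotation.bed")
sets <- read_gene_sets("results/data/gene_sets.tsv")
regions <- read.delim("results/scan/candidate_regions.bed", header = FALSE,
                      col.names = c("chrom", "start", "end", "direction"))
regions$n_windows <- NA_integer_

ann <- overlap_genes(regions, genes)
write_tsv(ann$regions, file.path(out, "region_genes.tsv"))

for (dir_lab in names(ann$genes_by_direction)) {
  glist <- ann$genes_by_direction[[dir_lab]]
  writeLines(glist, file.path(out, paste0("genes_", tolower(dir_lab), ".txt")))
  message(dir_lab, ": ", length(glist), " genes")
  if (length(glist) == 0) next
  enr <- hypergeometric_enrichment(glist, sets, genes$gene_id)
  write_tsv(enr, file.path(out, paste0("enrichment_", tolower(dir_lab),
                                       ".tsv")))
  top <- enr[1, ]
  message(sprintf("  top set %s: overlap %d/%d, p = %.3g, FDR = %.3g",
                  top$set_id, top$overlap, top$set_size, top$p_value,
                  top$fdr))
}
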