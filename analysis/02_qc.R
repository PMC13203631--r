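#!/usr/bin/env Rscript
# Stage 2 — SNP quality control on the merged two-population matrix:
# missingness > 10%, MAF < 5%, HWE exact p < 1e-6 (in that order, each
# removal attributed to the first failing filter). Writes the filtered VCF
# and the per-filter report under results/qc/.

suppressPackageStartupMessages(library(sweepscan))

gm <- read_vcf("results/data/genotypes.vcf")
popmap <- read_population_map("results/data/popmap.tsv")

out <- "results/qc"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

res <- apply_qc(gm, popmap, qc_thresholds())
print(res$report)

write_vcf(res$genotypes, file.path(out, "qc.vcf"))
write_qc_report(res$report, file.path(out, "qc_report.tsv"))
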