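#!/usr/bin/env Rscript
# Stage 1 — generate the study-scale dataset: two populations ("A", an
# HT-like purebred stand-in; "B", an OLF-like F2-cross stand-in) of 144
# diploids each, ~60,000 chip SNPs over a 300-Mb five-chromosome genome,
# genome-wide divergence F = 0.05, one 500-kb intensity-1.0 sweep injected
# per population, 2% missing calls and 2% HWE-violating sites.
# Writes VCF + population map + ground truth under results/data/.

suppressPackageStartupMessages(library(sweepscan))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed = 1L)
sim <- simulate_genotypes(cfg)

write_vcf(sim$genotypes, file.path(out, "genotypes.vcf"))
write_population_map(sim$popmap, file.path(out, "popmap.tsv"))
write_truth(sim$truth, file.path(out, "truth"))

genes <- simulate_gene_annotation(cfg$chrom_lengths, seed = 2L)
write_bed(genes[, c("chrom", "start", "end", "gene_id")],
          file.path(out, "annotation.bed"))
sets <- simulate_gene_sets(genes$gene_id, seed = 3L)
write_tsv(data.frame(set_id = rep(names(sets), lengths(sets)),
                     gene_id = unlist(sets, use.names = FALSE)),
          file.path(out, "gene_sets.tsv"))

message(sprintf("simulated %d samples x %d sites (%.1f%% missing)",
                n_samples(sim$genotypes), n_sites(sim$genotypes),
                100 * mean(is.na(sim$genotypes$dosage))))
message("injected sweeps:")
print(sim$truth$sweeps)
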