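#!/usr/bin/env Rscript
# Stage 3 — population structure on the QC'd genotypes: PCA of the
# variance-standardized relationship matrix, a neighbor-joining tree from
# allele-sharing distances, and ancestry proportions by masked NMF with
# cross-entropy selection of K over 2..10 (on a deterministic 10,000-site
# thinning). Writes coordinates, tree and Q matrices under
# results/structure/.

suppressPackageStartupMessages(library(sweepscan))

gm <- read_vcf("results/qc/qc.vcf")
popmap <- read_population_map("results/data/popmap.tsv")

out <- "results/structure"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

rmat <- relationship_matrix(gm)
pca <- pca_relationship(rmat, k = 10)
write_tsv(data.frame(sample = rownames(pca$coordinates), pca$coordinates,
                     check.names = FALSE),
          file.path(out, "pca_coordinates.tsv"))
write_tsv(data.frame(component = seq_along(pca$variance_fraction),
                     variance_fraction = pca$variance_fraction),
          file.path(out, "pca_variance.tsv"))
message(sprintf("PC1 explains %.1f%%, PC2 %.1f%% of the variance",
                100 * pca$variance_fraction[1],
                100 * pca$variance_fraction[2]))

nwk <- nj_tree(p_distance_matrix(gm))
writeLines(nwk, file.path(out, "nj_tree.nwk"))

thin <- unique(round(seq(1, n_sites(gm), length.out = 10000)))
ksel <- select_K(subset_sites(gm, thin), K_range = 2:10, seeds_per_K = 1,
                 base_seed = 4L)
write_tsv(ksel$table, file.path(out, "cross_entropy.tsv"))
fit <- ksel$fits[[paste0("K", ksel$best_K)]]
write_tsv(data.frame(sample = gm$samples, round(fit$Q, 6),
                     check.names = FALSE),
          file.path(out, sprintf("admixture_Q_K%d.tsv", ksel$best_K)))
message("best K by masked cross-entropy: ", ksel$best_K)
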