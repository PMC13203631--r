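#!/usr/bin/env Rscript
# Stage 4 — the selection-signature scan: per-site F_ST averaged over 50-kb
# windows sliding by 25 kb, per-window per-bp nucleotide diversity of each
# population and their log2 ratio; candidate windows are the intersection
# of the top-5% F_ST tail with each 2.5% ratio tail, merged into candidate
# regions. Recovery is reported against the simulator's truth intervals.
# Writes window stats and candidate BEDs under results/scan/.

suppressPackageStartupMessages(library(sweepscan))

gm <- read_vcf("results/qc/qc.vcf")
popmap <- read_population_map("results/data/popmap.tsv")

out <- "results/scan"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

windows <- make_windows(default_chrom_lengths())
stats <- scan_windows(gm, popmap, windows)
write_tsv(stats, file.path(out, "window_stats.tsv"))

cand <- candidate_windows(stats)
message(sprintf("thresholds: fst_top=%.4f ratio_high=%.3f ratio_low=%.3f",
                cand$thresholds["fst_top"], cand$thresholds["ratio_high"],
                cand$thresholds["ratio_low"]))
message(sprintf("%d windows selected in A, %d in B",
                nrow(cand$selected_in_A), nrow(cand$selected_in_B)))

regions <- rbind(merge_regions(cand$selected_in_A, "SELECTED_IN_A"),
                 merge_regions(cand$selected_in_B, "SELECTED_IN_B"))
write_bed(regions, file.path(out, "candidate_regions.bed"))
as_bed <- function(df, lab) {
  if (nrow(df) == 0L) return(NULL)
  data.frame(chrom = df$chrom, start = df$start, end = df$end, name = lab)
}
sel <- rbind(as_bed(cand$selected_in_A, "SELECTED_IN_A"),
             as_bed(cand$selected_in_B, "SELECTED_IN_B"))
if (!is.null(sel)) write_bed(sel, file.path(out, "candidate_windows.bed"))

# recovery against the injected truth
truth <- read_truth_sweeps("results/data/truth_sweeps.bed")
for (pop in unique(truth$population)) {
  tr <- truth[truth$population == pop, , drop = FALSE]
  sel_pop <- if (pop == "A") cand$selected_in_A else cand$selected_in_B
  for (r in seq_len(nrow(tr))) {
    in_truth <- stats$chrom == tr$chrom[r] & stats$start < tr$end[r] &
      stats$end > tr$start[r]
    hit <- paste(stats$chrom, stats$start)[in_truth] %in%
      paste(sel_pop$chrom, sel_pop$start)
    message(sprintf("sweep %s:%d-%d (pop %s): %d/%d truth windows recovered",
                    tr$chrom[r], tr$start[r], tr$end[r], pop,
                    sum(hit), length(hit)))
  }
}
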