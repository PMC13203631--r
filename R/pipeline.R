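#' Assemble a pipeline run configuration
#'
#' Defaults mirror the analysis conventions used throughout the package:
#' missingness 0.1 / MAF 0.05 / HWE 1e-6 quality filters, 50-kb windows with
#' 25-kb steps, top-5% F_ST and 2.5% diversity-ratio tails, ancestry K
#' scanned over 2..10. Input is either a simulation configuration or a
#' VCF + population-map pair.
#'
#' @param simulation a [simulation_config()], or `NULL` when reading files
#' @param vcf,popmap input file paths (ignored when `simulation` is given)
#' @param chrom_lengths named vector of chromosome lengths; required for
#'   windowing when input comes from files, taken from the simulation
#'   otherwise
#' @param annotation gene-annotation file path (BED/GFF3), or `"simulate"`
#'   to generate a synthetic annotation over `chrom_lengths`
#' @param gene_sets gene-set TSV path, or `"simulate"`
#' @param qc a [qc_thresholds()]
#' @param hwe_mode HWE testing mode, see [apply_qc()]
#' @param window_size,step scan window geometry in bp
#' @param fst_top_fraction,ratio_tail_fraction selection-tail fractions
#' @param min_snps minimum defined sites per window for F_ST
#' @param fst_estimator per-site estimator, see [fst_site()]
#' @param K_range candidate ancestral cluster counts
#' @param seeds_per_K NMF restarts per K
#' @param structure_n_sites site count for the (thinned) ancestry NMF
#' @param pca_k principal components to report
#' @param seed master seed; every stage derives its own stream from it
#' @param out_dir output directory
#' @return a `run_config` list
#' @export
run_config <- function(simulation = simulation_config(),
                       vcf = NULL, popmap = NULL,
                       chrom_lengths = NULL,
                       annotation = "simulate",
                       gene_sets = "simulate",
                       qc = qc_thresholds(),
                       hwe_mode = "merged",
                       window_size = 50000, step = 25000,
                       fst_top_fraction = 0.05,
                       ratio_tail_fraction = 0.025,
                       min_snps = 3L,
                       fst_estimator = "ratio",
                       K_range = 2:10,
                       seeds_per_K = 1L,
                       structure_n_sites = 10000L,
                       pca_k = 10L,
                       seed = 1L,
                       out_dir = "sweepscan_run") {
  cfg <- list(simulation = simulation, vcf = vcf, popmap = popmap,
              chrom_lengths = chrom_lengths, annotation = annotation,
              gene_sets = gene_sets, qc = qc, hwe_mode = hwe_mode,
              window_size = window_size, step = step,
              fst_top_fraction = fst_top_fraction,
              ratio_tail_fraction = ratio_tail_fraction,
              min_snps = as.integer(min_snps),
              fst_estimator = fst_estimator,
              K_range = as.integer(K_range),
              seeds_per_K = as.integer(seeds_per_K),
              structure_n_sites = as.integer(structure_n_sites),
              pca_k = as.integer(pca_k),
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [run_config()]; the `simulation`
#' block maps onto [simulation_config()] fields, `qc` onto
#' [qc_thresholds()].
#'
#' @param path YAML file path
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$simulation)) {
    sim_args <- y$simulation
    if (!is.null(sim_args$sweep_specs))
      sim_args$sweep_specs <- do.call(rbind.data.frame, sim_args$sweep_specs)
    if (!is.null(sim_args$chrom_lengths))
      sim_args$chrom_lengths <- unlist(sim_args$chrom_lengths)
    args$simulation <- do.call(simulation_config, sim_args)
  }
  if (!is.null(y$qc)) args$qc <- do.call(qc_thresholds, y$qc)
  if (!is.null(y$chrom_lengths)) args$chrom_lengths <- unlist(y$chrom_lengths)
  do.call(run_config, args)
}

#' Validate a run configuration
#'
#' @param cfg a `run_config`
#' @return character vector of violation names; empty when the
#'   configuration is valid. Never mutates its input.
#' @export
validate_config <- function(cfg) {
  v <- character(0)
  if (is.null(cfg$simulation)) {
    if (is.null(cfg$vcf) || !file.exists(cfg$vcf))
      v <- c(v, "vcf_missing")
    if (is.null(cfg$popmap) || !file.exists(cfg$popmap))
      v <- c(v, "popmap_missing")
    if (is.null(cfg$chrom_lengths)) v <- c(v, "chrom_lengths_missing")
  } else {
    ok <- tryCatch({validate_simulation_config(cfg$simulation); TRUE},
                   error = function(e) FALSE)
    if (!ok) v <- c(v, "simulation_invalid")
  }
  if (cfg$window_size < cfg$step) v <- c(v, "window_lt_step")
  if (cfg$step <= 0) v <- c(v, "step_nonpositive")
  for (f in c("fst_top_fraction", "ratio_tail_fraction"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 0.5) v <- c(v, paste0(f, "_range"))
  tok <- tryCatch({
    stopifnot(inherits(cfg$qc, "qc_thresholds"),
              cfg$qc$max_missing_rate > 0, cfg$qc$max_missing_rate < 1,
              cfg$qc$min_maf > 0, cfg$qc$min_maf < 1,
              cfg$qc$hwe_alpha > 0, cfg$qc$hwe_alpha < 1)
    TRUE}, error = function(e) FALSE)
  if (!tok) v <- c(v, "qc_thresholds_invalid")
  if (any(cfg$K_range < 1L)) v <- c(v, "K_range_invalid")
  if (cfg$seeds_per_K < 1L) v <- c(v, "seeds_per_K_invalid")
  if (cfg$min_snps < 1L) v <- c(v, "min_snps_invalid")
  if (!cfg$fst_estimator %in% c("ratio", "hudson", "wc"))
    v <- c(v, "fst_estimator_unknown")
  v
}

# per-stage seed substream: adding a stage never perturbs earlier stages
.stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, annotation = 2L, qc = 3L, structure = 4L,
               scan = 5L, enrich = 6L)
  (as.integer(seed) * 1009L + 97L * offsets[[stage]]) %% 2147483647L
}

#' Run the full pipeline
#'
#' Executes simulate/load -> QC -> population structure -> selection scan ->
#' gene annotation -> enrichment, writing every stage's outputs under
#' `cfg$out_dir` and returning a manifest of files, checksums and timings.
#' A stage failure halts the run; the error names the stage.
#'
#' @param cfg a `run_config`; see [run_config()]
#' @param verbose print stage progress
#' @return a `run_manifest` list: `config`, `version`, `stages` (per-stage
#'   timing), `outputs` (file -> md5), `warnings`
#' @export
run_all <- function(cfg, verbose = TRUE) {
  violations <- validate_config(cfg)
  if (length(violations) > 0L)
    stop("invalid configuration: ", paste(violations, collapse = ", "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  outputs <- character(0)
  stages <- list()
  notes <- character(0)
  t_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    stages[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  outp <- function(name) file.path(cfg$out_dir, name)

  # ---- input stage: simulate or load ----
  dat <- t_stage("input", {
    if (!is.null(cfg$simulation)) {
      sim_cfg <- cfg$simulation
      sim_cfg$seed <- .stage_seed(cfg$seed, "simulate")
      say("simulating ", 2 * sim_cfg$n_per_pop, " samples x ",
          sim_cfg$n_sites, " sites")
      d <- simulate_genotypes(sim_cfg)
      write_vcf(d$genotypes, outp("genotypes.vcf"))
      write_population_map(d$popmap, outp("popmap.tsv"))
      write_truth(d$truth, outp("truth"))
      outputs <- c(outputs, "genotypes.vcf", "popmap.tsv",
                   "truth_sweeps.bed", "truth_freqs.tsv")
      d$chrom_lengths <- sim_cfg$chrom_lengths
      d
    } else {
      say("reading ", cfg$vcf)
      d <- list(genotypes = read_vcf(cfg$vcf),
                popmap = read_population_map(cfg$popmap),
                truth = NULL, chrom_lengths = cfg$chrom_lengths)
      d
    }
  })
  outputs <- c(outputs, if (!is.null(cfg$simulation))
    c("genotypes.vcf", "popmap.tsv", "truth_sweeps.bed", "truth_freqs.tsv"))

  genes <- t_stage("annotation_input", {
    if (identical(cfg$annotation, "simulate")) {
      g <- simulate_gene_annotation(dat$chrom_lengths,
                                    seed = .stage_seed(cfg$seed, "annotation"))
      write_bed(g[, c("chrom", "start", "end", "gene_id")],
                outp("annotation.bed"))
      outputs <- c(outputs, "annotation.bed")
      g
    } else if (!is.null(cfg$annotation)) {
      read_gene_annotation(cfg$annotation)
    } else NULL
  })
  outputs <- c(outputs, if (identical(cfg$annotation, "simulate"))
    "annotation.bed")
  sets <- if (identical(cfg$gene_sets, "simulate") && !is.null(genes)) {
    s <- simulate_gene_sets(genes$gene_id,
                            seed = .stage_seed(cfg$seed, "enrich"))
    write_tsv(data.frame(set_id = rep(names(s), lengths(s)),
                         gene_id = unlist(s, use.names = FALSE)),
              outp("gene_sets.tsv"))
    outputs <- c(outputs, "gene_sets.tsv")
    s
  } else if (!is.null(cfg$gene_sets) && !identical(cfg$gene_sets, "simulate"))
    read_gene_sets(cfg$gene_sets) else NULL

  # ---- qc ----
  qc_res <- t_stage("qc", {
    r <- apply_qc(dat$genotypes, dat$popmap, cfg$qc, hwe_mode = cfg$hwe_mode)
    write_vcf(r$genotypes, outp("qc.vcf"))
    write_qc_report(r$report, outp("qc_report.tsv"))
    say("QC: ", r$report$sites_before, " -> ", r$report$sites_after, " sites")
    r
  })
  outputs <- c(outputs, "qc.vcf", "qc_report.tsv")
  gm <- qc_res$genotypes

  # ---- population structure ----
  struct <- t_stage("structure", {
    rmat <- relationship_matrix(gm)
    pca <- pca_relationship(rmat, k = min(cfg$pca_k, n_samples(gm) - 1L))
    write_tsv(data.frame(sample = rownames(pca$coordinates),
                         pca$coordinates, check.names = FALSE),
              outp("pca_coordinates.tsv"))
    write_tsv(data.frame(component = seq_along(pca$variance_fraction),
                         variance_fraction = pca$variance_fraction),
              outp("pca_variance.tsv"))
    dmat <- p_distance_matrix(gm)
    nwk <- nj_tree(dmat)
    writeLines(nwk, con <- file(outp("nj_tree.nwk"), "wb")); close(con)
    gm_thin <- subset_sites(gm, unique(round(seq(1, n_sites(gm),
      length.out = min(cfg$structure_n_sites, n_sites(gm))))))
    ksel <- select_K(gm_thin, K_range = cfg$K_range,
                     seeds_per_K = cfg$seeds_per_K,
                     base_seed = .stage_seed(cfg$seed, "structure"))
    write_tsv(ksel$table, outp("cross_entropy.tsv"))
    best_fit <- ksel$fits[[paste0("K", ksel$best_K)]]
    write_tsv(data.frame(sample = gm$samples,
                         round(best_fit$Q, 6), check.names = FALSE),
              outp(sprintf("admixture_Q_K%d.tsv", ksel$best_K)))
    say("structure: PC1 ", sprintf("%.1f%%", 100 * pca$variance_fraction[1]),
        ", best K = ", ksel$best_K)
    list(pca = pca, nwk = nwk, ksel = ksel)
  })
  outputs <- c(outputs, "pca_coordinates.tsv", "pca_variance.tsv",
               "nj_tree.nwk", "cross_entropy.tsv",
               sprintf("admixture_Q_K%d.tsv", struct$ksel$best_K))

  # ---- selection scan ----
  scan <- t_stage("scan", {
    windows <- make_windows(dat$chrom_lengths, cfg$window_size, cfg$step)
    stats <- scan_windows(gm, dat$popmap, windows, min_snps = cfg$min_snps,
                          estimator = cfg$fst_estimator)
    write_tsv(stats, outp("window_stats.tsv"))
    cand <- candidate_windows(stats, cfg$fst_top_fraction,
                              cfg$ratio_tail_fraction)
    regions <- rbind(merge_regions(cand$selected_in_A, "SELECTED_IN_A"),
                     merge_regions(cand$selected_in_B, "SELECTED_IN_B"))
    as_bed <- function(df, lab) {
      if (nrow(df) == 0L) return(NULL)
      data.frame(chrom = df$chrom, start = df$start, end = df$end,
                 name = lab, stringsAsFactors = FALSE)
    }
    cand_bed <- rbind(as_bed(cand$selected_in_A, "SELECTED_IN_A"),
                      as_bed(cand$selected_in_B, "SELECTED_IN_B"))
    if (is.null(cand_bed))
      cand_bed <- data.frame(chrom = character(0), start = numeric(0),
                             end = numeric(0), name = character(0))
    write_bed(cand_bed, outp("candidate_windows.bed"))
    write_bed(regions, outp("candidate_regions.bed"))
    if (!is.null(attr(stats, "n_clipped")) && attr(stats, "n_clipped") > 0)
      notes <- c(notes, sprintf("fst_clipped_sites=%d",
                                attr(stats, "n_clipped")))
    say("scan: ", nrow(cand$selected_in_A), " windows selected in A, ",
        nrow(cand$selected_in_B), " in B")
    list(stats = stats, cand = cand, regions = regions)
  })
  outputs <- c(outputs, "window_stats.tsv", "candidate_windows.bed",
               "candidate_regions.bed")

  # ---- annotation + enrichment ----
  if (!is.null(genes)) {
    enr <- t_stage("annotate_enrich", {
      ann <- overlap_genes(scan$regions, genes)
      write_tsv(ann$regions, outp("region_genes.tsv"))
      outputs <- c(outputs, "region_genes.tsv")
      for (dir_lab in names(ann$genes_by_direction)) {
        fn <- paste0("genes_", tolower(dir_lab), ".txt")
        con <- file(outp(fn), "wb")
        writeLines(ann$genes_by_direction[[dir_lab]], con); close(con)
        outputs <- c(outputs, fn)
      }
      if (!is.null(sets)) {
        universe <- genes$gene_id
        for (dir_lab in names(ann$genes_by_direction)) {
          tab <- hypergeometric_enrichment(
            ann$genes_by_direction[[dir_lab]], sets, universe)
          fn <- paste0("enrichment_", tolower(dir_lab), ".tsv")
          write_tsv(tab, outp(fn))
          outputs <- c(outputs, fn)
        }
      }
      ann
    })
    outputs <- c(outputs,
                 paste0("genes_", tolower(names(enr$genes_by_direction)),
                        ".txt"),
                 if (!is.null(sets))
                   paste0("enrichment_",
                          tolower(names(enr$genes_by_direction)), ".tsv"))
  }

  outputs <- unique(outputs)
  sums <- tools::md5sum(file.path(cfg$out_dir, outputs))
  names(sums) <- outputs
  manifest <- list(config = .config_echo(cfg),
                   version = as.character(utils::packageVersion("sweepscan")),
                   stages = stages,
                   outputs = as.list(sums),
                   warnings = notes)
  class(manifest) <- "run_manifest"
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  manifest
}

# flatten the config into manifest-friendly scalars
.config_echo <- function(cfg) {
  echo <- cfg
  class(echo) <- NULL
  if (!is.null(echo$simulation)) {
    sim <- echo$simulation
    class(sim) <- NULL
    sim$chrom_lengths <- as.list(sim$chrom_lengths)
    echo$simulation <- sim
  }
  echo$qc <- unclass(echo$qc)
  echo
}
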