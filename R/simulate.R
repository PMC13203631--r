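#' Default chicken-like chromosome lengths
#'
#' Five chromosomes totaling 300 Mb, a desk-scale stand-in for the
#' macrochromosome-dominated chicken karyotype covered by a 60K SNP chip.
#'
#' @return named numeric vector of lengths in bp
#' @export
default_chrom_lengths <- function() {
  c(chr1 = 90e6, chr2 = 75e6, chr3 = 60e6, chr4 = 45e6, chr5 = 30e6)
}

#' Simulation configuration for the two-population genotype generator
#'
#' Parameters of the Balding-Nichols divergence model with injected selective
#' sweeps, missing calls and Hardy-Weinberg-violating sites. Defaults emulate
#' the study system: two populations of 144 diploid individuals genotyped at
#' ~60,000 chip SNPs.
#'
#' @param n_per_pop diploid individuals per population
#' @param n_sites total SNP count
#' @param chrom_lengths named vector, chromosome -> length in bp
#' @param divergence_fst genome-wide divergence parameter F of the
#'   Balding-Nichols model, in (0, 1)
#' @param sweep_specs data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open bp), `population` (swept population, `"A"` or `"B"`),
#'   `intensity` in (0, 1]; `NULL` for no sweeps
#' @param missing_rate i.i.d. per-call missingness probability in [0, 1)
#' @param hwe_violation_fraction fraction of sites with a deflated
#'   heterozygote frequency, in [0, 1)
#' @param hwe_violation_f inbreeding-like heterozygote deflation factor at
#'   violating sites (P(het) scaled by `1 - hwe_violation_f`)
#' @param maf_floor minimum ancestral minor-allele frequency (chip
#'   ascertainment stand-in)
#' @param seed integer RNG seed
#' @return a `simulation_config` list
#' @export
simulation_config <- function(n_per_pop = 144L,
                              n_sites = 60000L,
                              chrom_lengths = default_chrom_lengths(),
                              divergence_fst = 0.05,
                              sweep_specs = default_sweep_specs(),
                              missing_rate = 0.02,
                              hwe_violation_fraction = 0.02,
                              hwe_violation_f = 0.5,
                              maf_floor = 0.05,
                              seed = 1L) {
  cfg <- list(n_per_pop = as.integer(n_per_pop),
              n_sites = as.integer(n_sites),
              chrom_lengths = chrom_lengths,
              divergence_fst = divergence_fst,
              sweep_specs = sweep_specs,
              missing_rate = missing_rate,
              hwe_violation_fraction = hwe_violation_fraction,
              hwe_violation_f = hwe_violation_f,
              maf_floor = maf_floor,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' Default injected sweeps: one 500-kb intensity-1 sweep per population
#' @return sweep specification data.frame
#' @export
default_sweep_specs <- function() {
  data.frame(chrom = c("chr1", "chr3"),
             start = c(50.0e6, 20.0e6),
             end = c(50.5e6, 20.5e6),
             population = c("B", "A"),
             intensity = c(1.0, 1.0),
             stringsAsFactors = FALSE)
}

#' Validate a simulation configuration
#' @param cfg a `simulation_config`
#' @return `cfg`, invisibly; stops on violation
#' @export
validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_per_pop >= 2L, cfg$n_sites >= 1L)
  if (is.null(names(cfg$chrom_lengths)) || any(cfg$chrom_lengths <= 0))
    stop("chrom_lengths must be a named vector of positive lengths")
  if (cfg$divergence_fst <= 0 || cfg$divergence_fst >= 1)
    stop("divergence_fst must be in (0, 1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (cfg$hwe_violation_fraction < 0 || cfg$hwe_violation_fraction >= 1)
    stop("hwe_violation_fraction must be in [0, 1)")
  if (cfg$maf_floor < 0 || cfg$maf_floor >= 0.5)
    stop("maf_floor must be in [0, 0.5)")
  sw <- cfg$sweep_specs
  if (!is.null(sw) && nrow(sw) > 0L) {
    if (!all(sw$chrom %in% names(cfg$chrom_lengths)))
      stop("sweep interval on unknown chromosome")
    len <- cfg$chrom_lengths[sw$chrom]
    if (any(sw$start < 0) || any(sw$end > len) || any(sw$start >= sw$end))
      stop("sweep interval outside chromosome bounds")
    if (!all(sw$population %in% c("A", "B")))
      stop("swept population must be 'A' or 'B'")
    if (any(sw$intensity <= 0) || any(sw$intensity > 1))
      stop("sweep intensity must be in (0, 1]")
  }
  invisible(cfg)
}

#' Simulate a two-population SNP genotype dataset with known truth
#'
#' Sites are placed uniformly at random over the chromosomes (then sorted).
#' Each site gets an ancestral frequency p ~ Uniform(maf_floor, 1 -
#' maf_floor); each population's frequency is an independent Balding-Nichols
#' draw Beta(p(1-F)/F, (1-p)(1-F)/F) with F = `divergence_fst`. Inside a
#' sweep interval the swept population's frequency f is pulled toward its
#' nearest fixation boundary, f + intensity * (round(f) - f), erasing local
#' diversity. Genotypes are binomial(2, frequency) draws (Hardy-Weinberg),
#' except at a random `hwe_violation_fraction` of sites where the
#' heterozygote probability is deflated by `hwe_violation_f`. Calls are then
#' masked i.i.d. at `missing_rate`. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [simulation_config()]
#' @return list with elements `genotypes` (a [genotype_matrix()], populations
#'   stacked A then B), `popmap` (a [population_map()] with labels `A`, `B`)
#'   and `truth` (a `simulation_truth` list: `ancestral_freq`, `pop_freq`
#'   (2-row matrix A/B, post-sweep), `sweeps`, `hwe_violating_sites` (site
#'   indices), `config`)
#' @export
simulate_genotypes <- function(cfg) {
  validate_simulation_config(cfg)
  set.seed(cfg$seed)
  chroms <- names(cfg$chrom_lengths)
  lens <- as.numeric(cfg$chrom_lengths)

  # site placement: multinomial split proportional to length, unique positions
  n_per_chrom <- as.vector(stats::rmultinom(1, cfg$n_sites, lens / sum(lens)))
  pos_list <- lapply(seq_along(chroms), function(i) {
    if (n_per_chrom[i] == 0L) return(integer(0))
    sort(sample.int(lens[i], n_per_chrom[i], replace = FALSE))
  })
  sites <- data.frame(
    chrom = rep(chroms, n_per_chrom),
    pos = unlist(pos_list),
    stringsAsFactors = FALSE)
  sites$id <- sprintf("snp_%s_%d", sites$chrom, sites$pos)
  alleles <- c("A", "C", "G", "T")
  sites$ref <- sample(alleles, nrow(sites), replace = TRUE)
  sites$alt <- vapply(sites$ref,
                      function(r) sample(setdiff(alleles, r), 1L), "")
  m <- nrow(sites)

  p_anc <- stats::runif(m, cfg$maf_floor, 1 - cfg$maf_floor)
  f <- cfg$divergence_fst
  shape_scale <- (1 - f) / f
  freq <- rbind(
    A = stats::rbeta(m, p_anc * shape_scale, (1 - p_anc) * shape_scale),
    B = stats::rbeta(m, p_anc * shape_scale, (1 - p_anc) * shape_scale))

  sw <- cfg$sweep_specs
  if (!is.null(sw) && nrow(sw) > 0L) {
    for (k in seq_len(nrow(sw))) {
      in_sweep <- sites$chrom == sw$chrom[k] &
        sites$pos - 1L >= sw$start[k] & sites$pos - 1L < sw$end[k]
      pop <- sw$population[k]
      fcur <- freq[pop, in_sweep]
      freq[pop, in_sweep] <- fcur + sw$intensity[k] * (round(fcur) - fcur)
    }
  }

  n_viol <- round(cfg$hwe_violation_fraction * m)
  viol <- if (n_viol > 0L) sort(sample.int(m, n_viol)) else integer(0)

  n <- cfg$n_per_pop
  dosage <- rbind(.draw_genotypes(freq["A", ], n, viol, cfg$hwe_violation_f),
                  .draw_genotypes(freq["B", ], n, viol, cfg$hwe_violation_f))
  if (cfg$missing_rate > 0) {
    dosage[stats::runif(length(dosage)) < cfg$missing_rate] <- NA_integer_
  }
  samples <- c(sprintf("A_%03d", seq_len(n)), sprintf("B_%03d", seq_len(n)))
  rownames(dosage) <- samples

  gm <- genotype_matrix(dosage, sites, samples)
  pm <- population_map(samples, rep(c("A", "B"), each = n))
  truth <- structure(list(ancestral_freq = p_anc,
                          pop_freq = freq,
                          sweeps = sw,
                          hwe_violating_sites = viol,
                          config = cfg),
                     class = "simulation_truth")
  list(genotypes = gm, popmap = pm, truth = truth)
}

# Genotypes for one population: HWE binomial draws, except violating sites,
# where P(het) = 2pq(1-f_inb) and the deficit goes to the homozygotes.
.draw_genotypes <- function(freq, n, viol_idx, f_inb) {
  m <- length(freq)
  p <- rep(freq, each = n)
  p0 <- (1 - p)^2
  p1 <- 2 * p * (1 - p)
  if (length(viol_idx) > 0L) {
    vmask <- rep(seq_len(m) %in% viol_idx, each = n)
    q <- 1 - p[vmask]
    pv <- p[vmask]
    p1[vmask] <- 2 * pv * q * (1 - f_inb)
    p0[vmask] <- q^2 + pv * q * f_inb
  }
  u <- stats::runif(n * m)
  g <- ifelse(u < p0, 0L, ifelse(u < p0 + p1, 1L, 2L))
  matrix(as.integer(g), nrow = n, ncol = m)
}

#' Write simulation ground truth to plain-text files
#'
#' Sweep intervals go to `<prefix>_sweeps.bed` (column 4 = swept population),
#' per-site frequencies to `<prefix>_freqs.tsv`.
#'
#' @param truth a `simulation_truth`
#' @param prefix output path prefix
#' @return character vector of the written paths, invisibly
#' @export
write_truth <- function(truth, prefix) {
  bed_path <- paste0(prefix, "_sweeps.bed")
  sw <- truth$sweeps
  if (is.null(sw)) sw <- data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0), population = character(0))
  write_bed(data.frame(chrom = sw$chrom, start = sw$start, end = sw$end,
                       name = sw$population, stringsAsFactors = FALSE),
            bed_path)
  tsv_path <- paste0(prefix, "_freqs.tsv")
  write_tsv(data.frame(site = seq_along(truth$ancestral_freq),
                       ancestral = truth$ancestral_freq,
                       freq_A = truth$pop_freq["A", ],
                       freq_B = truth$pop_freq["B", ],
                       hwe_violating =
                         seq_along(truth$ancestral_freq) %in%
                           truth$hwe_violating_sites),
            tsv_path)
  invisible(c(bed_path, tsv_path))
}

#' Read a sweep-truth BED back into a data.frame
#' @param path BED file written by [write_truth()]
#' @return data.frame with columns `chrom`, `start`, `end`, `population`
#' @export
read_truth_sweeps <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), population = character(0),
                      stringsAsFactors = FALSE))
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "population"))
  tab
}

#' Simulate a gene annotation over the simulated genome
#'
#' Places non-overlapping gene intervals uniformly along each chromosome, a
#' synthetic stand-in for a reference gene annotation so that the annotation
#' and enrichment stages can run against simulated scans.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp)
#' @param n_genes total gene count
#' @param mean_length mean gene length in bp
#' @param seed RNG seed
#' @return gene table as from [read_gene_annotation()]
#' @export
simulate_gene_annotation <- function(chrom_lengths, n_genes = 3000L,
                                     mean_length = 20000L, seed = 1L) {
  set.seed(seed)
  lens <- as.numeric(chrom_lengths)
  n_per <- as.vector(stats::rmultinom(1, n_genes, lens / sum(lens)))
  out <- lapply(seq_along(lens), function(i) {
    k <- n_per[i]
    if (k == 0L) return(NULL)
    gl <- pmax(200, round(stats::rexp(k, 1 / mean_length)))
    start <- sort(sample.int(max(1, lens[i] - max(gl)), k))
    data.frame(chrom = names(chrom_lengths)[i],
               start = start,
               end = pmin(start + gl, lens[i]),
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, out)
  genes$gene_id <- sprintf("gene_%05d", seq_len(nrow(genes)))
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Simulate gene sets over an annotation
#'
#' Random gene sets for exercising the enrichment stage: each set draws its
#' size log-uniformly between `min_size` and `max_size` from the gene
#' universe.
#'
#' @param gene_ids character vector of universe gene ids
#' @param n_sets number of sets
#' @param min_size,max_size set size range
#' @param seed RNG seed
#' @return named list of character vectors
#' @export
simulate_gene_sets <- function(gene_ids, n_sets = 50L, min_size = 10L,
                               max_size = 100L, seed = 1L) {
  set.seed(seed)
  sizes <- pmin(round(exp(stats::runif(n_sets, log(min_size), log(max_size)))),
                length(gene_ids))
  sets <- lapply(sizes, function(s) sort(sample(gene_ids, s)))
  names(sets) <- sprintf("set_%03d", seq_len(n_sets))
  sets
}
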