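#' Construct a genotype matrix
#'
#' The central container of the package: an `n_samples x n_sites` diploid
#' dosage matrix (counts of the alternate allele, `NA` = missing call)
#' together with per-site metadata. Sites must be sorted by `(chrom, pos)`
#' with chromosomes forming contiguous blocks; violations are an error, never
#' silently repaired.
#'
#' @param dosage integer matrix, samples in rows, sites in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param sites data.frame with columns `chrom`, `pos` (1-based bp), `id`,
#'   `ref`, `alt`.
#' @param samples character vector of unique sample names, one per row of
#'   `dosage`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sites, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  samples <- as.character(samples)

  required <- c("chrom", "pos", "id", "ref", "alt")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0L)
    stop("sites is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(dosage) != length(samples))
    stop("dosage has ", nrow(dosage), " rows but there are ",
         length(samples), " samples")
  if (ncol(dosage) != nrow(sites))
    stop("dosage has ", ncol(dosage), " columns but there are ",
         nrow(sites), " sites")
  if (anyDuplicated(samples))
    stop("duplicate sample names: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  bad <- dosage[!is.na(dosage)]
  if (length(bad) > 0L && (min(bad) < 0L || max(bad) > 2L))
    stop("dosage entries must be 0, 1, 2 or NA")
  if (nrow(sites) > 0L) {
    if (any(sites$pos < 1L)) stop("site positions must be >= 1")
    if (any(sites$ref == sites$alt))
      stop("ref and alt alleles must differ at every site")
    .check_site_order(sites)
  }
  rownames(dosage) <- samples
  colnames(dosage) <- sites$id
  structure(list(dosage = dosage, sites = sites, samples = samples),
            class = "genotype_matrix")
}

# sites must form contiguous chromosome blocks with strictly increasing pos
.check_site_order <- function(sites) {
  chrom <- as.character(sites$chrom)
  blocks <- rle(chrom)$values
  if (anyDuplicated(blocks))
    stop("sites are not grouped by chromosome (chromosome blocks repeat)")
  pos_ok <- tapply(sites$pos, factor(chrom, levels = blocks),
                   function(p) all(diff(p) > 0))
  if (!all(unlist(pos_ok)))
    stop("site positions are not strictly increasing within a chromosome ",
         "(unsorted or duplicated (chrom, pos))")
  invisible(TRUE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$sites), "sites on",
      length(unique(x$sites$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing fraction: %.4f\n", if (is.nan(miss)) 0 else miss))
  invisible(x)
}

#' Number of samples / sites in a genotype matrix
#' @param gm a `genotype_matrix`
#' @return integer count
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname n_samples
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' Subset a genotype matrix by site index
#'
#' @param gm a `genotype_matrix`
#' @param site_idx integer or logical index over sites
#' @return a `genotype_matrix` with the selected sites, sample set unchanged
#' @export
subset_sites <- function(gm, site_idx) {
  genotype_matrix(gm$dosage[, site_idx, drop = FALSE],
                  gm$sites[site_idx, , drop = FALSE],
                  gm$samples)
}

#' Construct a population map
#'
#' Assigns every sample to one of (in scan mode) exactly two populations.
#' Labels are reported in lexicographic order; by convention the first label
#' is population A (the HT-like population of the diversity ratio's
#' numerator) and the second is population B.
#'
#' @param samples character vector of sample names
#' @param populations character vector of population labels, parallel to
#'   `samples`
#' @return an object of class `population_map`: a data.frame with columns
#'   `sample` and `population`, plus a `labels` attribute (sorted unique
#'   labels).
#' @export
population_map <- function(samples, populations) {
  samples <- as.character(samples)
  populations <- as.character(populations)
  if (length(samples) != length(populations))
    stop("samples and populations must have equal length")
  dup <- duplicated(samples)
  if (any(dup)) {
    first <- match(samples[dup], samples)
    if (any(populations[dup] != populations[first]))
      stop("sample(s) repeated with conflicting population labels: ",
           paste(unique(samples[dup][populations[dup] != populations[first]]),
                 collapse = ", "))
    samples <- samples[!dup]
    populations <- populations[!dup]
  }
  labels <- sort(unique(populations))
  if (length(labels) < 1L) stop("population map is empty")
  pm <- data.frame(sample = samples, population = populations,
                   stringsAsFactors = FALSE)
  attr(pm, "labels") <- labels
  class(pm) <- c("population_map", "data.frame")
  pm
}

#' Split sample indices of a genotype matrix by population
#'
#' @param gm a `genotype_matrix`
#' @param popmap a `population_map` covering every sample of `gm`
#' @param n_populations required number of populations (default 2 for the
#'   two-population scan); `NA` to skip the check
#' @return named list of integer row-index vectors, one per population label
#'   in lexicographic label order
#' @export
population_indices <- function(gm, popmap, n_populations = 2L) {
  idx <- match(gm$samples, popmap$sample)
  if (anyNA(idx))
    stop("samples missing from population map: ",
         paste(gm$samples[is.na(idx)], collapse = ", "))
  pops <- popmap$population[idx]
  labels <- sort(unique(pops))
  if (!is.na(n_populations) && length(labels) != n_populations)
    stop("expected ", n_populations, " populations, found ", length(labels),
         ": ", paste(labels, collapse = ", "))
  out <- lapply(labels, function(l) which(pops == l))
  names(out) <- labels
  if (any(lengths(out) == 0L)) stop("a population has no samples")
  out
}
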