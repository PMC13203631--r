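#' SNP quality-control thresholds
#'
#' Defaults follow common chip-data practice: sites with call missingness
#' above 10%, minor-allele frequency below 5%, or Hardy-Weinberg exact-test
#' p below 1e-6 are removed. Both boundary comparisons are strict: a site at
#' exactly the missingness or MAF threshold is retained.
#'
#' @param max_missing_rate remove sites with missing rate strictly greater
#' @param min_maf remove sites with MAF strictly lower
#' @param hwe_alpha remove sites with HWE exact p strictly lower
#' @return a `qc_thresholds` list
#' @export
qc_thresholds <- function(max_missing_rate = 0.10, min_maf = 0.05,
                          hwe_alpha = 1e-6) {
  # boundary values give vacuous filters (all comparisons are strict)
  stopifnot(max_missing_rate > 0, max_missing_rate <= 1,
            min_maf >= 0, min_maf < 1, hwe_alpha >= 0, hwe_alpha < 1)
  structure(list(max_missing_rate = max_missing_rate, min_maf = min_maf,
                 hwe_alpha = hwe_alpha), class = "qc_thresholds")
}

#' Per-site missing-call rate
#' @param gm a [genotype_matrix()]
#' @param site_idx site index vector; default all sites
#' @return numeric vector of missing fractions in [0, 1]
#' @export
site_missing_rate <- function(gm, site_idx = seq_len(n_sites(gm))) {
  unname(colMeans(is.na(gm$dosage[, site_idx, drop = FALSE])))
}

#' Per-site minor-allele frequency
#'
#' Computed over non-missing genotypes only: the alternate-allele frequency
#' is the dosage sum over twice the non-missing count, folded to
#' `min(f, 1 - f)`. `NaN` where every genotype is missing.
#'
#' @inheritParams site_missing_rate
#' @return numeric vector of MAF values in [0, 0.5] (`NaN` if all missing)
#' @export
minor_allele_frequency <- function(gm, site_idx = seq_len(n_sites(gm))) {
  d <- gm$dosage[, site_idx, drop = FALSE]
  n_obs <- colSums(!is.na(d))
  f <- colSums(d, na.rm = TRUE) / (2 * n_obs)
  unname(pmin(f, 1 - f))
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided test conditioning on the observed allele count: with n
#' diploids and minor-allele count n_a fixed, the heterozygote count k has
#' probability proportional to 2^k * n! / (n_AA! k! n_aa!); the p-value sums
#' the probabilities of all outcomes no more likely than the observed one.
#' Monomorphic sites give p = 1. Vectorized over sites.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectors of equal length)
#' @return numeric vector of p-values in (0, 1]
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(n_AA < 0 | n_Aa < 0 | n_aa < 0, na.rm = TRUE))
    stop("genotype counts must be non-negative")
  mapply(.hwe_exact_one, n_AA, n_Aa, n_aa)
}

.hwe_exact_one <- function(n_AA, n_Aa, n_aa) {
  if (anyNA(c(n_AA, n_Aa, n_aa))) return(NA_real_)
  n <- n_AA + n_Aa + n_aa
  if (n < 1L) stop("genotype counts sum to zero")
  n_a <- 2L * min(n_AA, n_aa) + n_Aa     # minor-allele count
  if (n_a == 0L) return(1.0)             # monomorphic: single outcome
  # heterozygote counts share n_a's parity, bounded by allele counts
  k <- seq.int(n_a %% 2L, min(n_a, 2L * n - n_a), by = 2L)
  # log unnormalized conditional probability
  logp <- k * log(2) - lgamma((n_a - k) / 2 + 1) - lgamma(k + 1) -
    lgamma((2 * n - n_a - k) / 2 + 1)
  logp <- logp - max(logp)
  prob <- exp(logp)
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_Aa, k)]
  # tolerance absorbs floating-point ties between equally likely outcomes
  min(1.0, sum(prob[prob <= p_obs * (1 + 1e-9)]))
}

#' Per-site HWE p-values for a genotype matrix
#'
#' @inheritParams site_missing_rate
#' @param sample_idx rows to use (default all; pass a population's rows for
#'   per-population testing)
#' @return numeric vector of p-values (`NA` where no genotypes observed)
#' @export
hwe_test_sites <- function(gm, site_idx = seq_len(n_sites(gm)),
                           sample_idx = seq_len(n_samples(gm))) {
  d <- gm$dosage[sample_idx, site_idx, drop = FALSE]
  n0 <- colSums(d == 0L, na.rm = TRUE)
  n1 <- colSums(d == 1L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  p <- rep(NA_real_, length(n0))
  ok <- (n0 + n1 + n2) >= 1L
  p[ok] <- hwe_exact_test(n0[ok], n1[ok], n2[ok])
  p
}

#' Apply the three-stage SNP filter
#'
#' Removes sites in order: missing rate > `max_missing_rate`, then MAF <
#' `min_maf`, then HWE exact p < `hwe_alpha`; each removed site is
#' attributed to the first filter that rejects it. By default HWE is tested
#' on the merged two-population matrix (which conflates Wahlund structure
#' with genotyping error — a per-population mode is available).
#'
#' @param gm a [genotype_matrix()]
#' @param popmap a [population_map()]; required for `hwe_mode =
#'   "per_population"`, otherwise optional
#' @param thresholds a [qc_thresholds()]
#' @param hwe_mode `"merged"` (default) tests all samples jointly;
#'   `"per_population"` tests each population and removes a site if its
#'   minimum per-population p is below `hwe_alpha`
#' @return list with `genotypes` (filtered [genotype_matrix()]) and `report`
#'   (a `qc_report`: per-filter removed counts, per-site flags, before/after
#'   totals)
#' @export
apply_qc <- function(gm, popmap = NULL, thresholds = qc_thresholds(),
                     hwe_mode = c("merged", "per_population")) {
  hwe_mode <- match.arg(hwe_mode)
  m <- n_sites(gm)
  miss <- site_missing_rate(gm)
  fail_miss <- miss > thresholds$max_missing_rate
  # fully missing sites carry NaN MAF; they are caught by the missingness
  # filter (rate 1 > any valid threshold)
  maf <- minor_allele_frequency(gm)
  fail_maf <- !fail_miss & !is.nan(maf) & maf < thresholds$min_maf
  survivors <- !fail_miss & !fail_maf
  fail_hwe <- rep(FALSE, m)
  if (any(survivors)) {
    idx <- which(survivors)
    if (hwe_mode == "merged") {
      p <- hwe_test_sites(gm, idx)
    } else {
      if (is.null(popmap)) stop("per_population HWE mode needs a popmap")
      pops <- population_indices(gm, popmap, n_populations = NA)
      pmat <- vapply(pops, function(rows) hwe_test_sites(gm, idx, rows),
                     numeric(length(idx)))
      p <- do.call(pmin, c(as.data.frame(pmat), na.rm = TRUE))
    }
    fail_hwe[idx] <- !is.na(p) & p < thresholds$hwe_alpha
  }
  keep <- survivors & !fail_hwe
  if (!any(keep)) warning("no sites survive QC")
  flags <- rep("pass", m)
  flags[fail_hwe] <- "hwe"
  flags[fail_maf] <- "maf"
  flags[fail_miss] <- "missing"
  report <- structure(list(
    sites_before = m,
    sites_after = sum(keep),
    removed = c(missing = sum(fail_miss), maf = sum(fail_maf),
                hwe = sum(fail_hwe)),
    thresholds = thresholds,
    hwe_mode = hwe_mode,
    site_flags = flags), class = "qc_report")
  list(genotypes = subset_sites(gm, keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC:", x$sites_before, "sites ->", x$sites_after, "retained\n")
  cat(sprintf("  removed: %d missingness, %d MAF, %d HWE (%s)\n",
              x$removed["missing"], x$removed["maf"], x$removed["hwe"],
              x$hwe_mode))
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `qc_report`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_qc_report <- function(report, path) {
  write_tsv(data.frame(
    metric = c("sites_before", "removed_missing", "removed_maf",
               "removed_hwe", "sites_after"),
    value = c(report$sites_before, report$removed["missing"],
              report$removed["maf"], report$removed["hwe"],
              report$sites_after)), path)
}
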