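#' Per-site F_ST from two population allele frequencies
#'
#' F_ST = (pA - pB)^2 / (pA(1-pA) + pB(1-pB)). The expression exceeds 1 for
#' strongly diverged polymorphic pairs (e.g. pA = 0.9, pB = 0.1), so values
#' are clipped at 1 and the clip count recorded in attribute `n_clipped`.
#' When the denominator is zero the value is 1 for a fixed difference
#' (pA != pB) and undefined (`NA`) when both populations are fixed for the
#' same allele. Alternative estimators: `"hudson"` (1 - Hw/Hb) and
#' `"wc"` (Weir-Cockerham variance components, sample-size aware).
#'
#' @param p_a,p_b allele frequencies in [0, 1] (vectors)
#' @param estimator `"ratio"` (default, the squared-difference form),
#'   `"hudson"`, or `"wc"`
#' @param n_a,n_b per-site haploid sample sizes (2 x diploid counts);
#'   required for `"wc"` only
#' @return numeric vector of F_ST values (`NA` where undefined), with
#'   attribute `n_clipped`
#' @export
fst_site <- function(p_a, p_b, estimator = c("ratio", "hudson", "wc"),
                     n_a = NULL, n_b = NULL) {
  estimator <- match.arg(estimator)
  if (any(p_a < 0 | p_a > 1, na.rm = TRUE) ||
      any(p_b < 0 | p_b > 1, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]")
  if (estimator == "ratio") {
    num <- (p_a - p_b)^2
    den <- p_a * (1 - p_a) + p_b * (1 - p_b)
    fst <- ifelse(den > 0, num / den, ifelse(num > 0, 1, NA_real_))
    n_clipped <- sum(fst > 1, na.rm = TRUE)
    fst <- pmin(fst, 1)
  } else if (estimator == "hudson") {
    hb <- p_a * (1 - p_b) + p_b * (1 - p_a)  # between-population heterozygosity
    fst <- ifelse(hb > 0, 1 - (p_a * (1 - p_a) + p_b * (1 - p_b)) / hb,
                  NA_real_)
    n_clipped <- 0L
  } else {
    if (is.null(n_a) || is.null(n_b))
      stop("Weir-Cockerham estimator needs haploid sample sizes n_a, n_b")
    fst <- .fst_wc(p_a, p_b, n_a, n_b)
    n_clipped <- 0L
  }
  attr(fst, "n_clipped") <- n_clipped
  fst
}

# Weir & Cockerham two-population theta from allele frequencies and haploid
# sample sizes (heterozygosity correction term omitted: frequencies only)
.fst_wc <- function(p1, p2, n1, n2) {
  r <- 2
  n_bar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  a <- (n_bar / nc) *
    (s2 - (p_bar * (1 - p_bar) - s2 * (r - 1) / r) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) * (p_bar * (1 - p_bar) - s2 * (r - 1) / r)
  ifelse(a + b > 0, a / (a + b), NA_real_)
}

#' Tile sliding windows over chromosomes
#'
#' Windows start at 0, step, 2*step, ... per chromosome; a window is emitted
#' iff its start lies inside the chromosome, and its end is truncated to the
#' chromosome length. Coordinates are 0-based half-open.
#'
#' @param chrom_lengths named vector, chromosome -> length in bp
#' @param window_size window width in bp (default 50 kb)
#' @param step step between window starts in bp (default 25 kb)
#' @return data.frame with columns `chrom`, `start`, `end`, ordered by
#'   `(chrom, start)` in the input chromosome order
#' @export
make_windows <- function(chrom_lengths, window_size = 50000, step = 25000) {
  if (window_size < step || step <= 0)
    stop("need window_size >= step > 0")
  if (length(chrom_lengths) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-population alternate-allele frequencies over non-missing genotypes
#'
#' @param gm a [genotype_matrix()]
#' @param popmap a [population_map()] with two populations
#' @return list per population label: `freq` (alt-allele frequency, `NaN`
#'   where all missing) and `n_obs` (non-missing diploid count), plus
#'   `labels`
#' @export
population_frequencies <- function(gm, popmap) {
  pops <- population_indices(gm, popmap)
  out <- lapply(pops, function(rows) {
    d <- gm$dosage[rows, , drop = FALSE]
    n_obs <- colSums(!is.na(d))
    list(freq = colSums(d, na.rm = TRUE) / (2 * n_obs), n_obs = n_obs)
  })
  out$labels <- names(pops)
  out
}

# map site positions onto windows; returns list of site-index vectors,
# one per window row. 1-based pos covers the base [pos-1, pos).
.sites_in_windows <- function(sites, windows) {
  res <- vector("list", nrow(windows))
  for (ch in unique(windows$chrom)) {
    w_idx <- which(windows$chrom == ch)
    s_idx <- which(sites$chrom == ch)
    if (length(s_idx) == 0L) {
      res[w_idx] <- list(integer(0))
      next
    }
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = windows$start[w_idx] + 1,
                       end = windows$end[w_idx]),
      IRanges::IRanges(start = sites$pos[s_idx], width = 1))
    sp <- split(s_idx[S4Vectors::subjectHits(hits)],
                factor(S4Vectors::queryHits(hits),
                       levels = seq_along(w_idx)))
    res[w_idx] <- sp
  }
  res
}

#' Windowed selection-signature scan
#'
#' Computes, per sliding window: mean per-site F_ST over defined sites
#' (undefined below `min_snps` defined sites), per-bp nucleotide diversity
#' of each population (pairwise genotype differences summed over in-window
#' sites, divided by the window span), and the log2 ratio of the two
#' diversities, `log2(pi_A / pi_B)` with A the lexicographically first
#' population label (undefined unless both diversities are positive).
#'
#' @param gm a QC-filtered [genotype_matrix()]
#' @param popmap a [population_map()] with two populations
#' @param windows window table from [make_windows()]
#' @param min_snps minimum defined-F_ST sites for a window-level F_ST
#' @param estimator F_ST estimator, see [fst_site()]
#' @return `window_stats` data.frame: `chrom`, `start`, `end`, `n_snps`,
#'   `fst`, `pi_A`, `pi_B`, `log2_ratio`; attributes `n_clipped`,
#'   `labels`
#' @export
scan_windows <- function(gm, popmap, windows, min_snps = 3L,
                         estimator = "ratio") {
  freqs <- population_frequencies(gm, popmap)
  labels <- freqs$labels
  fa <- freqs[[labels[1]]]; fb <- freqs[[labels[2]]]
  ok <- fa$n_obs > 0L & fb$n_obs > 0L
  fst <- rep(NA_real_, n_sites(gm))
  fst_ok <- fst_site(fa$freq[ok], fb$freq[ok], estimator = estimator,
                     n_a = 2 * fa$n_obs[ok], n_b = 2 * fb$n_obs[ok])
  fst[ok] <- fst_ok
  pi_a <- pi_site(gm, population_indices(gm, popmap)[[labels[1]]])
  pi_b <- pi_site(gm, population_indices(gm, popmap)[[labels[2]]])

  site_lists <- .sites_in_windows(gm$sites, windows)
  n_snps <- lengths(site_lists)
  span <- windows$end - windows$start
  w_fst <- vapply(site_lists, function(s, v) {
    vals <- v[s]; vals <- vals[!is.na(vals)]
    if (length(vals) < min_snps) NA_real_ else mean(vals)
  }, 0, v = fst)
  sum0 <- function(s, v) sum(v[s], na.rm = TRUE)
  w_pi_a <- vapply(site_lists, sum0, 0, v = pi_a) / span
  w_pi_b <- vapply(site_lists, sum0, 0, v = pi_b) / span
  ratio <- ifelse(w_pi_a > 0 & w_pi_b > 0, log2(w_pi_a / w_pi_b), NA_real_)
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, n_snps = n_snps, fst = w_fst,
                    pi_A = w_pi_a, pi_B = w_pi_b, log2_ratio = ratio,
                    stringsAsFactors = FALSE)
  attr(out, "n_clipped") <- attr(fst_ok, "n_clipped")
  attr(out, "labels") <- labels
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Per-site nucleotide diversity within one population
#'
#' pi = 1/(n(n-1)) * sum over ordered-free pairs i<j of d_ij, with d_ij =
#' |dosage_i - dosage_j| / 2 and n the non-missing diploid count at the
#' site. Sites with fewer than 2 non-missing genotypes return `NA`.
#' Computed from genotype-class counts rather than explicit pairs.
#'
#' @param gm a [genotype_matrix()]
#' @param sample_idx rows belonging to the population
#' @return numeric vector, one value per site
#' @export
pi_site <- function(gm, sample_idx) {
  d <- gm$dosage[sample_idx, , drop = FALSE]
  n0 <- colSums(d == 0L, na.rm = TRUE)
  n1 <- colSums(d == 1L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  n <- n0 + n1 + n2
  pairsum <- 0.5 * n0 * n1 + 1.0 * n0 * n2 + 0.5 * n1 * n2
  unname(ifelse(n >= 2L, pairsum / (n * (n - 1)), NA_real_))
}

#' log2 diversity ratio
#' @param pi_a,pi_b per-window diversities (>= 0)
#' @return `log2(pi_a / pi_b)`; `NA` unless both are positive
#' @export
log2_pi_ratio <- function(pi_a, pi_b) {
  ifelse(pi_a > 0 & pi_b > 0, log2(pi_a / pi_b), NA_real_)
}

#' Empirical percentile cutoff
#'
#' Linear-interpolation quantile (the (q*(m-1))-th order statistic, R type
#' 7). "Top" selection takes values strictly greater than the (1 - f)
#' quantile; "bottom" strictly smaller than the f quantile, so threshold
#' ties are excluded.
#'
#' @param values numeric vector; `NA`s dropped
#' @param fraction tail fraction in (0, 0.5)
#' @param tail `"top"` or `"bottom"`
#' @param min_values minimum number of defined values required
#' @return list with `threshold` and `selected` (logical over `values`,
#'   `FALSE` at `NA`)
#' @export
percentile_cutoff <- function(values, fraction, tail = c("top", "bottom"),
                              min_values = 20L) {
  tail <- match.arg(tail)
  if (fraction <= 0 || fraction >= 0.5) stop("fraction must be in (0, 0.5)")
  ok <- !is.na(values)
  if (sum(ok) < min_values)
    stop("need at least ", min_values, " defined values, have ", sum(ok))
  if (tail == "top") {
    thr <- stats::quantile(values[ok], 1 - fraction, type = 7, names = FALSE)
    sel <- ok & values > thr
  } else {
    thr <- stats::quantile(values[ok], fraction, type = 7, names = FALSE)
    sel <- ok & values < thr
  }
  list(threshold = thr, selected = sel)
}

#' Candidate windows by intersecting F_ST and diversity-ratio tails
#'
#' The top `fst_top_fraction` of window F_ST values is intersected with each
#' tail of the log2(pi_A/pi_B) distribution: a high ratio (A much more
#' diverse than B) flags selection in population B, a low ratio selection in
#' population A. Windows with undefined F_ST or ratio are excluded from the
#' respective ranking, with one exception: a window where exactly one
#' population has zero diversity (and the other does not) lies beyond the
#' corresponding ratio tail — its ratio is infinite, the extreme of a sweep
#' signal — and is treated as selected on that side. Thresholds themselves
#' are always computed over the defined (finite) ratios only.
#'
#' @param stats a `window_stats` table from [scan_windows()]
#' @param fst_top_fraction F_ST upper-tail fraction (default 0.05)
#' @param ratio_tail_fraction ratio tail fraction per side (default 0.025)
#' @return list with `selected_in_A` / `selected_in_B` (window_stats rows),
#'   `thresholds` (named numeric), and per-criterion selection masks
#' @export
candidate_windows <- function(stats, fst_top_fraction = 0.05,
                              ratio_tail_fraction = 0.025) {
  if (fst_top_fraction <= 0 || fst_top_fraction >= 0.5 ||
      ratio_tail_fraction <= 0 || ratio_tail_fraction >= 0.5)
    stop("tail fractions must be in (0, 0.5)")
  fst_cut <- percentile_cutoff(stats$fst, fst_top_fraction, "top")
  hi_cut <- percentile_cutoff(stats$log2_ratio, ratio_tail_fraction, "top")
  lo_cut <- percentile_cutoff(stats$log2_ratio, ratio_tail_fraction, "bottom")
  inf_hi <- stats$pi_A > 0 & stats$pi_B == 0  # ratio +Inf: beyond the top tail
  inf_lo <- stats$pi_A == 0 & stats$pi_B > 0  # ratio -Inf: beyond the bottom
  hi_sel <- hi_cut$selected | inf_hi
  lo_sel <- lo_cut$selected | inf_lo
  sel_b <- fst_cut$selected & hi_sel
  sel_a <- fst_cut$selected & lo_sel
  list(selected_in_A = stats[sel_a, , drop = FALSE],
       selected_in_B = stats[sel_b, , drop = FALSE],
       thresholds = c(fst_top = fst_cut$threshold,
                      ratio_high = hi_cut$threshold,
                      ratio_low = lo_cut$threshold),
       fst_selected = fst_cut$selected,
       ratio_high_selected = hi_sel,
       ratio_low_selected = lo_sel)
}

#' Merge selected windows into candidate regions
#'
#' Overlapping or book-ended windows of one direction collapse into maximal
#' half-open intervals; the source-window count is recorded per region.
#'
#' @param windows data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), all of one direction
#' @param direction label stored on the regions (`"SELECTED_IN_A"` or
#'   `"SELECTED_IN_B"`)
#' @return data.frame `chrom`, `start`, `end`, `direction`, `n_windows`
#' @export
merge_regions <- function(windows, direction = NA_character_) {
  if (nrow(windows) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), direction = character(0),
                      n_windows = integer(0), stringsAsFactors = FALSE))
  gr <- GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(windows$start + 1, windows$end))
  red <- GenomicRanges::reduce(gr)  # merges overlapping and book-ended
  hits <- GenomicRanges::countOverlaps(red, gr)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1,
                    end = GenomicRanges::end(red),
                    direction = direction,
                    n_windows = as.integer(hits),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}
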