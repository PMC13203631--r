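# Independent brute-force oracles. These deliberately recompute every
# statistic from first principles (explicit loops, enumeration), never by
# calling the package's own vectorized paths.

# Eq.-1 style per-site differentiation, scalar
oracle_fst <- function(pA, pB) {
  num <- (pA - pB)^2
  den <- pA * (1 - pA) + pB * (1 - pB)
  if (den == 0) {
    if (num == 0) return(NA_real_)
    return(1)
  }
  min(num / den, 1)
}

# pairwise-difference diversity at one site, explicit double loop
oracle_pi <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  n <- length(d)
  if (n < 2) return(NA_real_)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + abs(d[i] - d[j]) / 2
  unname(s / (n * (n - 1)))
}

# naive window statistics from raw genotypes
oracle_window_stats <- function(gm, a_rows, b_rows, win_chrom, win_start,
                                win_end, min_snps = 3L) {
  in_win <- which(gm$sites$chrom == win_chrom &
                    gm$sites$pos - 1 >= win_start & gm$sites$pos - 1 < win_end)
  fst_vals <- c(); pi_a <- 0; pi_b <- 0
  for (s in in_win) {
    ga <- gm$dosage[a_rows, s]; gb <- gm$dosage[b_rows, s]
    na_obs <- sum(!is.na(ga)); nb_obs <- sum(!is.na(gb))
    if (na_obs > 0 && nb_obs > 0) {
      f <- oracle_fst(sum(ga, na.rm = TRUE) / (2 * na_obs),
                      sum(gb, na.rm = TRUE) / (2 * nb_obs))
      if (!is.na(f)) fst_vals <- c(fst_vals, f)
    }
    pa <- oracle_pi(ga); pb <- oracle_pi(gb)
    if (!is.na(pa)) pi_a <- pi_a + pa
    if (!is.na(pb)) pi_b <- pi_b + pb
  }
  span <- win_end - win_start
  list(fst = if (length(fst_vals) >= min_snps) unname(mean(fst_vals)) else NA_real_,
       pi_a = unname(pi_a / span), pi_b = unname(pi_b / span),
       n_snps = length(in_win))
}

# genomic relationship by explicit per-pair, per-site accumulation
oracle_relationship <- function(gm) {
  d <- gm$dosage
  n <- nrow(d)
  p <- numeric(ncol(d)); use <- logical(ncol(d))
  for (s in seq_len(ncol(d))) {
    g <- d[, s]
    obs <- sum(!is.na(g))
    if (obs == 0) next
    p[s] <- sum(g, na.rm = TRUE) / (2 * obs)
    use[s] <- p[s] > 0 && p[s] < 1
  }
  m <- sum(use)
  r <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (s in which(use)) {
      zi <- if (is.na(d[i, s])) 0 else
        (d[i, s] - 2 * p[s]) / sqrt(2 * p[s] * (1 - p[s]))
      zj <- if (is.na(d[j, s])) 0 else
        (d[j, s] - 2 * p[s]) / sqrt(2 * p[s] * (1 - p[s]))
      acc <- acc + zi * zj
    }
    r[i, j] <- acc / m
  }
  r
}

# exact conditional HWE test by full enumeration with exact factorials
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * min(n_AA, n_aa) + n_Aa
  if (n_a == 0) return(1)
  ks <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  w <- vapply(ks, function(k) {
    naa <- (n_a - k) / 2
    nAA <- n - naa - k
    2^k * factorial(n) / (factorial(nAA) * factorial(k) * factorial(naa))
  }, 0)
  prob <- w / sum(w)
  p_obs <- prob[ks == n_Aa]
  sum(prob[prob <= p_obs + 1e-12])
}

# upper-tail hypergeometric by direct combinatorial summation
oracle_hypergeom <- function(k, set_size, n_universe, n_draws) {
  total <- choose(n_universe, n_draws)
  js <- k:min(set_size, n_draws)
  sum(choose(set_size, js) * choose(n_universe - set_size, n_draws - js)) /
    total
}

# path-length distances of a binary tree given as an ape phylo object
oracle_tree_distances <- function(phy) {
  as.matrix(stats::cophenetic(phy))
}

# small deterministic genotype fixture builder
toy_gm <- function(dosage, chrom = "chr1", pos = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  genotype_matrix(
    dosage,
    data.frame(chrom = chrom, pos = pos,
               id = paste0("s", seq_len(m)), ref = "A", alt = "G",
               stringsAsFactors = FALSE),
    paste0("ind", seq_len(nrow(dosage))))
}

small_sim <- function(n_per_pop = 50, n_sites = 2000, fst = 0.3, seed = 11,
                      chrom_lengths = c(chr1 = 10e6), sweeps = NULL,
                      missing = 0.02, hwe_frac = 0) {
  simulate_genotypes(simulation_config(
    n_per_pop = n_per_pop, n_sites = n_sites, chrom_lengths = chrom_lengths,
    divergence_fst = fst, sweep_specs = sweeps, missing_rate = missing,
    hwe_violation_fraction = hwe_frac, seed = seed))
}
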