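test_that("same seed gives bit-identical simulations", {
  a <- small_sim(seed = 42, n_per_pop = 20, n_sites = 500)
  b <- small_sim(seed = 42, n_per_pop = 20, n_sites = 500)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$genotypes$sites, b$genotypes$sites)
  expect_identical(a$truth$pop_freq, b$truth$pop_freq)
  c_ <- small_sim(seed = 43, n_per_pop = 20, n_sites = 500)
  expect_false(identical(a$genotypes$dosage, c_$genotypes$dosage))
})

test_that("near-zero divergence keeps population frequencies at the ancestral value", {
  d <- simulate_genotypes(simulation_config(
    n_per_pop = 50, n_sites = 10000, chrom_lengths = c(chr1 = 50e6),
    divergence_fst = 0.001, sweep_specs = NULL, missing_rate = 0,
    hwe_violation_fraction = 0, seed = 5))
  # truth frequencies hug the ancestral frequency
  expect_lt(mean(abs(d$truth$pop_freq["A", ] - d$truth$ancestral_freq)), 0.02)
  # mean realized per-site differentiation is near zero
  fr <- population_frequencies(d$genotypes, d$popmap)
  fst <- fst_site(fr$A$freq, fr$B$freq)
  expect_lt(mean(fst, na.rm = TRUE), 0.02)
})

test_that("overall missing fraction concentrates at the configured rate", {
  d <- simulate_genotypes(simulation_config(
    n_per_pop = 144, n_sites = 60000, missing_rate = 0.05,
    hwe_violation_fraction = 0, sweep_specs = NULL, seed = 9))
  expect_equal(mean(is.na(d$genotypes$dosage)), 0.05, tolerance = 0.002 / 0.05)
})

test_that("an intensity-1 sweep fixes the swept population and zeroes window pi", {
  sweeps <- data.frame(chrom = "chr1", start = 2e6, end = 3e6,
                       population = "B", intensity = 1.0)
  d <- small_sim(n_per_pop = 40, n_sites = 4000, fst = 0.05, seed = 13,
                 sweeps = sweeps, missing = 0.01)
  in_sweep <- d$genotypes$sites$pos - 1 >= 2e6 & d$genotypes$sites$pos - 1 < 3e6
  expect_gt(sum(in_sweep), 10)
  expect_true(all(d$truth$pop_freq["B", in_sweep] %in% c(0, 1)))
  b_rows <- population_indices(d$genotypes, d$popmap)$B
  pi_b <- pi_site(d$genotypes, b_rows)
  expect_true(all(pi_b[in_sweep] == 0, na.rm = TRUE))
  # in-sweep windows have zero B diversity, below the genome-wide median
  win <- make_windows(c(chr1 = 10e6))
  st <- scan_windows(d$genotypes, d$popmap, win)
  fully_in <- st$start >= 2e6 & st$end <= 3e6
  expect_true(all(st$pi_B[fully_in] == 0))
  expect_lt(max(st$pi_B[fully_in]), stats::median(st$pi_B))
})

test_that("realized divergence increases with the divergence parameter", {
  mean_fst <- vapply(c(0.02, 0.1, 0.3), function(f) {
    d <- simulate_genotypes(simulation_config(
      n_per_pop = 50, n_sites = 10000, chrom_lengths = c(chr1 = 50e6),
      divergence_fst = f, sweep_specs = NULL, missing_rate = 0,
      hwe_violation_fraction = 0, seed = 21))
    fr <- population_frequencies(d$genotypes, d$popmap)
    mean(fst_site(fr$A$freq, fr$B$freq), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(mean_fst) > 0))
})

test_that("HWE violations depress heterozygosity at flagged sites", {
  d <- small_sim(n_per_pop = 100, n_sites = 3000, fst = 0.01, seed = 31,
                 missing = 0, hwe_frac = 0.1)
  viol <- d$truth$hwe_violating_sites
  expect_equal(length(viol), 300L)
  het <- colMeans(d$genotypes$dosage == 1L)
  expect_lt(mean(het[viol]), 0.75 * mean(het[-viol]))
})

test_that("truth files round-trip sweep intervals and tabulate frequencies", {
  sweeps <- data.frame(chrom = "chr1", start = 1e6, end = 1.5e6,
                       population = "B", intensity = 0.9)
  d <- small_sim(n_per_pop = 10, n_sites = 200, seed = 2, sweeps = sweeps)
  prefix <- tempfile()
  paths <- write_truth(d$truth, prefix)
  sw <- read_truth_sweeps(paste0(prefix, "_sweeps.bed"))
  expect_equal(sw$start, 1e6)
  expect_equal(sw$end, 1.5e6)
  expect_equal(sw$population, "B")
  freqs <- read.table(paste0(prefix, "_freqs.tsv"), header = TRUE)
  expect_equal(nrow(freqs), 200L)
  # zero sweeps -> empty BED
  d0 <- small_sim(n_per_pop = 10, n_sites = 50, seed = 2, sweeps = NULL)
  p0 <- tempfile()
  write_truth(d0$truth, p0)
  expect_equal(nrow(read_truth_sweeps(paste0(p0, "_sweeps.bed"))), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(divergence_fst = 0), "divergence_fst")
  expect_error(simulation_config(missing_rate = 1), "missing_rate")
  expect_error(simulation_config(
    sweep_specs = data.frame(chrom = "chr9", start = 0, end = 1e6,
                             population = "B", intensity = 1)),
    "unknown chromosome")
  expect_error(simulation_config(
    sweep_specs = data.frame(chrom = "chr5", start = 0, end = 99e6,
                             population = "B", intensity = 1)),
    "outside chromosome")
})
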