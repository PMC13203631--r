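test_that("site missing rate counts missing calls over all samples", {
  gm <- toy_gm(rbind(c(0L, NA, NA), c(1L, 2L, NA), c(2L, 0L, NA),
                     c(0L, 1L, NA), c(1L, NA, NA),
                     c(2L, 1L, NA), c(0L, 0L, NA), c(1L, 2L, NA),
                     c(2L, 1L, NA), c(0L, 0L, NA)))
  expect_equal(site_missing_rate(gm), c(0, 0.2, 1))
})

test_that("MAF folds to the minor allele and skips missing genotypes", {
  expect_equal(minor_allele_frequency(toy_gm(cbind(c(0L, 0L, 0L, 0L)))), 0)
  expect_equal(minor_allele_frequency(toy_gm(cbind(c(2L, 2L, 2L, 2L)))), 0)
  # alt count 3 over 6 observed alleles
  expect_equal(minor_allele_frequency(toy_gm(cbind(c(0L, 1L, 2L, NA)))), 0.5)
  # invariance to allele swap: dosage g -> 2 - g
  g <- cbind(c(0L, 1L, 1L, 2L, 0L, NA))
  expect_equal(minor_allele_frequency(toy_gm(g)),
               minor_allele_frequency(toy_gm(2L - g)))
})

test_that("HWE exact p-values match hand enumerations", {
  expect_equal(hwe_exact_test(0, 0, 10), 1.0)
  # (1,0,1): conditional outcomes het in {0,2}, P(0)=1/3, P(2)=2/3
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  # the modal outcome (2 hets) collects the whole distribution: p = 1
  expect_equal(hwe_exact_test(0, 2, 0), 1.0, tolerance = 1e-12)
})

test_that("HWE exact test equals full enumeration for every configuration with n <= 10", {
  for (n in 1:10) {
    for (n_AA in 0:n) for (n_Aa in 0:(n - n_AA)) {
      n_aa <- n - n_AA - n_Aa
      expect_equal(hwe_exact_test(n_AA, n_Aa, n_aa),
                   oracle_hwe(n_AA, n_Aa, n_aa),
                   tolerance = 1e-12,
                   label = sprintf("(%d,%d,%d)", n_AA, n_Aa, n_aa))
    }
  }
})

test_that("HWE test is symmetric under allele relabeling", {
  set.seed(1)
  for (i in 1:50) {
    cnt <- as.vector(stats::rmultinom(1, sample(2:60, 1), c(0.3, 0.4, 0.3)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_exact_test(cnt[3], cnt[2], cnt[1]), tolerance = 1e-12)
  }
})

test_that("the conditional heterozygote distribution is a proper distribution", {
  # the modal outcome's p-value must be exactly 1 (all outcomes included);
  # this fails unless the conditional probabilities sum to 1
  for (n in c(2, 5, 10, 17, 25, 34, 50)) {
    for (n_a in unique(pmin(c(1, 3, n %/% 2, n), 2 * n))) {
      ks <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
      ps <- vapply(ks, function(k) {
        naa <- (n_a - k) / 2
        hwe_exact_test(n - naa - k, k, naa)
      }, 0)
      expect_equal(max(ps), 1, tolerance = 1e-12)
      # p-values never exceed 1 anywhere in the support
      expect_true(all(ps <= 1 + 1e-12 & ps > 0))
    }
  }
})

test_that("apply_qc removes one site per filter on a constructed fixture", {
  # 40 samples; 6 sites: 1 fails missingness (25% missing), 1 fails MAF
  # (1/80 alt alleles), 1 fails HWE (all het, exact p ~ 1e-11), 3 clean
  n <- 40L
  clean <- c(rep(0L, 12), rep(1L, 18), rep(2L, 10))  # near-HWE
  miss_site <- c(rep(NA, 10L), clean[11:40])
  maf_site <- c(1L, rep(0L, 39L))
  hwe_site <- rep(1L, n)
  d <- cbind(miss_site, maf_site, hwe_site, clean, rev(clean),
             c(rep(0L, 20), rep(1L, 10), rep(2L, 10)))
  gm <- toy_gm(d)
  res <- apply_qc(gm, thresholds = qc_thresholds())
  expect_equal(res$report$sites_before, 6L)
  expect_equal(res$report$sites_after, 3L)
  expect_equal(unname(res$report$removed), c(1L, 1L, 1L))
  expect_equal(res$report$site_flags,
               c("missing", "maf", "hwe", "pass", "pass", "pass"))
})

test_that("boundary thresholds are vacuous and QC is idempotent", {
  d <- small_sim(n_per_pop = 30, n_sites = 500, seed = 17, missing = 0.05,
                 hwe_frac = 0.05)
  gm <- d$genotypes
  identity_res <- apply_qc(gm, thresholds = qc_thresholds(1.0, 0.0, 0.0))
  expect_equal(identity_res$report$sites_after, n_sites(gm))

  res1 <- apply_qc(gm, d$popmap)
  res2 <- apply_qc(res1$genotypes, d$popmap)
  expect_equal(res2$report$sites_after, res1$report$sites_after)
  expect_identical(res2$genotypes$sites$id, res1$genotypes$sites$id)
})

test_that("an all-missing site is attributed to the missingness filter", {
  gm <- toy_gm(cbind(rep(NA_integer_, 10), c(rep(0L, 3), rep(1L, 4), rep(2L, 3))))
  res <- apply_qc(gm)
  expect_equal(unname(res$report$removed), c(1L, 0L, 0L))
  expect_equal(res$report$site_flags[1], "missing")
})

test_that("per-population HWE mode uses the within-population counts", {
  # strong divergence: merged matrix shows a Wahlund heterozygote deficit,
  # within-population genotypes stay in HWE
  d <- small_sim(n_per_pop = 100, n_sites = 800, fst = 0.35, seed = 23,
                 missing = 0)
  merged <- apply_qc(d$genotypes, d$popmap, hwe_mode = "merged")
  per_pop <- apply_qc(d$genotypes, d$popmap, hwe_mode = "per_population")
  expect_gt(merged$report$removed["hwe"], per_pop$report$removed["hwe"])
})
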