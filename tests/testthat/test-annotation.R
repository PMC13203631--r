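test_that("gene-region overlap respects half-open boundaries and dedups", {
  regions <- data.frame(chrom = c("chr1", "chr1", "chr1"),
                        start = c(150, 200, 400),
                        end = c(300, 300, 500),
                        direction = c("SELECTED_IN_B", "SELECTED_IN_B",
                                      "SELECTED_IN_A"),
                        n_windows = 1L)
  genes <- data.frame(chrom = "chr1",
                      start = c(100, 100, 250, 420),
                      end = c(200, 150, 350, 430),
                      gene_id = c("g_overlap", "g_boundary", "g_span", "g_a"),
                      strand = c("+", "-", "+", "."))
  res <- overlap_genes(regions, genes)
  # [100,200) vs [150,300): overlap; [100,150) vs [150,300): none (half-open)
  expect_true(grepl("g_overlap", res$regions$gene_ids[1]))
  expect_false(grepl("g_boundary", res$regions$gene_ids[1]))
  # a gene spanning two regions of one direction appears once in its list
  expect_equal(sum(res$genes_by_direction$SELECTED_IN_B == "g_span"), 1L)
  expect_equal(res$genes_by_direction$SELECTED_IN_A, "g_a")
})

test_that("regions on unannotated chromosomes warn and get no genes", {
  regions <- data.frame(chrom = "chrZ", start = 0, end = 100,
                        direction = "SELECTED_IN_A", n_windows = 1L)
  genes <- data.frame(chrom = "chr1", start = 0, end = 100,
                      gene_id = "g1", strand = "+")
  expect_warning(res <- overlap_genes(regions, genes), "chrZ")
  expect_equal(res$regions$gene_ids, "")
})

test_that("hypergeometric p-values match closed forms and the counting oracle", {
  universe <- paste0("g", 1:20)
  sets <- list(hit = universe[1:5])
  res <- hypergeometric_enrichment(universe[1:5], sets, universe)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  # zero overlap: P(X >= 0) = 1; single tested set: FDR = p
  res0 <- hypergeometric_enrichment(universe[6:10],
                                    list(s = universe[1:5]), universe)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$fdr, res0$p_value)
  # random small cases against direct combinatorial summation
  set.seed(12)
  for (i in 1:30) {
    n_univ <- sample(10:25, 1)
    univ <- paste0("g", seq_len(n_univ))
    set_size <- sample(2:(n_univ - 2), 1)
    n_draw <- sample(2:(n_univ - 2), 1)
    gset <- sample(univ, set_size)
    cand <- sample(univ, n_draw)
    k <- length(intersect(gset, cand))
    mine <- hypergeometric_enrichment(cand, list(s = gset), univ)$p_value
    expect_equal(mine, oracle_hypergeom(k, set_size, n_univ, n_draw),
                 tolerance = 1e-12)
  }
})

test_that("enrichment validates inputs and sorts by p", {
  expect_error(hypergeometric_enrichment("g1", list(s = "g1"), character(0)),
               "empty")
  expect_error(hypergeometric_enrichment("gX", list(s = "g1"),
                                         paste0("g", 1:5)), "outside")
  universe <- paste0("g", 1:30)
  sets <- list(strong = universe[1:5], weak = universe[21:25])
  res <- hypergeometric_enrichment(universe[1:6], sets, universe)
  expect_equal(res$set_id[1], "strong")
  expect_true(all(diff(res$p_value) >= 0))
  expect_true(all(res$overlap <= pmin(res$set_size, 6)))
})

test_that("BH adjustment reproduces step-up arithmetic", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(4)
  p <- runif(50)^2
  q <- bh_adjust(p)
  # manual step-up recomputation
  o <- order(p)
  m <- length(p)
  qs <- rev(cummin(rev(m * p[o] / seq_len(m))))
  expect_equal(q[o], pmin(qs, 1))
  expect_true(all(diff(sort(q)) >= -1e-15))        # monotone after sorting
  expect_true(all(q >= p - 1e-15 & q <= 1))
  expect_error(bh_adjust(c(0.5, 0)), "p-values")
  expect_error(bh_adjust(c(0.5, 1.2)), "p-values")
})
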