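chrom_sizes_1 <- tibble::tibble(chrom = "chr1", length = 100000)

test_that("tiling sums counts on a fixed half-open grid", {
  calls <- tibble::tibble(
    sample = "s1", chrom = "chr1",
    start = c(10, 490, 500), end = c(11, 491, 501), strand = "+",
    context = "CG", n_meth = c(5, 3, 2), n_total = c(10, 10, 4)
  )
  tiles <- tile_methylation(calls, chrom_sizes_1, tile_size = 500)
  t0 <- dplyr::filter(tiles, start == 0)
  expect_equal(t0$n_meth, 8)
  expect_equal(t0$n_total, 20)
  t1 <- dplyr::filter(tiles, start == 500)  # position 500 is in [500, 1000)
  expect_equal(t1$n_meth, 2)
  expect_equal(nrow(tiles), 2)

  expect_equal(nrow(tile_methylation(calls[0, ], chrom_sizes_1)), 0)
  beyond <- dplyr::mutate(calls, start = 1e6, end = 1e6 + 1)
  expect_error(tile_methylation(beyond, chrom_sizes_1), "beyond")
})

make_tiles <- function(m1, t1, m2, t2, samples1 = "a", samples2 = "b") {
  dplyr::bind_rows(
    tibble::tibble(sample = samples1, chrom = "chr1", start = 0, end = 500,
                   context = "CG", n_meth = m1, n_total = t1),
    tibble::tibble(sample = samples2, chrom = "chr1", start = 0, end = 500,
                   context = "CG", n_meth = m2, n_total = t2)
  )
}

test_that("identical proportions give zero difference and p = 1", {
  tiles <- make_tiles(50, 100, 50, 100)
  res <- diff_methylation(tiles, "a", "b")
  expect_equal(res$meth_diff, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$test, "fisher")
})

test_that("strong hypomethylation is detected with the exact-test fallback", {
  res <- diff_methylation(make_tiles(5, 100, 80, 100), "a", "b")
  expect_equal(res$meth_diff, -75)
  expect_lt(res$p_value, 1e-20)
  # oracle: exact hypergeometric tail enumeration via fisher.test
  oracle <- stats::fisher.test(matrix(c(5, 95, 80, 20), 2, byrow = TRUE))$p.value
  expect_equal(res$p_value, oracle, tolerance = 1e-10)
})

test_that("two-versus-two symmetric groups give zero difference", {
  tiles <- make_tiles(c(10, 10), c(50, 50), c(10, 10), c(50, 50),
                      samples1 = c("a1", "a2"), samples2 = c("b1", "b2"))
  res <- diff_methylation(tiles, c("a1", "a2"), c("b1", "b2"))
  expect_equal(res$meth_diff, 0)
  expect_equal(res$test, "lrt")
  expect_equal(res$p_value, 1)
})

test_that("the closed-form group LRT equals a binomial logistic regression", {
  set.seed(42)
  for (i in 1:25) {
    totals <- rpois(4, 30) + 1                 # per-sample coverages
    meth <- rbinom(4, totals, runif(1, 0.1, 0.9))
    tiles <- tibble::tibble(
      sample = c("t1", "t2", "c1", "c2"), chrom = "chr1", start = 0, end = 500,
      context = "CG", n_meth = meth, n_total = totals
    )
    res <- diff_methylation(tiles, c("t1", "t2"), c("c1", "c2"),
                            min_coverage = 1)
    df <- dplyr::mutate(tiles, group = sample %in% c("t1", "t2"))
    fit1 <- stats::glm(cbind(n_meth, n_total - n_meth) ~ group,
                       family = binomial, data = df)
    fit0 <- stats::glm(cbind(n_meth, n_total - n_meth) ~ 1,
                       family = binomial, data = df)
    p_glm <- stats::pchisq(fit0$deviance - fit1$deviance, 1, lower.tail = FALSE)
    expect_equal(res$p_value, p_glm, tolerance = 1e-8)
  }
})

test_that("low-coverage tiles are excluded as untestable, not errors", {
  tiles <- dplyr::bind_rows(
    make_tiles(5, 100, 80, 100),
    tibble::tibble(sample = c("a", "b"), chrom = "chr1", start = 500,
                   end = 1000, context = "CG", n_meth = c(1, 1),
                   n_total = c(3, 50))
  )
  res <- diff_methylation(tiles, "a", "b", min_coverage = 10)
  expect_equal(nrow(res), 1)
  expect_equal(attr(res, "n_untestable"), 1)
})

test_that("DMR selection respects thresholds and merges book-ended tiles", {
  res <- tibble::tibble(
    chrom = "chr1",
    start = c(1000, 1500, 2500, 4000, 5000),
    end = c(1500, 2000, 3000, 4500, 5500),
    meth_diff = c(-20, -15, -30, -7.9, 25),
    p_value = 1e-8, q_value = c(1e-6, 1e-6, 1e-6, 1e-9, 1e-6)
  )
  dmrs <- call_dmrs(res, diff_threshold = 8, q_threshold = 0.01)
  # book-ended hypo tiles merge; gap starts a new region; |diff| < 8 dropped
  expect_equal(nrow(dmrs), 3)
  merged <- dmrs[dmrs$start == 1000, ]
  expect_equal(merged$end, 2000)
  expect_equal(merged$n_tiles, 2)
  expect_equal(merged$direction, "hypo")
  expect_true(all(dmrs$direction[dmrs$meth_diff > 0] == "hyper"))
  expect_false(any(dmrs$start == 4000))  # -7.9 misses the >= 8 threshold

  # adjacent tiles of opposite direction never merge
  res2 <- tibble::tibble(chrom = "chr1", start = c(0, 500), end = c(500, 1000),
                         meth_diff = c(-20, 20), p_value = 1e-8,
                         q_value = 1e-6)
  expect_equal(nrow(call_dmrs(res2)), 2)
})

test_that("context levels are coverage-weighted with NA for uncovered regions", {
  calls <- tibble::tibble(
    chrom = "chr1", start = c(10, 20, 30), end = c(11, 21, 31), strand = "+",
    context = c("CG", "CG", "CHH"), n_meth = c(3, 1, 10),
    n_total = c(10, 10, 10)
  )
  regions <- region_tbl("chr1", c(0, 5000), c(100, 5100))
  lv <- context_levels(calls, regions, context = "CG")
  expect_equal(lv$level, c(0.2, NA))
  lv_all <- context_levels(calls, regions, context = "all")
  expect_equal(lv_all$level[1], 14 / 30)
  full <- context_levels(dplyr::mutate(calls, n_meth = n_total), regions,
                         context = "all")
  expect_equal(full$level[1], 1)
})

test_that("sliding-window matrix emits the expected window count and levels", {
  # derived count: windows k*step with k*step + window <= len
  cs <- tibble::tibble(chrom = "chrA", length = 100000)
  calls <- tibble::tibble(
    sample = "s1", chrom = "chrA",
    start = seq(0, 99999, by = 100), end = seq(0, 99999, by = 100) + 1,
    strand = "+", context = "CG", n_meth = 5, n_total = 10
  )
  mat <- pca_window_matrix(calls, cs, window = 50000, step = 10000)
  expect_equal(nrow(mat), 6)                # starts 0, 10k, ..., 50k
  expect_equal(mat$start, seq(0, 50000, by = 10000))
  expect_true(all(mat$s1 == 0.5))           # constant methylation
  # a sample with no coverage in a window is NA
  calls2 <- dplyr::bind_rows(
    calls,
    tibble::tibble(sample = "s2", chrom = "chrA", start = 10, end = 11,
                   strand = "+", context = "CG", n_meth = 10, n_total = 10)
  )
  mat2 <- pca_window_matrix(calls2, cs, window = 50000, step = 10000)
  expect_true(is.na(mat2$s2[mat2$start == 50000]))
  expect_equal(mat2$s2[mat2$start == 0], 1)
})

test_that("mutant hypomethylation always yields direction hypo", {
  ann <- simulate_genome(n_chrom = 1, chrom_len = 60000, te_fraction = 0.5,
                         gene_fraction = 0.2, seed = 5)
  te <- ann$tes[which.max(ann$tes$end - ann$tes$start), ]
  pd <- tibble::tibble(chrom = te$chrom,
                       start = ceiling(te$start / 500) * 500,
                       end = floor(te$end / 500) * 500,
                       d_cg = -50, d_chg = -30, d_chh = -12)
  expect_gte(pd$end - pd$start, 500)
  sim <- simulate_methylome(ann, pd, seed = 6)
  tiles <- tile_methylation(sim$calls, ann$chrom_sizes)
  res <- diff_methylation(tiles, c("mut_r1", "mut_r2"), c("WT_r1", "WT_r2"))
  dmrs <- call_dmrs(res)
  expect_gt(nrow(dmrs), 0)
  expect_true(all(dmrs$direction == "hypo"))
})
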