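test_that("genome simulation is deterministic and honours fractions", {
  a1 <- simulate_genome(seed = 42)
  a2 <- simulate_genome(seed = 42)
  expect_identical(a1$tes, a2$tes)
  expect_identical(a1$genes, a2$genes)

  no_te <- simulate_genome(te_fraction = 0, seed = 1)
  expect_equal(nrow(no_te$tes), 0)

  half <- simulate_genome(n_chrom = 1, chrom_len = 1e6, te_fraction = 0.5,
                          gene_fraction = 0.2, seed = 3)
  te_bp <- sum(half$tes$end - half$tes$start)
  expect_lt(abs(te_bp - 5e5) / 5e5, 0.10)
  expect_error(simulate_genome(te_fraction = 0.7, gene_fraction = 0.5),
               "<= 0.95")
  # features never overlap
  feats <- dplyr::arrange(dplyr::bind_rows(half$tes, half$genes,
                                           half$structural_rna), start)
  expect_true(all(feats$start[-1] >= feats$end[-nrow(feats)]))
})

test_that("null methylomes are exchangeable between genotypes", {
  ann <- simulate_genome(n_chrom = 1, chrom_len = 50000, seed = 4)
  sim <- simulate_methylome(ann, planted_dmrs = NULL, seed = 5)
  lv <- sim$calls |>
    dplyr::group_by(genotype) |>
    dplyr::summarise(level = sum(n_meth) / sum(n_total))
  expect_lt(abs(diff(lv$level)), 0.01)
  # coverage 0 yields an empty call table
  empty <- simulate_methylome(ann, coverage_mean = 0, seed = 6)
  expect_equal(nrow(empty$calls), 0)
  # determinism
  s1 <- simulate_methylome(ann, seed = 7)
  s2 <- simulate_methylome(ann, seed = 7)
  expect_identical(s1$calls, s2$calls)
})

test_that("planted methylation deltas are realized within binomial error", {
  ann <- simulate_genome(n_chrom = 1, chrom_len = 100000, te_fraction = 0.6,
                         gene_fraction = 0.1, seed = 9)
  te <- ann$tes[which.max(ann$tes$end - ann$tes$start), ]
  pd <- tibble::tibble(chrom = te$chrom, start = te$start,
                       end = pmin(te$end, te$start + 1000),
                       d_cg = 0, d_chg = 0, d_chh = -10)
  sim <- simulate_methylome(ann, pd, coverage_mean = 20, seed = 11)
  chh <- dplyr::filter(sim$calls, context == "CHH",
                       start >= pd$start, end <= pd$end)
  # >= 100 cytosines expected in 1 kb at 8 bp spacing, 60% CHH
  expect_gte(dplyr::n_distinct(chh$start), 50)
  lv <- chh |>
    dplyr::group_by(genotype) |>
    dplyr::summarise(level = sum(n_meth) / sum(n_total))
  realized <- 100 * (lv$level[lv$genotype == "mut"] -
                       lv$level[lv$genotype == "WT"])
  expect_lt(abs(realized - (-10)), 3)
  # deltas below zero are clipped with a warning
  pd_big <- dplyr::mutate(pd, d_chh = -100)
  expect_warning(simulate_methylome(ann, pd_big, seed = 12), "clipped")
})

test_that("small-RNA simulation enforces the window grid and plants truth", {
  ann <- simulate_genome(seed = 7)
  off <- tibble::tibble(chrom = "chr1", start = 150, end = 350,
                        wt_hna = 40, mut_hna = 10)
  expect_error(simulate_srna_library(ann, off, seed = 1), "off the 200-bp grid")
  pw <- tibble::tibble(chrom = "chr1", start = 1000, end = 1200,
                       wt_hna = 40, mut_hna = 40)
  # equal targets: WT and mutant HNA agree in expectation
  sim <- simulate_srna_library(ann, pw, seed = 2)
  h <- compute_hna(compute_rptm(filter_srna(sim$alignments, ann),
                                srna_totals(sim$alignments)), 10)
  gm <- genotype_hna(window_hna(h, ann$chrom_sizes))
  planted <- dplyr::filter(gm, start == 1000, chrom == "chr1")
  expect_equal(nrow(planted), 2)
  expect_lt(abs(diff(planted$hna)) / mean(planted$hna), 0.5)
  expect_lt(abs(mean(planted$hna) - 40) / 40, 0.3)
  # determinism
  s1 <- simulate_srna_library(ann, pw, seed = 3)
  s2 <- simulate_srna_library(ann, pw, seed = 3)
  expect_identical(s1$alignments, s2$alignments)
  # truth is emitted alongside the data, not re-derived
  expect_identical(s1$truth$planted_windows, pw)
})

test_that("ChIP simulation with zero effect gives near-zero enrichment", {
  cs <- tibble::tibble(chrom = "chr1", length = 1e6)
  regions <- region_tbl("chr1", seq(1e4, 9e4, by = 2e4),
                        seq(1e4, 9e4, by = 2e4) + 1000)
  regions$enrichment <- 0
  sim <- simulate_chip(cs, regions, total_fragments = 1e6, seed = 5)
  out <- region_enrichment(sim$chip, sim$input, regions[, 1:4])
  expect_lt(mean(abs(out$enrichment)), 0.1)
  # zero fragments give empty tracks and zero enrichment by pseudocounts
  sim0 <- simulate_chip(cs, regions, total_fragments = 0, seed = 6)
  expect_equal(nrow(sim0$chip), 0)
  expect_equal(chip_enrichment(0, 1, 0, 1), 0)
})

test_that("ITC simulation is the model plus seeded noise", {
  p <- itc_params(n_stoich = 1, ka = 6.8e5, dh = 0)
  tit <- simulate_itc(p, noise_sd = 0, seed = 1)
  expect_equal(tit$heat, rep(0, 19))   # dh = 0, no noise
  p2 <- itc_params(n_stoich = 1, ka = 6.8e5, dh = -10)
  t1 <- simulate_itc(p2, noise_sd = 0.3, seed = 9)
  t2 <- simulate_itc(p2, noise_sd = 0.3, seed = 9)
  expect_identical(t1$heat, t2$heat)
  mu <- predict_heats(p2, 2e-4, 1e-4, 1.2e-3, rep(2e-6, 19))
  expect_equal(mean(abs(t1$heat - mu)) < 1, TRUE)
  expect_identical(attr(t1, "truth")$ka, 6.8e5)
})
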