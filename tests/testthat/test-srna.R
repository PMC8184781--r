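ann1 <- tiny_annotation()
cs1 <- ann1$chrom_sizes

test_that("length and structural-RNA filters drop the right sequences", {
  seq17 <- strrep("A", 17)
  seq24 <- strrep("AC", 12)
  seq24b <- paste(rep(c("G", "T"), 12), collapse = "")
  recs <- dplyr::bind_rows(
    srna_records(seq17, "lib1", 10, "chr1", 100),            # too short
    srna_records(seq24, "lib1", 20, "chr1", 8050),           # hits rRNA locus
    srna_records(seq24b, "lib1", 30, "chr1", c(100, 400, 900)) # clean, 3 loci
  )
  filt <- filter_srna(recs, ann1)
  expect_setequal(unique(filt$sequence), seq24b)
  expect_equal(nrow(filt), 3)
  expect_equal(attr(filt, "n_dropped_length"), 1)
  expect_equal(attr(filt, "n_dropped_structural"), 1)
  # idempotence (the retained records are unchanged)
  again <- filter_srna(filt, ann1)
  expect_equal(tibble::as_tibble(again), tibble::as_tibble(filt),
               ignore_attr = TRUE)
  expect_equal(attr(again, "n_dropped_structural"), 0)
  # a structural overlap at ANY locus drops the whole sequence
  recs2 <- srna_records(seq24, "lib1", 5, "chr1", c(100, 8050))
  expect_equal(nrow(filter_srna(recs2, ann1)), 0)
})

test_that("RPTM normalizes to reads per ten million of the library total", {
  recs <- dplyr::bind_rows(
    srna_records(strrep("A", 24), "lib1", 150, "chr1", 100),
    srna_records(strrep("C", 24), "lib1", 4999850, "chr1", 200)
  )
  out <- compute_rptm(recs)
  expect_equal(out$rptm[out$read_count == 150], 150 / 5e6 * 1e7)  # 300
  solo <- compute_rptm(srna_records(strrep("G", 24), "l", 42, "chr1", 0))
  expect_equal(solo$rptm, 1e7)  # one sequence is the whole library
  zero <- srna_records(strrep("G", 24), "l", 0, "chr1", 0)
  expect_error(compute_rptm(zero), "zero genome-matched")
})

test_that("HNA divides RPTM equally over capped hits", {
  recs <- srna_records(strrep("AG", 12), "lib1", 30, "chr1",
                       c(100, 400, 900))
  h <- compute_hna(compute_rptm(recs), max_hits = 10)
  expect_equal(unique(h$hits), 3)
  expect_equal(h$hna, rep(1e7 / 3, 3))            # rptm 1e7 over 3 loci
  expect_equal(sum(h$hna), unique(h$rptm))        # conservation
  one <- compute_hna(compute_rptm(
    srna_records(strrep("A", 24), "l", 5, "chr1", 50)), max_hits = 10)
  expect_equal(one$hna, one$rptm)                 # hits = 1 keeps full RPTM
  # the cap drops loci beyond max_hits and divides by the cap
  capped <- compute_hna(compute_rptm(
    srna_records(strrep("C", 24), "l", 5, "chr1", c(0, 300, 600, 900))),
    max_hits = 2)
  expect_equal(nrow(capped), 2)
  expect_equal(unique(capped$hits), 2)
  expect_equal(capped$hna, rep(unique(capped$rptm) / 2, 2))
})

test_that("window assignment is half-open on the 5' start coordinate", {
  recs <- dplyr::bind_rows(
    srna_records(strrep("A", 24), "lib1", 10, "chr1", 199),
    srna_records(strrep("C", 24), "lib1", 10, "chr1", 200),
    srna_records(strrep("G", 24), "lib1", 10, "chr1", 210)
  )
  w <- window_hna(compute_hna(compute_rptm(recs), 10), cs1, window = 200)
  expect_equal(w$start, c(0, 200))
  expect_equal(w$hna[w$start == 200], sum(w$hna) * 2 / 3)  # two loci there
  # minus-strand locus is assigned by its 5' end (right edge)
  minus <- srna_records(strrep("T", 24), "lib1", 10, "chr1", 190, strand = "-")
  wm <- window_hna(compute_hna(compute_rptm(minus), 10), cs1, window = 200)
  expect_equal(wm$start, 200)  # 5' end at 213
})

test_that("window HNA sums to retained RPTM when hits are uncapped", {
  set.seed(99)
  n <- 400
  seqs <- vapply(1:n, function(i) paste(
    sample(c("A", "C", "G", "T"), 24, replace = TRUE), collapse = ""),
    character(1))
  recs <- purrr::map_dfr(seq_len(n), function(i) {
    h <- sample(1:6, 1)
    srna_records(seqs[i], "lib1", sample(1:100, 1), "chr1",
                 sort(sample(0:9000, h)))
  })
  recs <- dplyr::distinct(recs, library, sequence, chrom, start,
                          .keep_all = TRUE)
  h <- compute_hna(compute_rptm(recs), max_hits = Inf)
  w <- window_hna(h, cs1, window = 200)
  rptm_total <- sum(dplyr::distinct(h, sequence, rptm)$rptm)
  expect_equal(sum(w$hna), rptm_total, tolerance = 1e-12)
  expect_true(all(w$hna24 <= w$hna + 1e-12))
})

test_that("depleted-region calling applies the sum cutoff and fold rule", {
  mkw <- function(hna) tibble::tibble(
    chrom = "chr1", start = seq(0, by = 200, length.out = length(hna)),
    end = start + 200, hna = hna, hna24 = hna
  )
  wt <- mkw(c(40, 13, 30, 0, 25))
  mut <- mkw(c(10, 10, 20, 0, 0))
  dep <- call_depleted_regions(wt, mut)
  expect_equal(dep$start, c(0, 800))        # 40/10 and 25/0 pass
  expect_equal(dep$fold_reduction, c(4, Inf))
  # missing windows in one genotype count as zero
  dep2 <- call_depleted_regions(mkw(c(40, 40)), mkw(10)[1, ])
  expect_equal(nrow(dep2), 2)
  expect_equal(dep2$mut_hna, c(10, 0))
})

test_that("raising mutant HNA never turns a non-depleted window depleted", {
  set.seed(7)
  wt_vals <- runif(500, 0, 60)
  mut_vals <- runif(500, 0, 60)
  mkw <- function(hna) tibble::tibble(
    chrom = "chr1", start = seq(0, by = 200, length.out = length(hna)),
    end = start + 200, hna = hna, hna24 = hna
  )
  base <- call_depleted_regions(mkw(wt_vals), mkw(mut_vals))
  bumped <- call_depleted_regions(mkw(wt_vals), mkw(mut_vals + runif(500, 0, 20)))
  expect_true(all(bumped$start %in% base$start))
})

test_that("region abundance sums windows by midpoint with zero fallback", {
  w <- tibble::tibble(chrom = "chr1", start = c(0, 200, 400),
                      end = c(200, 400, 600), hna = c(10, 20, 5),
                      hna24 = c(8, 15, 5))
  regions <- region_tbl("chr1", c(0, 350, 5000), c(400, 600, 5200))
  ab <- region_abundance(w, regions, size_filter = "all")
  expect_equal(ab$abundance, c(30, 5, 0))
  ab24 <- region_abundance(w, regions, size_filter = "24nt")
  expect_equal(ab24$abundance, c(23, 5, 0))
  # a region equal to one window returns that window's value
  one <- region_abundance(w, region_tbl("chr1", 200, 400), "all")
  expect_equal(one$abundance, 20)
})

test_that("planted depleted windows are recovered through the full pipeline", {
  ann <- simulate_genome(seed = 7)
  pw <- tibble::tibble(chrom = "chr1", start = seq(1000, 40800, by = 2000))
  pw$end <- pw$start + 200
  pw$wt_hna <- 40
  pw$mut_hna <- 10
  sim <- simulate_srna_library(ann, pw, seed = 3)
  totals <- srna_totals(sim$alignments)
  filt <- filter_srna(sim$alignments, ann)
  h <- compute_hna(compute_rptm(filt, totals), max_hits = 10)
  gm <- genotype_hna(window_hna(h, ann$chrom_sizes))
  dep <- call_depleted_regions(dplyr::filter(gm, genotype == "WT"),
                               dplyr::filter(gm, genotype == "mut"))
  hit <- dplyr::inner_join(dep, pw, by = c("chrom", "start", "end"))
  expect_gte(nrow(hit) / nrow(pw), 0.95)              # sensitivity
  expect_lte(nrow(dep) - nrow(hit), 0.05 * nrow(dep)) # false windows
  # recovered window HNAs are close to targets
  expect_lt(median(abs(hit$wt_hna.x - 40) / 40), 0.15)
  expect_lt(median(abs(hit$mut_hna.x - 10) / 10), 0.2)
})

test_that("simulated sequences repeat their string once per locus", {
  ann <- simulate_genome(seed = 2)
  sim <- simulate_srna_library(ann, n_families = 50, seed = 4, n_decoys = 0,
                               multimap_profile = c(0, 0, 0, 1))  # 4 loci each
  lib1 <- dplyr::filter(sim$alignments, library == "WT_r1")
  per_seq <- dplyr::count(dplyr::distinct(lib1, sequence, chrom, start),
                          sequence)
  expect_true(all(per_seq$n == 4))
})
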