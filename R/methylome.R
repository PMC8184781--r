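#' Summarise methylation calls over fixed tiling windows
#'
#' Sums methylated and total read counts per sample, per context, over a
#' fixed genome-wide grid of `tile_size`-bp windows
#' (`[k * tile_size, (k + 1) * tile_size)`; the last tile of a chromosome
#' may be shorter). Tiles with no covered cytosine are omitted.
#'
#' @param calls Tibble of per-cytosine calls (`sample`, `chrom`, `start`,
#'   `end`, `context`, `n_meth`, `n_total`); a missing `sample` column is
#'   treated as a single sample.
#' @param chrom_sizes Tibble with `chrom`, `length`.
#' @param tile_size Window size in bp (default 500).
#' @return A tibble with one row per (sample, tile, context):
#'   `sample`, `chrom`, `start`, `end`, `context`, `n_meth`, `n_total`.
#' @export
tile_methylation <- function(calls, chrom_sizes, tile_size = 500) {
  calls <- ensure_sample(calls)
  validate_regions(calls, "calls")
  sizes <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  unknown <- setdiff(unique(calls$chrom), names(sizes))
  if (length(unknown) > 0) {
    abort(sprintf("calls on chromosome '%s' absent from chrom_sizes", unknown[1]))
  }
  if (any(calls$end > sizes[calls$chrom])) {
    abort("a call lies beyond its chromosome end")
  }
  calls |>
    mutate(tile = floor(.data$start / tile_size)) |>
    group_by(.data$sample, .data$chrom, .data$tile, .data$context) |>
    summarise(n_meth = sum(.data$n_meth), n_total = sum(.data$n_total),
              .groups = "drop") |>
    mutate(start = .data$tile * tile_size,
           end = pmin(.data$start + tile_size, sizes[.data$chrom])) |>
    select("sample", "chrom", "start", "end", "context", "n_meth", "n_total") |>
    arrange(.data$sample, .data$chrom, .data$start, .data$context)
}

ensure_sample <- function(calls) {
  if (!"sample" %in% names(calls)) calls <- mutate(calls, sample = "sample1")
  calls
}

# Two-sided Fisher exact p for 2x2 tables (m1,u1 | m2,u2), by enumeration of
# the conditional hypergeometric distribution: sum of all outcome
# probabilities <= observed (with the customary 1e-7 relative tolerance).
fisher_p_2x2 <- function(m1, u1, m2, u2) {
  pmap_dbl <- function(...) purrr::pmap_dbl(...)
  pmap_dbl(list(m1, u1, m2, u2), function(a, b, c, d) {
    m <- a + b          # row 1 total (treatment reads)
    k <- a + c          # methylated column total
    n <- c + d
    lo <- max(0, k - n)
    hi <- min(k, m)
    probs <- dhyper(lo:hi, m, n, k)
    p_obs <- dhyper(a, m, n, k)
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  })
}

# G-statistic (likelihood-ratio) for a pooled 2x2 table. With grouped
# binomial counts and a single group covariate, the logistic-regression LRT
# reduces exactly to this statistic: the per-group MLEs are the pooled
# proportions, so per-sample terms collapse into group sums.
g_stat_2x2 <- function(m1, u1, m2, u2) {
  t1 <- m1 + u1
  t2 <- m2 + u2
  p1 <- m1 / t1
  p2 <- m2 / t2
  p0 <- (m1 + m2) / (t1 + t2)
  xlog <- function(obs, p) ifelse(obs > 0, obs * log(p), 0)
  ll_alt <- xlog(m1, p1) + xlog(u1, 1 - p1) + xlog(m2, p2) + xlog(u2, 1 - p2)
  ll_null <- xlog(m1 + m2, p0) + xlog(u1 + u2, 1 - p0)
  pmax(0, 2 * (ll_alt - ll_null))
}

#' Tiling-window differential methylation test
#'
#' Tests each tile for a methylation difference between a treatment group
#' (e.g. pooled mutant replicates) and a control group. The test is a
#' likelihood-ratio test of a binomial logistic regression of methylation
#' on group membership over the per-sample counts; because the model's
#' group-wise maximum-likelihood fits are the pooled proportions, the
#' statistic is computed in closed form from the pooled 2x2 table. When
#' either group has a single sample the test falls back to Fisher's exact
#' test on the same table. `meth_diff` is
#' `100 * (pooled treatment proportion - pooled control proportion)`, so
#' mutant hypomethylation is negative. Tiles whose pooled coverage in
#' either group is below `min_coverage` are untestable and excluded;
#' q-values are Benjamini-Hochberg over the tested tiles.
#'
#' @param tiles Output of [tile_methylation()] covering all samples.
#' @param treatment,control Character vectors of sample names.
#' @param min_coverage Minimum pooled reads per group (default 10).
#' @return A tibble with one row per testable tile: `chrom`, `start`, `end`,
#'   `cov_treatment`, `cov_control`, `meth_treatment`, `meth_control`,
#'   `meth_diff` (pp), `p_value`, `q_value`, `test` (`"lrt"` or `"fisher"`).
#'   The number of untestable tiles is stored in attribute `n_untestable`.
#' @export
diff_methylation <- function(tiles, treatment, control, min_coverage = 10) {
  if (length(intersect(treatment, control)) > 0) {
    abort("treatment and control sample sets overlap")
  }
  missing_samples <- setdiff(c(treatment, control), unique(tiles$sample))
  if (length(missing_samples) > 0) {
    abort(sprintf("sample(s) not present in tiles: %s",
                  paste(missing_samples, collapse = ", ")))
  }
  grouped <- tiles |>
    filter(.data$sample %in% c(treatment, control)) |>
    mutate(group = if_else(.data$sample %in% treatment, "treatment", "control")) |>
    group_by(.data$chrom, .data$start, .data$end, .data$group) |>
    summarise(n_meth = sum(.data$n_meth), n_total = sum(.data$n_total),
              .groups = "drop") |>
    pivot_wider(names_from = "group", values_from = c("n_meth", "n_total"),
                values_fill = 0)
  for (col in c("n_meth_treatment", "n_total_treatment",
                "n_meth_control", "n_total_control")) {
    if (!col %in% names(grouped)) grouped[[col]] <- 0
  }
  testable <- grouped$n_total_treatment >= min_coverage &
    grouped$n_total_control >= min_coverage
  n_untestable <- sum(!testable)
  res <- grouped[testable, , drop = FALSE]
  m1 <- res$n_meth_treatment
  u1 <- res$n_total_treatment - m1
  m2 <- res$n_meth_control
  u2 <- res$n_total_control - m2
  use_fisher <- length(treatment) == 1 || length(control) == 1
  if (use_fisher) {
    p <- fisher_p_2x2(m1, u1, m2, u2)
    test <- "fisher"
  } else {
    g <- g_stat_2x2(m1, u1, m2, u2)
    p <- pchisq(g, df = 1, lower.tail = FALSE)
    # a degenerate regression (one group without coverage) cannot reach here
    # because of the coverage filter; identical pooled proportions give g = 0
    test <- "lrt"
  }
  out <- tibble(
    chrom = res$chrom, start = res$start, end = res$end,
    cov_treatment = res$n_total_treatment,
    cov_control = res$n_total_control,
    meth_treatment = m1 / res$n_total_treatment,
    meth_control = m2 / res$n_total_control,
    meth_diff = 100 * (m1 / res$n_total_treatment - m2 / res$n_total_control),
    p_value = p,
    q_value = p.adjust(p, method = "BH"),
    test = test
  ) |>
    arrange(.data$chrom, .data$start)
  attr(out, "n_untestable") <- n_untestable
  out
}

#' Select significant tiles and merge them into DMRs
#'
#' Keeps tiles with `|meth_diff| >= diff_threshold` and
#' `q_value < q_threshold`, then merges overlapping or book-ended kept
#' tiles of the same direction into differentially methylated regions.
#' Adjacent tiles of opposite direction are never merged. A region is
#' `hypo` iff its tiles' `meth_diff < 0` (lower methylation in treatment).
#'
#' @param results Output of [diff_methylation()].
#' @param diff_threshold Minimum |methylation difference| in pp (default 8).
#' @param q_threshold q-value cutoff (default 0.01).
#' @return A tibble of DMRs: `chrom`, `start`, `end`, `direction`
#'   (`"hypo"`/`"hyper"`), `meth_diff` (mean over tiles), `q_value`
#'   (minimum over tiles), `n_tiles`.
#' @export
call_dmrs <- function(results, diff_threshold = 8, q_threshold = 0.01) {
  kept <- results |>
    filter(abs(.data$meth_diff) >= diff_threshold,
           .data$q_value < q_threshold) |>
    mutate(direction = if_else(.data$meth_diff < 0, "hypo", "hyper")) |>
    arrange(.data$chrom, .data$direction, .data$start)
  if (nrow(kept) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  direction = character(), meth_diff = numeric(),
                  q_value = numeric(), n_tiles = integer()))
  }
  kept |>
    group_by(.data$chrom, .data$direction) |>
    mutate(new_run = .data$start > lag(.data$end, default = -1),
           run = cumsum(.data$new_run)) |>
    group_by(.data$chrom, .data$direction, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              meth_diff = mean(.data$meth_diff),
              q_value = min(.data$q_value),
              n_tiles = n(), .groups = "drop") |>
    select("chrom", "start", "end", "direction", "meth_diff", "q_value",
           "n_tiles") |>
    arrange(.data$chrom, .data$start)
}

#' Per-region methylation level in a sequence context
#'
#' The level of a region is `sum(n_meth) / sum(n_total)` over the cytosines
#' of the requested context that fall inside it. Regions without any
#' covered cytosine get `NA` (flagged undefined, never 0).
#'
#' @param calls Per-cytosine calls (single sample or pre-pooled).
#' @param regions Region tibble.
#' @param context `"CG"`, `"CHG"`, `"CHH"`, or `"all"` for every context.
#' @return `regions` with columns `level` and `n_total` appended.
#' @export
context_levels <- function(calls, regions, context = "all") {
  stopifnot(context %in% c("CG", "CHG", "CHH", "all"))
  validate_regions(regions, "regions")
  if (context != "all") calls <- filter(calls, .data$context == !!context)
  regions <- mutate(as_tibble(regions), .region_id = row_number())
  acc <- tibble(.region_id = integer(), n_meth = numeric(), n_total = numeric())
  if (nrow(calls) > 0 && nrow(regions) > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges(calls), as_granges(regions),
                                        ignore.strand = TRUE)
    acc <- tibble(
      .region_id = S4Vectors::subjectHits(hits),
      n_meth = calls$n_meth[S4Vectors::queryHits(hits)],
      n_total = calls$n_total[S4Vectors::queryHits(hits)]
    ) |>
      group_by(.data$.region_id) |>
      summarise(n_meth = sum(.data$n_meth), n_total = sum(.data$n_total),
                .groups = "drop")
  }
  regions |>
    left_join(acc, by = ".region_id") |>
    mutate(level = if_else(!is.na(.data$n_total) & .data$n_total > 0,
                           .data$n_meth / .data$n_total, NA_real_),
           n_total = replace_na(.data$n_total, 0)) |>
    select(-".region_id", -"n_meth")
}

#' Sliding-window methylation matrix for PCA
#'
#' Computes the all-context methylation level of every sample in sliding
#' windows `[k * step, k * step + window)` (only full-length windows are
#' emitted). Windows with no coverage in a sample are `NA` and should be
#' dropped (or complete-case filtered) before the decomposition, which is
#' left to standard tools (`prcomp`).
#'
#' @param calls Per-cytosine calls with a `sample` column.
#' @param chrom_sizes Tibble with `chrom`, `length`.
#' @param window Window size in bp (default 50000).
#' @param step Step size in bp (default 10000).
#' @return A wide tibble: `chrom`, `start`, `end`, then one level column
#'   per sample.
#' @export
pca_window_matrix <- function(calls, chrom_sizes, window = 50000, step = 10000) {
  calls <- ensure_sample(calls)
  n_shifts <- ceiling(window / step)
  sizes <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  per_shift <- map_dfr(seq_len(n_shifts) - 1, function(j) {
    calls |>
      mutate(k = floor((.data$start - j * step) / window)) |>
      filter(.data$k >= 0) |>
      mutate(wstart = .data$k * window + j * step) |>
      group_by(.data$sample, .data$chrom, .data$wstart) |>
      summarise(n_meth = sum(.data$n_meth), n_total = sum(.data$n_total),
                .groups = "drop")
  })
  grid <- map_dfr(seq_len(nrow(chrom_sizes)), function(i) {
    len <- chrom_sizes$length[i]
    starts <- seq(0, len, by = step)
    starts <- starts[starts + window <= len]
    tibble(chrom = chrom_sizes$chrom[i], wstart = starts)
  })
  grid |>
    left_join(per_shift, by = c("chrom", "wstart")) |>
    mutate(level = if_else(!is.na(.data$n_total) & .data$n_total > 0,
                           .data$n_meth / .data$n_total, NA_real_)) |>
    filter(!is.na(.data$sample)) |>
    select("sample", "chrom", "wstart", "level") |>
    tidyr::complete(sample = unique(calls$sample),
                    tidyr::nesting(chrom = grid$chrom, wstart = grid$wstart)) |>
    pivot_wider(names_from = "sample", values_from = "level") |>
    mutate(start = .data$wstart, end = .data$wstart + window, .after = "chrom") |>
    select(-"wstart") |>
    arrange(.data$chrom, .data$start)
}
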