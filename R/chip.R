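#' Count fragments overlapping regions
#'
#' A fragment (paired-end template interval) increments every region it
#' overlaps by at least 1 bp, and at most once per region — the semantics
#' of counting with multi-overlap allowed. Fragments are expected to be
#' deduplicated, uniquely-mapped template intervals.
#'
#' @param fragments Region tibble of fragment intervals.
#' @param regions Region tibble.
#' @return `regions` with an `n_fragments` column.
#' @export
count_fragments <- function(fragments, regions) {
  bad <- which(fragments$end <= fragments$start | fragments$start < 0)
  if (length(bad) > 0) {
    abort(sprintf("malformed fragment interval at record %d", bad[1]))
  }
  validate_regions(regions, "regions")
  n <- GenomicRanges::countOverlaps(as_granges(regions), as_granges(fragments),
                                    ignore.strand = TRUE)
  mutate(as_tibble(regions), n_fragments = as.numeric(n))
}

#' Input-normalized log2 ChIP enrichment
#'
#' `log2((1 + n_chip) / N_chip) - log2((1 + n_input) / N_input)`, where
#' `n` counts fragments in the region and `N` is the total number of
#' mapped unique fragments of the track. The pseudocount keeps the value
#' finite at zero counts and cancels exactly when both tracks agree.
#'
#' @param n_chip,n_input Region fragment counts (vectorized).
#' @param N_chip,N_input Track library sizes (total unique fragments).
#' @return log2 enrichment values.
#' @examples
#' chip_enrichment(99, 1e6, 24, 1e6)  # log2(100/25) = 2
#' @export
chip_enrichment <- function(n_chip, N_chip, n_input, N_input) {
  if (any(N_chip <= 0) || any(N_input <= 0)) {
    abort("library sizes N_chip and N_input must be positive")
  }
  log2((1 + n_chip) / N_chip) - log2((1 + n_input) / N_input)
}

#' Per-region ChIP enrichment from fragment tracks
#'
#' Convenience wrapper: counts ChIP and input fragments per region and
#' applies [chip_enrichment()]. Library sizes default to the total number
#' of fragments supplied per track.
#'
#' @param chip,input Fragment region tibbles.
#' @param regions Region tibble.
#' @param N_chip,N_input Library sizes; default `nrow(chip)`, `nrow(input)`.
#' @return `regions` with `n_chip`, `n_input`, `enrichment` columns.
#' @export
region_enrichment <- function(chip, input, regions,
                              N_chip = nrow(chip), N_input = nrow(input)) {
  out <- count_fragments(chip, regions) |> rename(n_chip = "n_fragments")
  out$n_input <- count_fragments(input, regions)$n_fragments
  mutate(out, enrichment = chip_enrichment(.data$n_chip, N_chip,
                                           .data$n_input, N_input))
}

#' Enrichment profile over regions ranked by siRNA change
#'
#' Orders regions by decreasing siRNA change (`delta`, typically WT minus
#' mutant 24-nt HNA, so the most factor-dependent regions come first),
#' smooths the enrichment with a centred rolling mean of `smoothing_k`
#' regions, and reports the Spearman rank correlation between the change
#' and the enrichment.
#'
#' @param regions Tibble with columns `delta` and `enrichment` (e.g. from
#'   [region_enrichment()] joined with [region_abundance()] differences).
#' @param smoothing_k Rolling-mean width in regions (default 50). When
#'   fewer regions than `smoothing_k` are supplied, smoothing is skipped
#'   with a warning.
#' @return An object of class `ranked_profile`: list with `profile`
#'   (tibble `rank`, `delta`, `enrichment`, `enrichment_smooth`),
#'   `spearman_rho`, and `smoothing_k`.
#' @export
ranked_profile <- function(regions, smoothing_k = 50) {
  if (!all(c("delta", "enrichment") %in% names(regions))) {
    abort("regions must carry columns delta and enrichment")
  }
  prof <- regions |>
    arrange(dplyr::desc(.data$delta)) |>
    mutate(rank = row_number())
  if (nrow(prof) < smoothing_k) {
    warn("fewer regions than smoothing_k; smoothing skipped")
    prof$enrichment_smooth <- prof$enrichment
  } else {
    prof$enrichment_smooth <- as.numeric(
      stats::filter(prof$enrichment, rep(1 / smoothing_k, smoothing_k),
                    sides = 2)
    )
  }
  rho <- suppressWarnings(
    cor(prof$delta, prof$enrichment, method = "spearman")
  )
  if (is.na(rho)) rho <- 0  # all-tied input has no rank signal
  structure(
    list(profile = select(prof, "rank", "delta", "enrichment",
                          "enrichment_smooth"),
         spearman_rho = rho,
         smoothing_k = smoothing_k),
    class = "ranked_profile"
  )
}

#' @export
print.ranked_profile <- function(x, ...) {
  cat(sprintf("<ranked_profile> %d regions, smoothing_k = %d\n",
              nrow(x$profile), x$smoothing_k))
  cat(sprintf("  Spearman rho(delta, enrichment) = %.3f\n", x$spearman_rho))
  invisible(x)
}

#' Metagene enrichment profile around genes
#'
#' Scales every gene body to `n_body_bins` equal bins and adds fixed-width
#' flank bins (`flank_bp` split into `flank_bp / flank_bin` bins on each
#' side). Minus-strand genes are reversed so bins run 5' to 3'. ChIP and
#' input fragments are counted per bin, pooled over genes, and converted
#' to log2 enrichment with [chip_enrichment()].
#'
#' @param chip,input Fragment region tibbles.
#' @param genes Stranded gene region tibble.
#' @param n_body_bins Number of gene-body bins (default 40).
#' @param flank_bp Flank width in bp (default 2000).
#' @param flank_bin Flank bin width in bp (default 100).
#' @param N_chip,N_input Library sizes; default the track totals.
#' @return An object of class `metagene_profile`: tibble `bin`, `zone`
#'   (`upstream`/`body`/`downstream`), `n_chip`, `n_input`, `enrichment`.
#' @export
metagene_profile <- function(chip, input, genes, n_body_bins = 40,
                             flank_bp = 2000, flank_bin = 100,
                             N_chip = nrow(chip), N_input = nrow(input)) {
  validate_regions(genes, "genes")
  n_flank <- as.integer(round(flank_bp / flank_bin))
  bins <- imap_dfr(seq_len(nrow(genes)), function(i, ...) {
    g <- genes[i, ]
    up <- tibble(start = g$start - flank_bp + (seq_len(n_flank) - 1) * flank_bin)
    up$end <- up$start + flank_bin
    body_edges <- round(seq(g$start, g$end, length.out = n_body_bins + 1))
    body <- tibble(start = body_edges[-(n_body_bins + 1)],
                   end = body_edges[-1])
    down <- tibble(start = g$end + (seq_len(n_flank) - 1) * flank_bin)
    down$end <- down$start + flank_bin
    out <- bind_rows(up, body, down)
    out$zone <- c(rep("upstream", n_flank), rep("body", n_body_bins),
                  rep("downstream", n_flank))
    out$bin <- seq_len(nrow(out))
    minus <- identical(g$strand, "-")
    if (minus) {
      out$bin <- rev(out$bin)
      out$zone <- rev(out$zone)
    }
    out$chrom <- g$chrom
    filter(out, .data$start >= 0, .data$end > .data$start)
  })
  count_in_bins <- function(frags) {
    hits <- GenomicRanges::countOverlaps(as_granges(bins), as_granges(frags),
                                         ignore.strand = TRUE)
    tibble(bin = bins$bin, zone = bins$zone, n = hits) |>
      group_by(.data$bin, .data$zone) |>
      summarise(n = sum(.data$n), .groups = "drop")
  }
  prof <- count_in_bins(chip) |>
    rename(n_chip = "n") |>
    left_join(rename(count_in_bins(input), n_input = "n"),
              by = c("bin", "zone")) |>
    mutate(enrichment = chip_enrichment(.data$n_chip, N_chip,
                                        .data$n_input, N_input)) |>
    arrange(.data$bin)
  class(prof) <- c("metagene_profile", class(prof))
  prof
}
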