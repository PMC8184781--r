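round_half_up <- function(x) floor(x + 0.5)

#' Overlap statistics between two region sets
#'
#' Counts the members of A that overlap (by at least 1 bp) at least one
#' member of B, each A member counted once, and reports the percentage
#' rounded half-up to an integer. The relation is directional:
#' `overlap_stats(a, b)` and `overlap_stats(b, a)` generally differ.
#'
#' @param a,b Region tibbles.
#' @return One-row tibble: `n_a`, `n_b`, `n_a_overlapping`, `percent`.
#' @examples
#' a <- region_tbl("chr1", c(0, 1000), c(500, 1500))
#' b <- region_tbl("chr1", 400, 600)
#' overlap_stats(a, b)  # 1 of 2, 50%
#' @export
overlap_stats <- function(a, b) {
  validate_regions(a, "a")
  validate_regions(b, "b")
  n_over <- sum(overlaps_any(a, b))
  tibble(
    n_a = nrow(a), n_b = nrow(b), n_a_overlapping = n_over,
    percent = if (nrow(a) > 0) round_half_up(100 * n_over / nrow(a)) else NA_real_
  )
}

#' Genomic feature composition of a region set
#'
#' Assigns each region exactly one label by overlap (>= 1 bp) with the
#' annotation tracks, using the precedence TE > gene > intergenic (a
#' region inside a TE that also touches a gene counts as TE). Fractions
#' sum to 1.
#'
#' @param regions Region tibble.
#' @param annotation A [genome_annotation()].
#' @param precedence Track order tried first to last (default
#'   `c("te", "gene")`; anything unmatched is intergenic).
#' @return Tibble `category`, `n`, `fraction`, with a `labels` attribute
#'   holding the per-region assignment.
#' @export
feature_composition <- function(regions, annotation,
                                precedence = c("te", "gene")) {
  validate_regions(regions, "regions")
  track_of <- c(te = "tes", gene = "genes")
  labels <- rep("intergenic", nrow(regions))
  unassigned <- rep(TRUE, nrow(regions))
  for (cat in precedence) {
    hit <- overlaps_any(regions, annotation[[track_of[[cat]]]])
    labels[unassigned & hit] <- cat
    unassigned <- unassigned & !hit
  }
  out <- tibble(category = factor(labels,
                                  levels = c(precedence, "intergenic"))) |>
    count(.data$category, .drop = FALSE, name = "n") |>
    mutate(category = as.character(.data$category),
           fraction = if (nrow(regions) > 0) .data$n / nrow(regions) else NA_real_)
  attr(out, "labels") <- labels
  out
}

#' Per-region methylation change between genotypes
#'
#' For each region, the methylation level difference
#' `level(mutant) - level(WT)` in the requested context, via
#' [context_levels()]. Regions without coverage in either genotype get
#' `NA`.
#'
#' @param calls_wt,calls_mut Per-cytosine call tibbles (replicates pooled
#'   or concatenated; levels are computed on summed counts).
#' @param regions Region tibble.
#' @param context `"CG"`, `"CHG"`, `"CHH"` or `"all"`.
#' @return `regions` with `level_wt`, `level_mut`, `delta_meth` columns.
#' @export
region_methylation_delta <- function(calls_wt, calls_mut, regions,
                                     context = "all") {
  wt <- context_levels(calls_wt, regions, context)
  mut <- context_levels(calls_mut, regions, context)
  regions |>
    as_tibble() |>
    mutate(level_wt = wt$level, level_mut = mut$level,
           delta_meth = .data$level_mut - .data$level_wt)
}

#' Per-region 24-nt siRNA change between genotypes
#'
#' `abundance(mutant) - abundance(WT)` of 24-nt HNA summed over the
#' windows of each region (see [region_abundance()]); negative values mean
#' siRNA loss in the mutant.
#'
#' @param wt_windows,mut_windows Genotype-mean window tibbles.
#' @param regions Region tibble.
#' @param size_filter `"24nt"` (default) or `"all"`.
#' @return `regions` with `abundance_wt`, `abundance_mut`, `delta_sirna`.
#' @export
region_sirna_delta <- function(wt_windows, mut_windows, regions,
                               size_filter = "24nt") {
  wt <- region_abundance(select(wt_windows, -any_of(c("library", "genotype"))),
                         regions, size_filter)
  mut <- region_abundance(select(mut_windows, -any_of(c("library", "genotype"))),
                          regions, size_filter)
  regions |>
    as_tibble() |>
    mutate(abundance_wt = wt$abundance, abundance_mut = mut$abundance,
           delta_sirna = .data$abundance_mut - .data$abundance_wt)
}
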