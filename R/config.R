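#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis chain in one list, with
#' the defaults used throughout the package. Sizes are in bp, `diff_threshold`
#' in percentage points of methylation, `rptm_scale` is the reads-per-ten-million
#' normalization constant.
#'
#' @param tile_size Bisulfite tiling-window size (bp).
#' @param srna_window Small-RNA quantification window size (bp).
#' @param diff_threshold Minimum absolute methylation difference (pp) for a
#'   tile to enter a DMR.
#' @param q_threshold BH-adjusted significance cutoff for DMR tiles.
#' @param hna_sum_cutoff Minimum WT + mutant window HNA for depletion calling.
#' @param depletion_fold Minimum WT/mutant HNA fold reduction.
#' @param srna_min_len,srna_max_len Retained small-RNA length range (nt).
#' @param max_hits Cap on genomic loci per small-RNA sequence (the aligner's
#'   `-k` limit); loci beyond the cap are dropped.
#' @param pca_window,pca_step Sliding-window size and step for the
#'   methylation PCA matrix (bp).
#' @param rptm_scale Library-size normalization constant (reads per ten million).
#' @param min_coverage Minimum pooled per-group read coverage for a tile to
#'   be testable.
#' @param seed Integer seed recorded with the configuration.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(tile_size = 500,
                            srna_window = 200,
                            diff_threshold = 8,
                            q_threshold = 0.01,
                            hna_sum_cutoff = 25,
                            depletion_fold = 2,
                            srna_min_len = 18,
                            srna_max_len = 31,
                            max_hits = 10,
                            pca_window = 50000,
                            pca_step = 10000,
                            rptm_scale = 1e7,
                            min_coverage = 10,
                            seed = 1L) {
  cfg <- list(
    tile_size = tile_size, srna_window = srna_window,
    diff_threshold = diff_threshold, q_threshold = q_threshold,
    hna_sum_cutoff = hna_sum_cutoff, depletion_fold = depletion_fold,
    srna_min_len = srna_min_len, srna_max_len = srna_max_len,
    max_hits = max_hits, pca_window = pca_window, pca_step = pca_step,
    rptm_scale = rptm_scale, min_coverage = min_coverage,
    seed = as.integer(seed)
  )
  sizes <- c("tile_size", "srna_window", "pca_window", "pca_step", "rptm_scale")
  if (any(unlist(cfg[sizes]) <= 0)) abort("all sizes must be positive")
  if (cfg$srna_min_len > cfg$srna_max_len) abort("srna_min_len must be <= srna_max_len")
  thr <- c("diff_threshold", "q_threshold", "hna_sum_cutoff", "depletion_fold",
           "min_coverage")
  if (any(unlist(cfg[thr]) < 0)) abort("thresholds must be >= 0")
  if (cfg$max_hits < 1) abort("max_hits must be >= 1")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error, missing keys fall back to the defaults. `overrides` (e.g. parsed
#' command-line flags) take precedence over the file.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file values.
#' @return A `pipeline_config` list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    unknown <- setdiff(names(vals), names(formals(pipeline_config)))
    if (length(unknown) > 0) {
      abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
    }
  }
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) cat(sprintf("  %-16s %s\n", k, format(x[[k]])))
  invisible(x)
}
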