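#' Classify siRNA windows from a mutant-panel depletion pattern
#'
#' RdDM siRNA clusters separate into an upstream class that requires only
#' the Pol IV arm of the pathway and a downstream class that additionally
#' requires the Pol V arm. Given, per window, logical depletion calls in a
#' panel of mutants, each window is labelled:
#'
#' * `PolIV_only` — depleted in `nrpd1` but in none of `polv_requires`;
#' * `PolV_dependent` — depleted in `nrpd1` *and* in all of `polv_requires`;
#' * `unaffected` — depleted in no panel mutant;
#' * `other` — any remaining pattern.
#'
#' The labels form a partition: every window receives exactly one.
#'
#' @param panel Tibble with region columns and one logical column per panel
#'   genotype; `nrpd1` and all of `polv_requires` must be present and
#'   non-missing.
#' @param polv_requires Downstream-arm mutants that must all be depleted
#'   for `PolV_dependent` (default `c("nrpe1", "drm2")`; set to `"nrpe1"`
#'   for an nrpe1-only definition).
#' @return `panel` with a `class` column appended.
#' @export
classify_sirna <- function(panel, polv_requires = c("nrpe1", "drm2")) {
  genos <- unique(c("nrpd1", polv_requires))
  missing_cols <- setdiff(genos, names(panel))
  if (length(missing_cols) > 0) {
    abort(sprintf("panel is missing genotype column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  flags <- panel[, genos, drop = FALSE]
  if (any(!vapply(flags, is.logical, logical(1))) ||
      any(is.na(as.matrix(flags)))) {
    abort("panel genotype columns must be logical and non-missing")
  }
  down <- as.matrix(panel[, polv_requires, drop = FALSE])
  any_down <- apply(down, 1, any)
  all_down <- apply(down, 1, all)
  none <- !panel$nrpd1 & !any_down
  mutate(panel, class = dplyr::case_when(
    panel$nrpd1 & all_down ~ "PolV_dependent",
    panel$nrpd1 & !any_down ~ "PolIV_only",
    none ~ "unaffected",
    TRUE ~ "other"
  ))
}

#' Cross-tabulate factor-mutant depletion against siRNA class
#'
#' Counts, per siRNA class, how many windows are depleted in a factor
#' mutant of interest (e.g. a putative RdDM component) and the fraction of
#' the class that this represents — the summary behind "factor siRNAs
#' behave like the downstream class" arguments.
#'
#' @param classified Output of [classify_sirna()].
#' @param factor_genotype Name of the logical column holding the factor
#'   mutant's depletion calls.
#' @return Tibble `class`, `n`, `n_factor_depleted`, `fraction_depleted`.
#' @export
class_contingency <- function(classified, factor_genotype) {
  if (!factor_genotype %in% names(classified)) {
    abort(sprintf("column '%s' not found", factor_genotype))
  }
  classified |>
    group_by(.data$class) |>
    summarise(n = n(),
              n_factor_depleted = sum(.data[[factor_genotype]]),
              .groups = "drop") |>
    mutate(fraction_depleted = .data$n_factor_depleted / .data$n)
}
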