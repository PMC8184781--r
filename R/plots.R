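#' Plot a fitted ITC isotherm
#'
#' Measured per-injection heats against molar ratio, with the fitted
#' one-site curve overlaid.
#'
#' @param object An `itc_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot itc_fit
#' @export
autoplot.itc_fit <- function(object, ...) {
  geo <- object$geometry
  vols <- cumsum(object$data$volume)
  # molar ratio of cumulative ligand to (displacement-diluted) macromolecule
  dil <- cumprod(1 - object$data$volume / geo$cell_volume)
  xt <- numeric(length(vols))
  x <- 0
  for (i in seq_along(vols)) {
    f <- object$data$volume[i] / geo$cell_volume
    x <- x * (1 - f) + geo$syringe_conc * f
    xt[i] <- x
  }
  ratio <- xt / (geo$cell_conc * dil)
  df <- tibble(ratio = ratio, heat = object$data$heat,
               fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = ratio)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$heat)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "Molar ratio (ligand / macromolecule)",
                  y = "Heat (kcal per mol of injectant)",
                  title = sprintf("One-site fit: Kd = %.3g uM, N = %.2f",
                                  object$kd_uM, object$params$n_stoich)) +
    ggplot2::theme_minimal()
}

#' Plot a ranked siRNA-change enrichment profile
#'
#' @param object A `ranked_profile` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ranked_profile
#' @export
autoplot.ranked_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$enrichment),
                        alpha = 0.25, size = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$enrichment_smooth),
                       colour = "firebrick", na.rm = TRUE) +
    ggplot2::labs(x = "Regions ranked by siRNA change (largest loss first)",
                  y = "log2 ChIP enrichment",
                  subtitle = sprintf("Spearman rho = %.2f", object$spearman_rho)) +
    ggplot2::theme_minimal()
}

#' Plot a metagene enrichment profile
#'
#' @param object A `metagene_profile` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot metagene_profile
#' @export
autoplot.metagene_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$bin, y = .data$enrichment,
                               colour = .data$zone, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Bin (5' flank - scaled gene body - 3' flank)",
                  y = "log2 ChIP enrichment", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of genomic feature composition
#'
#' @param composition Output of [feature_composition()], optionally with a
#'   `set` column when several region sets are row-bound.
#' @return A ggplot.
#' @export
plot_feature_composition <- function(composition) {
  aes <- if ("set" %in% names(composition)) {
    ggplot2::aes(x = .data$set, y = .data$fraction, fill = .data$category)
  } else {
    ggplot2::aes(x = .data$category, y = .data$fraction, fill = .data$category)
  }
  ggplot2::ggplot(composition, aes) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "Fraction of regions", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Box plot of per-region methylation levels by sample group
#'
#' @param levels Tibble with columns `group` and `level` (e.g. stacked
#'   [context_levels()] results with a `context` column for facetting).
#' @return A ggplot.
#' @export
plot_context_levels <- function(levels) {
  p <- ggplot2::ggplot(levels, ggplot2::aes(x = .data$group, y = .data$level)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "Methylation level") +
    ggplot2::theme_minimal()
  if ("context" %in% names(levels)) {
    p <- p + ggplot2::facet_wrap(~context)
  }
  p
}
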