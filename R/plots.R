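# ggplot2 methods for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_line
#'   geom_hline labs theme_minimal
NULL

#' Plot a PCoA ordination
#'
#' @param object A `pcoa_result`.
#' @param colour Optional per-sample grouping vector (e.g. habitat labels)
#'   used as point colour.
#' @param axes Which two axes to draw (default 1:2).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pcoa_result
#' @export
autoplot.pcoa_result <- function(object, colour = NULL, axes = c(1, 2), ...) {
  df <- tidy(object)
  ax <- paste0("Axis", axes)
  if (!all(ax %in% names(df))) abort("requested axes not available")
  pct <- 100 * object$prop_explained[axes]
  if (!is.null(colour)) df$group <- as.character(colour)
  p <- ggplot(df, aes(x = .data[[ax[1]]], y = .data[[ax[2]]])) +
    labs(x = sprintf("%s (%.1f%%)", ax[1], pct[1]),
         y = sprintf("%s (%.1f%%)", ax[2], pct[2])) +
    theme_minimal()
  if (is.null(colour)) p + geom_point()
  else p + geom_point(aes(colour = .data$group)) + labs(colour = "group")
}

#' Plot an AMOVA variance partition
#'
#' @param object An `amova_result`.
#' @param ... Unused.
#' @return A ggplot bar chart of the percentage of variation per stratum.
#' @method autoplot amova_result
#' @export
autoplot.amova_result <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$source != "Total")
  ggplot(df, aes(x = .data$source, y = .data$pct_variation)) +
    geom_col() +
    labs(x = NULL, y = "% of variation") +
    theme_minimal()
}

#' Plot an Fst-outlier scan against its neutral envelope
#'
#' @param object An `fdist_scan`.
#' @param ... Unused.
#' @return A ggplot of per-locus fst vs heterozygosity with the envelope
#'   bounds.
#' @method autoplot fdist_scan
#' @export
autoplot.fdist_scan <- function(object, ...) {
  env <- object$envelope
  env_df <- tibble::tibble(
    het = (env$het_lo + env$het_hi) / 2,
    lower = env$lower, upper = env$upper)
  ggplot(object$records, aes(x = .data$het, y = .data$fst)) +
    geom_point(aes(colour = .data$flag), size = 0.8) +
    geom_line(data = env_df, aes(x = .data$het, y = .data$upper),
              linetype = 2, inherit.aes = FALSE) +
    geom_line(data = env_df, aes(x = .data$het, y = .data$lower),
              linetype = 2, inherit.aes = FALSE) +
    labs(x = "heterozygosity (Ht)", y = "Fst", colour = NULL) +
    theme_minimal()
}
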