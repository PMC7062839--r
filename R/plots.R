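#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_abline geom_hline
#'   labs scale_x_continuous theme_minimal autoplot
NULL

#' Plot stratified curves
#'
#' Fold-enrichment curves are drawn as one line per secondary-phenotype
#' stratum against the -log10(p1) grid; conditional Q-Q curves as observed
#' vs expected -log10 quantiles with the identity line. Rising separation
#' between strata indicates pleiotropic enrichment.
#'
#' @param object A `stratified_curves` tibble from [fold_enrichment()] or
#'   [conditional_qq()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stratified_curves <- function(object, ...) {
  type <- attr(object, "curve_type")
  dir <- attr(object, "direction")
  d <- as_tibble(object) |>
    mutate(stratum_label = factor(
      sprintf("p2 <= %g", .data$stratum),
      levels = sprintf("p2 <= %g", sort(unique(.data$stratum), decreasing = TRUE))))
  if (identical(type, "conditional_qq")) {
    ggplot(d, aes(x = .data$expected, y = .data$observed,
                  colour = .data$stratum_label)) +
      geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
      geom_line() +
      labs(x = expression(Expected ~ -log[10](p)),
           y = expression(Observed ~ -log[10](p)),
           colour = "Stratum",
           title = sprintf("Conditional Q-Q (%s)", dir)) +
      theme_minimal()
  } else {
    ggplot(d, aes(x = .data$t, y = .data$fe, colour = .data$stratum_label)) +
      geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
      geom_line(na.rm = TRUE) +
      labs(x = expression(Nominal ~ -log[10](p[1])), y = "Fold enrichment",
           colour = "Stratum",
           title = sprintf("Fold enrichment (%s)", dir)) +
      theme_minimal()
  }
}

#' @rdname autoplot.stratified_curves
#' @param x A `stratified_curves` tibble.
#' @param y Unused.
#' @export
plot.stratified_curves <- function(x, y, ...) print(autoplot(x, ...))

#' Manhattan plot of conditional or conjunction FDR values
#'
#' @param r A `cfdr_result` or tibble accepted by [manhattan_data()].
#' @param value FDR column to plot (see [manhattan_data()]).
#' @return A ggplot with the tier reference lines.
#' @export
plot_cfdr_manhattan <- function(r, value = "q") {
  md <- manhattan_data(r, value = value)
  ref <- attr(md, "ref_lines")
  centers <- attr(md, "chrom_centers")
  ggplot(as_tibble(md), aes(x = .data$coord, y = .data$neg_log10,
                            colour = factor(.data$chrom_index))) +
    geom_point(size = 0.4, show.legend = FALSE) +
    geom_hline(yintercept = ref[["genome_wide"]], colour = "red") +
    geom_hline(yintercept = ref[["suggestive"]], colour = "blue") +
    scale_x_continuous(breaks = centers$center, labels = centers$chrom) +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    labs(x = "Chromosome", y = expression(-log[10](FDR))) +
    theme_minimal()
}
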