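# Quick-look ggplot2 graphics for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-protein glycosite locale fractions
#'
#' Box plot of the per-protein fraction of glycosites in ordered vs
#' disordered regions.
#'
#' @param records A `glyco_records` tibble.
#' @return A ggplot object.
#' @export
plot_locale_fractions <- function(records) {
  frac <- glycosite_locale_fractions(records)
  long <- tidyr::pivot_longer(frac, c("ordered_fraction", "disordered_fraction"),
                              names_to = "locale", values_to = "fraction")
  long$locale <- ifelse(long$locale == "ordered_fraction", "Ordered", "Disordered")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$locale, y = .data$fraction)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "Fraction of N-glycosites",
                  title = "N-glycosite occurrence by locale") +
    ggplot2::theme_minimal()
}

#' Bar plot of amino-acid fractional enrichment
#'
#' @param object A `glyco_enrichment` tibble from [bootstrap_enrichment()].
#' @param ... Unused.
#' @return A ggplot object: per-residue fractional difference D, significant
#'   residues filled.
#' @export
autoplot.glyco_enrichment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$aa, y = .data$d,
                                       fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
                               name = "Significant") +
    ggplot2::labs(x = "Amino acid", y = "Fractional enrichment D",
                  title = "Query vs background composition") +
    ggplot2::theme_minimal()
}

#' Tile plot of property enrichment directions
#'
#' @param object A `glyco_property_enrichment` tibble from
#'   [property_enrichment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glyco_property_enrichment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = 1, y = .data$scale,
                                       fill = .data$direction)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(enriched = "firebrick",
                                          depleted = "steelblue", ns = "grey80")) +
    ggplot2::labs(x = NULL, y = NULL, title = "Residue property enrichment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Box plot of per-region mean entropies
#'
#' @param entropy The `entropy` tibble from [run_conserve()] (columns
#'   `protein_id`, `region`, `mean_entropy`).
#' @return A ggplot object.
#' @export
plot_region_entropy <- function(entropy) {
  ggplot2::ggplot(entropy, ggplot2::aes(x = .data$region, y = .data$mean_entropy)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "Mean Shannon entropy (bits)",
                  title = "Conservation by region") +
    ggplot2::theme_minimal()
}
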