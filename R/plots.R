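# ggplot2 displays for association results and marker digests.

#' Plot an association scan (trait means by year and genotype)
#'
#' One facet per trait: per-year group means with 95% confidence interval
#' bars, colored by allele class, with the per-year F-test p-value printed
#' at the top of each year column.
#'
#' @param object A [assoc_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grf_assoc_scan
#' @export
autoplot.grf_assoc_scan <- function(object, ...) {
  labs <- object |>
    dplyr::distinct(.data$trait, .data$year, .data$p_value)
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$year), y = .data$mean,
                                       color = .data$allele)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::geom_text(
      data = labs,
      ggplot2::aes(x = factor(.data$year), y = Inf,
                   label = sprintf("p = %.3g", .data$p_value)),
      inherit.aes = FALSE, vjust = 1.4, size = 2.8
    ) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "year", y = "trait value (mean, 95% CI)",
                  color = "allele") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.grf_assoc_scan
#' @method autoplot grf_assoc
#' @export
autoplot.grf_assoc <- function(object, ...) {
  g <- object$groups
  ggplot2::ggplot(g, ggplot2::aes(x = .data$allele, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::labs(
      x = object$marker, y = object$trait,
      title = sprintf("%s, %s: F = %.2f, p = %.3g",
                      object$trait, object$year, object$statistic,
                      object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Gel-style plot of digestion fragments
#'
#' Draws one lane per sample with a band at each fragment size (bp),
#' mimicking the agarose gel used to read PCR/CAPS markers.
#'
#' @param fragments Named list of numeric fragment-length vectors.
#' @return A ggplot object.
#' @export
plot_gel <- function(fragments) {
  stopifnot(is.list(fragments), !is.null(names(fragments)))
  df <- purrr::map_dfr(names(fragments), function(nm) {
    tibble(lane = nm, bp = as.numeric(fragments[[nm]]))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lane, y = .data$bp)) +
    ggplot2::geom_tile(width = 0.6, height = 0.015 * df$bp, fill = "grey20") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "fragment size (bp)") +
    ggplot2::theme_minimal()
}
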