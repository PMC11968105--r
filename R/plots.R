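# ggplot2 helpers for the main result types

#' Plot a site-density track
#'
#' Column plot of site counts per genome window, one facet per
#' chromosome — a plain rendering of an editome density map.
#'
#' @param track a tibble from [density_track()].
#' @return a ggplot.
#' @export
plot_density_track <- function(track) {
  ggplot2::ggplot(track,
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$n_sites)) +
    ggplot2::geom_col(width = (track$end - track$start) / 1e6,
                      fill = "grey30") +
    ggplot2::facet_wrap(~chrom, ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "position (Mb)", y = "editing sites per window") +
    ggplot2::theme_minimal()
}

#' Plot the editing-level distribution of called sites
#'
#' @param sites an editing-site tibble.
#' @param bins histogram bins.
#' @return a ggplot.
#' @export
plot_level_histogram <- function(sites, bins = 30) {
  ggplot2::ggplot(sites, ggplot2::aes(x = .data$level)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30", colour = "white") +
    ggplot2::labs(x = "editing level", y = "sites") +
    ggplot2::theme_minimal()
}

#' Autoplot an editome summary
#'
#' Two panels: per-chromosome site counts and the genic-region
#' distribution with percentage labels.
#'
#' @param object an `editome_summary`.
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot editome_summary
#' @export
autoplot.editome_summary <- function(object, ...) {
  region <- object$region |>
    mutate(region = factor(.data$region, levels = REGION_LEVELS))
  p_chrom <- ggplot2::ggplot(object$per_chrom,
                             ggplot2::aes(x = .data$chrom,
                                          y = .data$n_sites)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "sites") +
    ggplot2::theme_minimal()
  p_region <- ggplot2::ggplot(region,
                              ggplot2::aes(x = .data$region,
                                           y = .data$n_sites)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", .data$pct_of_total)), vjust = -0.3,
      size = 3) +
    ggplot2::labs(x = NULL, y = "sites") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(p_chrom, p_region, ncol = 1)
  } else {
    p_region
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
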