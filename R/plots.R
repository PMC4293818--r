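#' Plot a sliding-window nucleotide diversity track
#'
#' @param track A `diversity_track` from [sliding_pi()].
#' @param hotspots Optional hotspot tibble from [find_hotspots()]; drawn as
#'   shaded intervals with the threshold as a dashed line.
#' @return A ggplot object.
#' @export
plot_diversity_track <- function(track, hotspots = NULL) {
  p <- ggplot2::ggplot(as_tibble(track),
                       ggplot2::aes(x = .data$midpoint, y = .data$pi)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "alignment position (window midpoint)",
                  y = expression(pi)) +
    ggplot2::theme_minimal()
  if (!is.null(hotspots) && nrow(hotspots) > 0) {
    p <- p +
      ggplot2::geom_rect(
        data = hotspots,
        ggplot2::aes(xmin = .data$start, xmax = .data$end,
                     ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, alpha = 0.15, fill = "firebrick") +
      ggplot2::geom_hline(yintercept = hotspots$threshold[1],
                          linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot discrimination power against window length
#'
#' @param curve Tibble with `length` and `max_pm` (from [pm_length_curve()]
#'   or a `minibarcode_result`'s curve).
#' @return A ggplot object.
#' @export
plot_pm_curve <- function(curve) {
  if (inherits(curve, "minibarcode_result")) curve <- curve$curve
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$length, y = .data$max_pm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "window length (bp)", y = "maximum Pm (%)") +
    ggplot2::theme_minimal()
}

#' Plot the collapsed substitution spectrum
#'
#' @param x A `substitution_scan`.
#' @return A ggplot bar chart of the six strand-collapsed substitution
#'   classes.
#' @export
plot_substitution_spectrum <- function(x) {
  spec <- x$summary$spectrum |>
    mutate(collapsed_type = factor(.data$collapsed_type,
                                   levels = COLLAPSED_TYPES))
  ggplot2::ggplot(spec, ggplot2::aes(x = .data$collapsed_type, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "substitution class (reference base first)",
                  y = "events") +
    ggplot2::theme_minimal()
}
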