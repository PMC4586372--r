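#' Plot control and treated occupancy profiles for one locus
#'
#' Renders the basal profile in black and the treated profile in red over
#' a grey zero baseline (occupancy above, depletion below), x-axis in
#' TSS-relative bp. Optional display-only moving-average smoothing;
#' analysis never uses smoothed values. TFBS annotations are drawn as
#' glyphs at their interval midpoints, colored by regulatory class.
#'
#' @param control,treated Profile tibbles for one locus (one profile each,
#'   e.g. replicate-averaged).
#' @param tfbs Optional TFBS tibble for the locus (`factor`, `start`,
#'   `end`, `regulatory_class`).
#' @param smooth Moving-average window in grid positions (0 = none).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_profile <- function(control, treated, tfbs = NULL, smooth = 0L,
                         title = NULL) {
  smooth_vals <- function(v) {
    if (smooth < 2L) return(v)
    as.numeric(stats::filter(v, rep(1 / smooth, smooth), sides = 2))
  }
  dat <- dplyr::bind_rows(
    dplyr::mutate(control[order(control$offset), ],
                  state = "basal", value = smooth_vals(.data$value)),
    dplyr::mutate(treated[order(treated$offset), ],
                  state = "treated", value = smooth_vals(.data$value))
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$offset, y = .data$value,
                                         color = .data$state)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey60") +
    ggplot2::geom_vline(xintercept = 0, color = "grey85", linetype = 2) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_color_manual(values = c(basal = "black", treated = "red")) +
    ggplot2::labs(x = "position relative to TSS (bp)",
                  y = expression(log[2] * "(nucleosomal / genomic)"),
                  color = NULL, title = title) +
    ggplot2::theme_classic()
  if (!is.null(tfbs) && nrow(tfbs)) {
    glyphs <- tibble::tibble(
      x = (tfbs$start + tfbs$end) / 2,
      y = min(dat$value, na.rm = TRUE) - 0.2,
      class = tfbs$regulatory_class
    )
    p <- p +
      ggplot2::geom_point(
        data = glyphs,
        ggplot2::aes(x = .data$x, y = .data$y, fill = .data$class),
        shape = 23, size = 3, inherit.aes = FALSE) +
      ggplot2::scale_fill_manual(values = c(permissive = "forestgreen",
                                            repressive = "firebrick"))
  }
  p
}
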