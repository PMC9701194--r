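#' Plot a PAM sequence logo (stacked information-content bars)
#'
#' Each position's bar reaches its information content in bits, split by
#' base contribution (`prob * IC`), the numeric content of a sequence
#' logo.
#'
#' @param object A [build_ppm()] result.
#' @param background Background distribution passed to
#'   [information_content()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pam_ppm <- function(object, background = rep(0.25, 4), ...) {
  heights <- logo_heights(object, background)
  ggplot2::ggplot(heights,
    ggplot2::aes(x = .data$position, y = .data$height,
      fill = .data$base)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_x_continuous(breaks = unique(heights$position)) +
    ggplot2::labs(x = "cassette position", y = "information (bits)",
      fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pam_ppm
#' @export
plot_logo <- function(object, background = rep(0.25, 4)) {
  autoplot.pam_ppm(object, background)
}

#' Plot a PAM profile (logo + consensus annotation)
#'
#' @param object A [pam_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pam_profile <- function(object, ...) {
  autoplot.pam_ppm(object$ppm) +
    ggplot2::ggtitle(paste0("consensus: ", as.character(object$consensus)))
}

#' Plot reporter events with rectangular gates
#'
#' @param events Tibble with `green` and `red` columns.
#' @param green_threshold,red_threshold Gate thresholds drawn as dashed
#'   lines.
#' @return A ggplot object.
#' @export
plot_reporter_gates <- function(events, green_threshold = 500,
                                red_threshold = 1000) {
  ggplot2::ggplot(events,
    ggplot2::aes(x = .data$red, y = .data$green)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(yintercept = green_threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = red_threshold, linetype = 2) +
    ggplot2::labs(x = "red (tdTomato)", y = "green (EGFP)") +
    ggplot2::theme_minimal()
}

#' Plot a base-editing conversion profile with its editing window
#'
#' @param profile Tibble with `position` and `freq` (or
#'   `converted`/`depth`).
#' @param window Optional `c(start, end)` editing window, shaded.
#' @return A ggplot object.
#' @export
plot_base_edit_profile <- function(profile, window = NULL) {
  if (!"freq" %in% names(profile)) {
    profile <- mutate(profile, freq = .data$converted / .data$depth)
  }
  p <- ggplot2::ggplot(profile,
    ggplot2::aes(x = .data$position, y = .data$freq)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "spacer position (5' PAM-distal = 1)",
      y = "conversion frequency") +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect",
      xmin = window[1] - 0.5, xmax = window[2] + 0.5,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue")
  }
  p
}
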