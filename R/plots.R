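#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a positional contrast map
#'
#' Raster of the pixelwise t-statistics; positive values (hot) are adult
#' evidence, negative (cold) child evidence, following the contrast's
#' sign convention. Significant pixels can be outlined.
#'
#' @param object A `dfm_contrast`.
#' @param outline_significant Overlay the significant pixels.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dfm_contrast <- function(object, outline_significant = TRUE, ...) {
  df <- tidy(object)
  pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                         fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "grey95",
                                  high = "#b2182b") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "t", x = NULL, y = NULL,
                  title = paste0("Positional contrast (positive = ",
                                 object$positive, " evidence)")) +
    ggplot2::theme_minimal()
  if (outline_significant && any(object$significant)) {
    pl <- pl + ggplot2::geom_point(
      data = dplyr::filter(df, .data$significant),
      ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, size = 0.1, alpha = 0.25, colour = "black")
  }
  pl
}

#' Plot a band contrast profile
#'
#' t-statistic per SF or orientation band; positive values are child
#' evidence. Significant bands are starred.
#'
#' @param object A `dfm_band_contrast`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dfm_band_contrast <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(round(.data$level, 1)),
                                   y = .data$t, fill = .data$t > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(data = dplyr::filter(df, .data$significant),
                       ggplot2::aes(label = "*",
                                    y = .data$t + 0.3 * sign(.data$t)),
                       size = 6) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "#2166ac")) +
    ggplot2::labs(x = if (df$axis[1] == "sf") "SF (cycles per image)"
                  else "Orientation (deg)",
                  y = "t (positive = child evidence)") +
    ggplot2::theme_minimal()
}

#' Plot a session's staircase trace
#'
#' Number of features presented on every trial, with the final threshold
#' estimate.
#'
#' @param object A `dfm_session`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dfm_session <- function(object, ...) {
  df <- object$log
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$n_presented)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_hline(yintercept = object$threshold$n_gabors_threshold,
                        linetype = 2, colour = "#b2182b") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Trial", y = "Features presented (log scale)",
                  title = paste0("QUEST staircase, threshold ",
                                 round(object$threshold$n_gabors_threshold, 1),
                                 " features")) +
    ggplot2::theme_minimal()
}

#' Plot a position map or stimulus image
#'
#' @param image Numeric matrix (map or 0-255 image).
#' @param title Plot title.
#' @return A ggplot raster.
#' @export
plot_image <- function(image, title = NULL) {
  n <- nrow(image)
  df <- tibble::tibble(
    x = rep(seq_len(ncol(image)) - 1L, each = n),
    y = rep(seq_len(n) - 1L, times = ncol(image)),
    value = as.vector(image)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL, title = title) +
    ggplot2::theme_minimal()
}
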