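strength_levels <- c("poor", "fair", "moderate", "substantial",
                     "almost perfect")

#' Plot a co-occurrence matrix as a probability heatmap
#'
#' @param g A `bonetex_glcm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_glcm <- function(g, ...) {
  stopifnot(inherits(g, "bonetex_glcm"))
  d <- tibble(i = as.vector(row(g$p)),
              j = as.vector(col(g$p)),
              p = as.vector(g$p))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$j, y = .data$i,
                                  fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "p(i, j)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "gray level j", y = "gray level i",
                  title = sprintf("Co-occurrence matrix, offset (%s)",
                                  paste(g$offset, collapse = ","))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bonetex_glcm <- function(object, ...) plot_glcm(object, ...)

#' @export
autoplot.bonetex_assoc <- function(object, ...) {
  d <- as_tibble(object)
  d$attribute <- factor(d$attribute, levels = rev(d$attribute))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pearson_r, y = .data$attribute,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#D55E00",
                                          `FALSE` = "grey65"),
                               name = "p < alpha") +
    ggplot2::labs(x = "Pearson r with BMD", y = NULL,
                  title = "Texture attribute vs bone mineral density") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bonetex_concordance <- function(object, ...) {
  d <- as_tibble(object)
  d$attribute <- factor(d$attribute, levels = rev(d$attribute))
  d$strength <- factor(d$strength, levels = strength_levels)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ccc, y = .data$attribute,
                                  colour = .data$strength)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.3) +
    ggplot2::geom_vline(xintercept = 0.8, linetype = 2) +
    ggplot2::scale_colour_viridis_d(drop = FALSE, name = "agreement") +
    ggplot2::labs(x = "Lin's concordance correlation coefficient", y = NULL,
                  title = "Interobserver agreement per texture attribute") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
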