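#' Plot an axial slice of an information map
#'
#' @param object An `information_map`.
#' @param slice Slice index along `axis` (default: middle slice).
#' @param axis Axis the slice is taken across (1, 2 or 3; default 3).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.information_map <- function(object, slice = NULL, axis = 3L, ...) {
  grid <- attr(object, "grid")
  ax <- c("x", "y", "z")[axis]
  slice <- slice %||% ceiling(grid$shape[axis] / 2)
  keep <- object[[ax]] == slice
  d <- as_tibble(object)[keep, , drop = FALSE]
  d$value <- ifelse(is.finite(d$score), d$score, NA_real_)
  plane <- setdiff(c("x", "y", "z"), ax)
  ggplot2::ggplot(d, ggplot2::aes(.data[[plane[1]]], .data[[plane[2]]],
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(title = sprintf("%s map, %s = %d", attr(object, "method"),
                                  ax, slice),
                  fill = "score") +
    ggplot2::theme_minimal()
}

#' Plot cluster size against relevance for a search result
#'
#' One point per origin; informative regions show up as arms of large,
#' high-relevance clusters.
#'
#' @param object An `ics_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ics_result <- function(object, ...) {
  d <- tidy(object)
  d$relevance <- ifelse(is.finite(d$relevance), d$relevance, NA_real_)
  aes <- if ("information" %in% names(d))
    ggplot2::aes(.data$size, .data$relevance, colour = .data$information)
  else ggplot2::aes(.data$size, .data$relevance)
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cluster size (voxels)", y = "trace-ratio relevance") +
    ggplot2::theme_minimal()
}
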