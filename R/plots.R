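#' Heatmap of a mixing matrix
#'
#' Standard contact-matrix heatmap: classes on both axes, fill mapped to
#' the (optionally normalized) contact count; brighter cells mean heavier
#' mixing.
#'
#' @param object A `mixing_matrix`.
#' @param normalized Plot the min-max-normalized values (requires
#'   [normalize_mixing()]); default uses them when present.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixing_matrix <- function(object, normalized = !is.null(object$normalized), ...) {
  long <- tidy(object)
  if (normalized) {
    if (is.null(object$normalized)) {
      stop("call `normalize_mixing()` first or use `normalized = FALSE`", call. = FALSE)
    }
    fill_var <- "normalized"
    fill_lab <- "Normalized contacts"
  } else {
    fill_var <- "count"
    fill_lab <- "Contacts"
  }
  n_axis <- length(object$axis)
  breaks <- if (n_axis > 20) object$axis[seq(1, n_axis, by = 10)] else object$axis
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$class_a, y = .data$class_b, fill = .data[[fill_var]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = fill_lab) +
    ggplot2::scale_x_discrete(breaks = breaks) +
    ggplot2::scale_y_discrete(breaks = breaks) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = object$axis_name, y = object$axis_name) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mixing_matrix
#' @param matrix A `mixing_matrix`.
#' @export
plot_mixing_matrix <- function(matrix, ...) {
  autoplot(matrix, ...)
}

#' Degree distribution of a contact network
#'
#' Histogram of per-admission contact partner counts (unweighted degree).
#'
#' @param object A `contact_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contact_network <- function(object, ...) {
  g <- as_igraph(object, weighted = FALSE)
  d <- tibble::tibble(degree = igraph::degree(g))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(
      x = "Degree (co-located admissions)", y = "Admissions",
      title = paste0(
        object$hospital_id, ": ", format(object$window[1]), " to ",
        format(object$window[2])
      )
    ) +
    ggplot2::theme_minimal()
}
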