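#' Force-extension plot of a pulling run
#'
#' @param object an `sop_pulling`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sop_pulling <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$extension, y = .data$force_pN)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "extension (Å)", y = "force (pN)",
                  title = "Cantilever force-extension") +
    ggplot2::theme_minimal()
}

#' Translocation progress plot
#'
#' Translocated fraction x(t) per cycle.
#'
#' @param object an `sop_translocation`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sop_translocation <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$time_ps, y = .data$x)) +
    ggplot2::geom_step(colour = "darkorange") +
    ggplot2::labs(x = "time (ps)", y = "translocated fraction x(t)",
                  title = "Pore translocation progress") +
    ggplot2::theme_minimal()
}

#' Free-energy landscape heat map
#'
#' @param object an `sop_fel`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sop_fel <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$F)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = expression(-k[B] * T ~ ln ~ P)) +
    ggplot2::labs(title = "Free-energy landscape") +
    ggplot2::theme_minimal()
}

#' Interface-resolved contact map plot
#'
#' @param topology an `sop_topology`.
#' @return a ggplot of the native contact list coloured by interface class.
#' @export
plot_contact_map <- function(topology) {
  ggplot2::ggplot(topology$contacts,
                  ggplot2::aes(x = .data$i, y = .data$j,
                               colour = .data$class)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "bead i", y = "bead j", colour = "interface") +
    ggplot2::theme_minimal()
}
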