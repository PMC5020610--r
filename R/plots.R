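# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a contact-probability map
#'
#' @param object A `"contact_map"` from [contact_probability()].
#' @param ... Unused.
#' @return A ggplot (tile map, residue i vs residue j).
#' @export
autoplot.contact_map <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$resid_i, y = .data$resid_j,
                                 fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "residue (chain 1)", y = "residue (chain 2)",
                  fill = "P(contact)",
                  title = paste(object$scope, object$mode, "contact map"))
}

#' Plot a free-energy surface
#'
#' @param object A `"fes_grid"` from [fes2d()].
#' @param ... Unused.
#' @return A ggplot raster of G (kcal/mol); masked bins are blank.
#' @export
autoplot.fes_grid <- function(object, ...) {
  tidy(object) |>
    dplyr::filter(!is.na(.data$G)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$x, y = .data$y, fill = .data$G)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(fill = "G (kcal/mol)")
}

#' Plot per-residue secondary-structure probabilities
#'
#' @param object An `"ss_profile"` from [ss_profile()].
#' @param classes Classes to draw (default sheet, helix, coil).
#' @param ... Unused.
#' @return A ggplot of probability vs residue, one facet per chain.
#' @export
autoplot.ss_profile <- function(object, classes = c("sheet", "helix", "coil"),
                                ...) {
  object$residue |>
    dplyr::filter(.data$class %in% classes) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$resid, y = .data$probability,
                                 color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chain) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "residue", y = "probability", color = NULL)
}
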