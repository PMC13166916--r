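#' Ternary scatter of diagnosed grids
#'
#' Plots prescription rows on the 2-simplex: the left, right and top vertices
#' are the three top-weight components (X, Y, Z), points are coloured by
#' management level, and the centre region (all components limited) is
#' marked. Requires ggplot2.
#'
#' @param pres prescription data frame from [prescribe()] (or any data frame
#'   with `X`, `Y`, `Z` and `level` columns).
#' @param components character length-3 vertex labels.
#' @param center_radius radius of the drawn centre circle (matches the
#'   diagnosis default).
#' @param title plot title.
#' @return A ggplot object.
#' @export
plot_ternary <- function(pres, components = ugci_components()[1:3],
                         center_radius = 0.15, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_ternary() requires ggplot2")
  keep <- !is.na(pres$X)
  pres <- pres[keep, , drop = FALSE]
  # simplex -> plane: vertex X at (0,0), Y at (1,0), Z at (0.5, sqrt(3)/2)
  to_xy <- function(X, Y, Z) {
    cbind(x = Y + Z / 2, y = Z * sqrt(3) / 2)
  }
  xy <- to_xy(pres$X, pres$Y, pres$Z)
  df <- data.frame(x = xy[, "x"], y = xy[, "y"],
                   level = if ("level" %in% names(pres)) pres$level else "diagnosed")
  tri <- data.frame(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  theta <- seq(0, 2 * pi, length.out = 100)
  cen <- to_xy(1 / 3, 1 / 3, 1 / 3)
  # drawn circle is indicative (plane distance ~ proportion distance times
  # sqrt(3)/2); classification happens in proportion space
  circ <- data.frame(x = cen[1] + center_radius * cos(theta) * sqrt(3) / 2,
                     y = cen[2] + center_radius * sin(theta) * sqrt(3) / 2)
  labs <- data.frame(x = c(-0.04, 1.04, 0.5), y = c(-0.04, -0.04, sqrt(3) / 2 + 0.05),
                     lab = components)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_path(data = tri, linewidth = 0.4, colour = "grey30") +
    ggplot2::geom_path(data = circ, linetype = "dashed", colour = "grey55",
                       linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = level), size = 1.1,
                        alpha = 0.75) +
    ggplot2::geom_text(data = labs, ggplot2::aes(label = lab), size = 3) +
    ggplot2::scale_colour_manual(values = c(extremely_low = "#2166ac",
                                            low = "#b2182b",
                                            diagnosed = "grey40")) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = title, colour = "UGCI level")
  }

utils::globalVariables(c("x", "y", "level", "lab"))
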