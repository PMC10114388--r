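#' Plot an elastin-content sweep
#'
#' Shows the fibre-model metrics against elastin content: required rotation
#' stresses, mean collagen von Mises stress per traction protocol, mean
#' collagen displacement, and stress-strain slopes. The sheet row, having
#' no content, is drawn as a horizontal dashed reference where applicable.
#'
#' @param object A `ligafem_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ligafem_sweep
#' @export
autoplot.ligafem_sweep <- function(object, ...) {
  fib <- dplyr::filter(object, .data$model == "fibre")
  long <- tidyr::pivot_longer(
    fib,
    cols = dplyr::any_of(c("sigma_y_MPa", "sigma_z_MPa",
                           "tensile_mean_vm_Pa", "shear_mean_vm_Pa",
                           "tensile_mean_disp_m", "shear_mean_disp_m",
                           "tensile_slope_Pa", "shear_slope_Pa")),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$content_pct, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "elastin content [%]", y = NULL,
                  title = "Fibre-model response vs elastin content") +
    ggplot2::theme_minimal()
}

#' Plot a von Mises stress slice of a solved load case
#'
#' Tile plot of element-centroid von Mises stress on the structured voxel
#' layer nearest the requested coordinate.
#'
#' @param result A `ligafem_result`.
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @param at Coordinate (um) of the slice along the remaining axis;
#'   defaults to the mid-plane.
#' @return A ggplot object.
#' @export
plot_vm_slice <- function(result, plane = c("xy", "xz", "yz"), at = NULL) {
  plane <- match.arg(plane)
  mesh <- result$mesh
  cen <- (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 7], ]) / 2 * 1e6
  ax <- switch(plane, xy = 3L, xz = 2L, yz = 1L)
  keep <- switch(plane, xy = c(1L, 2L), xz = c(1L, 3L), yz = c(2L, 3L))
  if (is.null(at)) at <- stats::median(cen[, ax])
  layer <- abs(cen[, ax] - at) <= min(mesh$h_um) / 1.999
  if (!any(layer)) layer <- abs(cen[, ax] - at) <= min(abs(cen[, ax] - at)) + 1e-9
  df <- tibble::tibble(
    a = cen[layer, keep[1]], b = cen[layer, keep[2]],
    von_mises = result$stress$von_mises[layer])
  labs <- c("x [um]", "y [um]", "z [um]")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$von_mises)) +
    ggplot2::geom_tile(width = mesh$h_um[keep[1]], height = mesh$h_um[keep[2]]) +
    ggplot2::scale_fill_viridis_c(name = "von Mises [Pa]") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = labs[keep[1]], y = labs[keep[2]],
                  title = sprintf("%s case, %s slice at %.0f um",
                                  result$case$kind, plane, at)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
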