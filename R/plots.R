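#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a structural-space growth curve
#'
#' Cumulative number of non-redundant fragments per year; a plateau
#' signals that newly deposited structures add essentially nothing beyond
#' the novelty radius of known conformers.
#'
#' @param object A `growth_series` from [build_yearly_library()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.growth_series <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$year, y = .data$cumulative)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Release year",
      y = "Cumulative non-redundant fragments",
      title = sprintf("Fragment growth, frame %s (k = %s)",
                      object$frame, object$k),
      subtitle = sprintf("fine %.2g Å / novelty %.2g Å",
                         object$fine_threshold, object$novelty_threshold)) +
    ggplot2::theme_minimal()
}

#' Plot an RMSD-versus-RMSD density scatter
#'
#' @param object An `rmsd_correlation` from [rmsd_correlation()].
#' @param bins Number of bins per axis for the 2-d histogram.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rmsd_correlation <- function(object, bins = 60, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$rmsd_a, y = .data$rmsd_b)) +
    ggplot2::geom_bin2d(bins = bins) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = sprintf("RMSD, %s (Å)", object$frame_a),
      y = sprintf("RMSD, %s (Å)", object$frame_b),
      title = sprintf("PCC = %.3f (%d pairs)", object$pcc, object$n_pairs)) +
    ggplot2::theme_minimal()
}

#' Plot pseudo-torsion (eta, theta) occupancy
#'
#' @param torsions Tibble with `eta` and `theta` columns (degrees), e.g.
#'   from [pseudo_torsions()].
#' @param bin_width Grid cell width in degrees.
#' @return A ggplot of the occupied grid.
#' @export
plot_pseudo_torsion_grid <- function(torsions, bin_width = 5) {
  ggplot2::ggplot(torsions, ggplot2::aes(x = .data$eta, y = .data$theta)) +
    ggplot2::geom_bin2d(binwidth = c(bin_width, bin_width)) +
    ggplot2::coord_cartesian(xlim = c(-180, 180), ylim = c(-180, 180)) +
    ggplot2::labs(x = "η (degrees)", y = "θ (degrees)") +
    ggplot2::theme_minimal()
}
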