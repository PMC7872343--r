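#' Plot a simulation grid report
#'
#' Diagnosis percentages against the equicorrelation level, one line per
#' (rule, category).  The WHO lines move with the correlation while the
#' ellipsoid lines are flat — the central contrast of the simulation
#' study.
#'
#' @param object A `table3_report` from [run_table3()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.table3_report <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$rho, y = .data$pct,
                               colour = .data$rule)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$category), scales = "free_y") +
    ggplot2::labs(x = "equicorrelation between sites",
                  y = "patients (%)", colour = "rule") +
    ggplot2::theme_minimal()
}

#' Pairwise T-score scatter with both diagnoses
#'
#' Scatter of two of the three T-scores for a classified cohort, coloured
#' by one rule's diagnosis, with the univariate WHO thresholds drawn as
#' reference lines.  A quick visual of how the ellipsoid rule cuts across
#' the axis-aligned WHO boxes.
#'
#' @param classified Output of [classify_cohort()].
#' @param x,y Which T-score columns to plot (defaults `t_fneck`,
#'   `t_thip`).
#' @param colour `"ellipsoid_dx"` (default) or `"who_dx"`.
#' @return A ggplot object.
#' @export
plot_cohort <- function(classified, x = "t_fneck", y = "t_thip",
                        colour = c("ellipsoid_dx", "who_dx")) {
  colour <- match.arg(colour)
  if (!colour %in% names(classified)) {
    abort(sprintf("Column `%s` not found; run classify_cohort() first.", colour))
  }
  ggplot2::ggplot(classified,
                  ggplot2::aes(x = .data[[x]], y = .data[[y]],
                               colour = .data[[colour]])) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-2.5, -1), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(-2.5, -1), linetype = "dashed") +
    ggplot2::labs(x = x, y = y, colour = sub("_dx$", " rule", colour)) +
    ggplot2::theme_minimal()
}

#' Plot an ellipsoid boundary projection
#'
#' Projects an [ellipsoid_mesh()] onto a coordinate plane; useful as a
#' text-friendly stand-in for a full 3-D rendering.
#'
#' @param mesh Output of [ellipsoid_mesh()].
#' @param plane Which coordinate plane: `"xy"`, `"xz"` or `"yz"`.
#' @return A ggplot object.
#' @export
plot_ellipsoid <- function(mesh, plane = c("xy", "xz", "yz")) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  ggplot2::ggplot(mesh, ggplot2::aes(x = .data[[ax[1]]],
                                     y = .data[[ax[2]]])) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0("T-score (", ax[1], ")"),
                  y = paste0("T-score (", ax[2], ")")) +
    ggplot2::theme_minimal()
}
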