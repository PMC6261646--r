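# ggplot2 views of the result objects

#' @describeIn survey_fractions Bar chart of the category percentages.
#' @param object A `tmd_survey` object.
#' @export
autoplot.tmd_survey <- function(object, ...) {
  ggplot2::ggplot(object$fractions,
                  ggplot2::aes(x = .data$category, y = .data$percent)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "% of proteins",
                  title = "Intramembrane basic-residue content") +
    ggplot2::theme_minimal()
}

#' Plot the border-distance histogram of a survey
#'
#' @param survey A `tmd_survey` object (see [survey_fractions()]).
#' @param counting `"residues"` (one entry per basic residue) or
#'   `"proteins"` (distinct proteins per distance).
#' @return A ggplot.
#' @export
plot_border_histogram <- function(survey, counting = c("residues", "proteins")) {
  counting <- match.arg(counting)
  col <- if (counting == "residues") "n_residues" else "n_proteins"
  ggplot2::ggplot(survey$histogram,
                  ggplot2::aes(x = .data$border_distance, y = .data[[col]],
                               fill = .data$residue)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "distance from TMD/CD border", y = counting,
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn csp Per-residue CSP bar chart.
#' @param object A `csp_profile`.
#' @param ... Unused.
#' @export
autoplot.csp_profile <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object), resno = residue_number(.data$residue))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resno, y = .data$csp)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "residue", y = expression(Delta * delta ~ "(ppm)")) +
    ggplot2::theme_minimal()
}

#' @describeIn intensity_ratio Per-residue I/I0 profile.
#' @param object A `ratio_profile`.
#' @param ... Unused.
#' @export
autoplot.ratio_profile <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object), resno = residue_number(.data$residue))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$resno, y = .data$ratio))
  if ("class" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$class))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "residue", y = expression(I / I[0])) +
    ggplot2::theme_minimal()
}

#' @describeIn double_ratio Per-residue scatter of R_D/R_M by Ca level.
#' @param object A `double_ratio_profile`.
#' @param ... Unused.
#' @export
autoplot.double_ratio_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(round(.data$ca_ratio, 3)),
                                   y = .data$double_ratio)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "Ca : phospholipid ratio",
                  y = expression(R[D] / R[M])) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_indo_calibration Standard points with the fitted curve.
#' @param object An `indo_calibration`.
#' @export
autoplot.indo_calibration <- function(object, ...) {
  pts <- object$points[object$points$free_ca > 0, ]
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$free_ca, y = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression("free" ~ Ca^{"2+"} ~ "(uM)"),
                  y = "F405/F485") +
    ggplot2::theme_minimal()
  if (object$model == "ratiometric") {
    grid <- tibble(free_ca = exp(seq(log(min(pts$free_ca)),
                                     log(max(pts$free_ca)), length.out = 100)))
    grid$ratio <- indo_ratio(grid$free_ca, object)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}

#' @describeIn project_xy Raster view of the xy density map, optionally with
#'   a protein C-alpha overlay.
#' @param object An `sdf_map`.
#' @param ca_points Optional tibble from [project_protein_ca()] to overlay.
#' @param ... Unused.
#' @export
autoplot.sdf_map <- function(object, ca_points = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (A)", y = "y (A)",
                  fill = if (object$normalized) "probability" else "mean count") +
    ggplot2::theme_minimal()
  if (!is.null(ca_points)) {
    p <- p + ggplot2::geom_point(data = ca_points,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 inherit.aes = FALSE, colour = "white",
                                 size = 0.8)
  }
  p
}
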