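#' Cohort result plots
#'
#' Scatter plots of the per-set audit endpoints in the usual audit-report
#' layout: measured source-position shifts with +/-3 and +/-5 mm action
#' lines and the film-derived error bars, and dose ratios
#' (D_IAEA / D_user) with +/-3 % and +/-5 % lines, the cohort mean, and
#' the measurement-uncertainty band.
#'
#' @param records Audit records, see [dose_ratio()].
#' @param uncertainty_pct Overall dose measurement uncertainty shown as
#'   error bars on the ratio plot (%, k = 1).
#' @return A ggplot object.
#' @export
plot_cohort_shifts <- function(records) {
  res <- dose_ratio(records) |>
    dplyr::arrange(.data$mean_shift_mm) |>
    dplyr::mutate(set = dplyr::row_number())
  ggplot2::ggplot(res, ggplot2::aes(x = .data$set, y = .data$mean_shift_mm)) +
    ggplot2::geom_hline(yintercept = c(-3, 3), colour = "orange") +
    ggplot2::geom_hline(yintercept = c(-5, 5), colour = "red") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_shift_mm - .data$shift_u_mm,
                   ymax = .data$mean_shift_mm + .data$shift_u_mm),
      width = 0, colour = "grey55"
    ) +
    ggplot2::geom_point(shape = 18, size = 2.4) +
    ggplot2::labs(x = "Dosimeter set (ordered)",
                  y = "Source position shift [mm]",
                  title = "Film-measured source position shifts") +
    ggplot2::theme_minimal()
}

#' @rdname plot_cohort_shifts
#' @export
plot_cohort_ratios <- function(records, uncertainty_pct = 2.24) {
  res <- dose_ratio(records) |>
    dplyr::arrange(.data$dose_ratio) |>
    dplyr::mutate(set = dplyr::row_number())
  u <- uncertainty_pct / 100
  ggplot2::ggplot(res, ggplot2::aes(x = .data$set, y = .data$dose_ratio)) +
    ggplot2::geom_hline(yintercept = 1 + c(-0.03, 0.03), colour = "orange") +
    ggplot2::geom_hline(yintercept = 1 + c(-0.05, 0.05), colour = "red") +
    ggplot2::geom_hline(yintercept = mean(res$dose_ratio),
                        linetype = "dashed", colour = "blue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$dose_ratio * (1 - u),
                   ymax = .data$dose_ratio * (1 + u)),
      width = 0, colour = "grey55"
    ) +
    ggplot2::geom_point(shape = 1, size = 2.2) +
    ggplot2::labs(x = "Dosimeter set (ordered)",
                  y = expression(D[IAEA] / D[user]),
                  title = "Audit dose ratios") +
    ggplot2::theme_minimal()
}

#' Dose profile of a reference plan along the dosimeter axis
#'
#' Plots the accumulated dose along x through the phantom centre, showing
#' the low-gradient region the plan is designed to create over the RPLD
#' sensitive volume.
#'
#' @param object A `ref_plan`.
#' @param span_mm Half-width of the profile (mm).
#' @param step_mm Profile sampling step (mm).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ref_plan <- function(object, span_mm = 20, step_mm = 0.25, ...) {
  x <- seq(-span_mm, span_mm, by = step_mm)
  prof <- accumulate_dose(
    tibble::tibble(x_mm = x, y_mm = 0, z_mm = 0),
    object$dwells, object$source, object$rakr
  )
  hl <- object$geometry$sensitive_length_mm / 2
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$x_mm, y = .data$dose_Gy)) +
    ggplot2::annotate("rect", xmin = -hl, xmax = hl, ymin = -Inf, ymax = Inf,
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$prescription_Gy,
                        linetype = "dotted") +
    ggplot2::labs(x = "x [mm]", y = "Dose [Gy]",
                  title = "Central-axis dose profile",
                  subtitle = "Shaded: RPLD sensitive volume") +
    ggplot2::theme_minimal()
}

#' Film strip with detected track and fiducial
#'
#' Raster view of a film with the detected track edges, midpoint and the
#' fiducial overlaid.
#'
#' @param object A [film_image()].
#' @param ... Passed to [detect_track()].
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.film_image <- function(object, ...) {
  track <- tryCatch(detect_track(object, ...), error = function(e) NULL)
  df <- tidyr::expand_grid(
    row = seq_len(nrow(object$pixels)),
    col = seq_len(ncol(object$pixels))
  )
  df$value <- as.vector(t(object$pixels))
  mmpp <- 25.4 / object$dpi
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col * mmpp,
                                        y = .data$row * mmpp,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "grey10", high = "grey95",
                                 guide = "none") +
    ggplot2::geom_vline(xintercept = object$fiducial_col * mmpp,
                        colour = "blue", linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Along catheter [mm]", y = "[mm]") +
    ggplot2::theme_minimal()
  if (!is.null(track)) {
    p <- p + ggplot2::geom_vline(
      xintercept = c(track$proximal_edge_mm, track$distal_edge_mm,
                     track$midpoint_mm) + mmpp,
      colour = c("red", "red", "orange")
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
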