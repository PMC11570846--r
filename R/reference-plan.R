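#' Audit phantom geometry
#'
#' Geometry of the compact PMMA audit phantom: a 160 x 80 x 30 mm block with
#' two parallel catheter channels 40 mm apart running along x, and a
#' cylindrical glass dosimeter (RPLD, 12 mm x 1.5 mm diameter) at the
#' centre, between the channels. The coordinate origin is the centre of the
#' RPLD sensitive volume, which is also the plan control point; catheters
#' lie at y = +/-20 mm, z = 0. The sensitive length of the glass rod is
#' configurable (default 6 mm) since it is shorter than the physical rod.
#'
#' @param outer_mm Outer dimensions (mm).
#' @param channel_separation_mm Distance between the two channels (mm).
#' @param rpld_length_mm Physical dosimeter rod length (mm).
#' @param rpld_diameter_mm Dosimeter rod diameter (mm).
#' @param sensitive_length_mm Length of the sensitive volume (mm).
#' @return A `phantom_geometry` list.
#' @export
phantom_geometry <- function(outer_mm = c(160, 80, 30),
                             channel_separation_mm = 40,
                             rpld_length_mm = 12,
                             rpld_diameter_mm = 1.5,
                             sensitive_length_mm = 6) {
  stopifnot(
    channel_separation_mm > rpld_diameter_mm,
    sensitive_length_mm <= rpld_length_mm,
    sensitive_length_mm > 0
  )
  structure(
    list(
      outer_mm = outer_mm,
      channel_separation_mm = channel_separation_mm,
      rpld_length_mm = rpld_length_mm,
      rpld_diameter_mm = rpld_diameter_mm,
      sensitive_length_mm = sensitive_length_mm
    ),
    class = "phantom_geometry"
  )
}

#' Dwell positions of the standardized two-catheter audit plan
#'
#' 13 dwell positions per catheter at a 5 mm step, centred on the control
#' point: x in {-30, -25, ..., +30} mm on each of the two catheters at
#' y = +/- separation/2.
#'
#' @param n_per_catheter Dwells per catheter (odd, so the span is centred).
#' @param step_mm Step size between consecutive dwells (mm).
#' @param channel_separation_mm Catheter separation (mm).
#' @return Tibble with columns `catheter`, `x_mm`, `y_mm`, `z_mm`.
#' @export
reference_dwell_positions <- function(n_per_catheter = 13, step_mm = 5,
                                      channel_separation_mm = 40) {
  stopifnot(n_per_catheter >= 1, step_mm > 0)
  half <- (n_per_catheter - 1) / 2
  x <- (seq_len(n_per_catheter) - 1 - half) * step_mm
  tidyr::expand_grid(
    catheter = c(1L, 2L),
    x_mm = x
  ) |>
    dplyr::mutate(
      y_mm = ifelse(.data$catheter == 1L, 1, -1) * channel_separation_mm / 2,
      z_mm = 0
    )
}

#' Build the reference audit plan
#'
#' Solves the single uniform dwell time so that the accumulated TG-43 dose
#' at the control point (the phantom centre) equals the prescription,
#' 2 Gy by default.
#'
#' @param source A [source_dataset()].
#' @param rakr Reference air kerma rate in U (> 0).
#' @param prescription_Gy Prescribed dose at the control point (Gy).
#' @param geometry A [phantom_geometry()].
#' @param n_per_catheter,step_mm Plan layout, see
#'   [reference_dwell_positions()].
#' @return A `ref_plan` object: dwell table with `dwell_time_s`, the
#'   prescription, control point, source and rakr used.
#' @examples
#' plan <- build_reference_plan(brachy_source("toy"), rakr = 40000)
#' plan$uniform_dwell_time_s
#' @export
build_reference_plan <- function(source, rakr, prescription_Gy = 2,
                                 geometry = phantom_geometry(),
                                 n_per_catheter = 13, step_mm = 5) {
  stopifnot(rakr > 0, prescription_Gy > 0)
  dwells <- reference_dwell_positions(
    n_per_catheter = n_per_catheter, step_mm = step_mm,
    channel_separation_mm = geometry$channel_separation_mm
  )
  control <- tibble::tibble(x_mm = 0, y_mm = 0, z_mm = 0)
  # total dose rate at the control point with unit dwell weighting
  rate <- sum(purrr::map_dbl(
    seq_len(nrow(dwells)),
    \(i) dose_rate_at(control, dwells[i, ], source, rakr)
  ))
  if (!is.finite(rate) || rate <= 0) {
    abort("Non-positive total dose rate at the control point.")
  }
  t_h <- prescription_Gy / rate
  structure(
    list(
      dwells = dplyr::mutate(dwells, dwell_time_s = t_h * 3600),
      uniform_dwell_time_s = t_h * 3600,
      prescription_Gy = prescription_Gy,
      control_point = control,
      geometry = geometry,
      source = source,
      rakr = rakr
    ),
    class = "ref_plan"
  )
}

#' @export
print.ref_plan <- function(x, ...) {
  cat("<ref_plan> ", nrow(x$dwells), " dwells (",
      length(unique(x$dwells$catheter)), " catheters), source ",
      x$source$label, ", RAKR ", x$rakr, " U\n", sep = "")
  cat(sprintf("  uniform dwell time: %.2f s; prescription %.3f Gy at the control point\n",
              x$uniform_dwell_time_s, x$prescription_Gy))
  invisible(x)
}

#' Dose metrics over the RPLD sensitive volume
#'
#' Samples the plan dose on a regular Cartesian grid clipped to the
#' cylindrical sensitive volume (axis along x, centred at the origin) and
#' reports minimum, maximum and mean dose. The reference plan is designed
#' so this region sits in a low dose gradient, making the measured dose
#' insensitive to small source-position errors.
#'
#' @param plan A `ref_plan` from [build_reference_plan()].
#' @param sampling_resolution_mm Grid spacing (mm, <= 0.25).
#' @return One-row tibble: `d_min_Gy`, `d_max_Gy`, `d_mean_Gy`, `n_samples`.
#' @export
rpld_dose_metrics <- function(plan, sampling_resolution_mm = 0.1) {
  stopifnot(inherits(plan, "ref_plan"))
  if (sampling_resolution_mm > 0.25) {
    abort("Sampling resolution must be <= 0.25 mm.")
  }
  geom <- plan$geometry
  hl <- geom$sensitive_length_mm / 2
  rad <- geom$rpld_diameter_mm / 2
  ax <- seq(-hl, hl, by = sampling_resolution_mm)
  tr <- seq(-rad, rad, by = sampling_resolution_mm)
  pts <- tidyr::expand_grid(x_mm = ax, y_mm = tr, z_mm = tr) |>
    dplyr::filter(.data$y_mm^2 + .data$z_mm^2 <= rad^2 + 1e-12)
  if (nrow(pts) == 0) abort("Empty sample set for the sensitive volume.")
  dosed <- accumulate_dose(pts, plan$dwells, plan$source, plan$rakr)
  tibble::tibble(
    d_min_Gy = min(dosed$dose_Gy),
    d_max_Gy = max(dosed$dose_Gy),
    d_mean_Gy = mean(dosed$dose_Gy),
    n_samples = nrow(dosed)
  )
}

#' @rdname rpld_dose_metrics
#' @param x A `ref_plan`.
#' @param ... Passed to [rpld_dose_metrics()].
#' @exportS3Method generics::glance
glance.ref_plan <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      n_dwells = nrow(x$dwells),
      uniform_dwell_time_s = x$uniform_dwell_time_s,
      prescription_Gy = x$prescription_Gy,
      rakr_U = x$rakr
    ),
    rpld_dose_metrics(x, ...)
  )
}

#' @exportS3Method generics::tidy
tidy.ref_plan <- function(x, ...) x$dwells
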