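#' TG-43 geometry function
#'
#' Evaluates the TG-43 geometry function G(r, theta): `1/r^2` for the point
#' model, and `beta / (L r sin(theta))` for the line model, where beta is the
#' angle (radians) subtended by the active length at the calculation point.
#' On the source long axis (sin(theta) ~ 0) the line model takes its
#' analytic limit `1 / (r^2 - L^2/4)`.
#'
#' @param r_cm Distance from the source centre in cm (vectorized, > 0).
#' @param theta_deg Polar angle from the source long axis in degrees
#'   (vectorized; recycled against `r_cm`).
#' @param active_length_mm Active length in mm (line model only).
#' @param model `"point"` or `"line"`.
#' @return Geometry function values in cm^-2.
#' @examples
#' geometry_function(2, 90, model = "point") # 0.25
#' geometry_function(1, 90, active_length_mm = 3.5, model = "line")
#' @export
geometry_function <- function(r_cm, theta_deg = 90, active_length_mm = NA_real_,
                              model = c("point", "line")) {
  model <- match.arg(model)
  if (any(r_cm <= 0)) abort("Geometry function undefined at r <= 0.")
  if (model == "point") return(1 / r_cm^2)
  if (!is.finite(active_length_mm) || active_length_mm <= 0) {
    abort("Line geometry requires a positive active length.")
  }
  n <- max(length(r_cm), length(theta_deg))
  r_cm <- rep_len(r_cm, n)
  theta <- rep_len(theta_deg, n) * pi / 180
  L <- active_length_mm / 10 # cm
  z <- r_cm * cos(theta)     # along-axis coordinate
  rho <- r_cm * sin(theta)   # off-axis distance
  out <- numeric(n)
  on_axis <- rho < 1e-9 * r_cm
  if (any(!on_axis)) {
    beta <- atan2(z[!on_axis] + L / 2, rho[!on_axis]) -
      atan2(z[!on_axis] - L / 2, rho[!on_axis])
    out[!on_axis] <- beta / (L * rho[!on_axis])
  }
  if (any(on_axis)) {
    r0 <- r_cm[on_axis]
    if (any(r0 <= L / 2)) abort("On-axis point inside the active length.")
    out[on_axis] <- 1 / (r0^2 - L^2 / 4)
  }
  out
}

#' TG-43 dose rate from a single dwell position
#'
#' Computes the TG-43 dose rate
#' \deqn{\dot D(r,\theta) = S_K \Lambda \frac{G(r,\theta)}{G(r_0,\theta_0)}
#'       g(r) F(r,\theta)}
#' at one or more points for a source resting at one dwell position, with
#' the reference point at r0 = 1 cm, theta0 = 90 degrees. The reference air
#' kerma rate (RAKR, in U = uGy m^2 h^-1) is taken as numerically equal to
#' the air-kerma strength S_K, the standard convention for HDR sources. The
#' source long axis is assumed parallel to the catheter (x) axis.
#'
#' @param points Data frame with columns `x_mm`, `y_mm`, `z_mm`.
#' @param dwell Length-3 numeric (mm) or one-row data frame with
#'   `x_mm`, `y_mm`, `z_mm`: the dwell position.
#' @param source A [source_dataset()].
#' @param rakr Reference air kerma rate in U.
#' @return Dose rate in Gy h^-1 at each point.
#' @export
dose_rate_at <- function(points, dwell, source, rakr) {
  points <- as_points(points)
  if (is.data.frame(dwell)) dwell <- unlist(dwell[1, c("x_mm", "y_mm", "z_mm")])
  dx <- (points$x_mm - dwell[[1]]) / 10 # cm
  dy <- (points$y_mm - dwell[[2]]) / 10
  dz <- (points$z_mm - dwell[[3]]) / 10
  r <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(r == 0)) abort("Calculation point coincides with the dwell position.")
  # theta from the source long axis (x)
  theta_deg <- acos(pmin(pmax(dx / r, -1), 1)) * 180 / pi

  G <- geometry_function(r, theta_deg, source$active_length_mm,
                         source$geometry_model)
  G0 <- geometry_function(1, 90, source$active_length_mm,
                          source$geometry_model)
  g <- interpolate_radial(source$radial_dose, r)
  Fa <- interpolate_anisotropy(source$anisotropy, r, theta_deg)
  # cGy/h -> Gy/h
  rakr * source$lambda_cGy_per_h_per_U * (G / G0) * g * Fa / 100
}

#' Accumulate dose over a set of dwell positions
#'
#' Superposes TG-43 dose contributions: the dose at each point is the sum
#' over dwells of dose rate times dwell time (seconds converted to hours).
#'
#' @param points Data frame with columns `x_mm`, `y_mm`, `z_mm`.
#' @param dwells Data frame with columns `x_mm`, `y_mm`, `z_mm`,
#'   `dwell_time_s` (all times finite and >= 0).
#' @param source A [source_dataset()].
#' @param rakr Reference air kerma rate in U.
#' @return The `points` tibble with an added `dose_Gy` column.
#' @examples
#' src <- brachy_source("toy")
#' pts <- data.frame(x_mm = 10, y_mm = 0, z_mm = 0)
#' dws <- data.frame(x_mm = 0, y_mm = 0, z_mm = 0, dwell_time_s = 3600)
#' accumulate_dose(pts, dws, src, rakr = 1)$dose_Gy # 0.01 Gy
#' @export
accumulate_dose <- function(points, dwells, source, rakr) {
  points <- as_points(points)
  stopifnot(all(c("x_mm", "y_mm", "z_mm", "dwell_time_s") %in% names(dwells)))
  if (any(!is.finite(dwells$dwell_time_s)) || any(dwells$dwell_time_s < 0)) {
    abort("Dwell times must be finite and non-negative.")
  }
  dose <- numeric(nrow(points))
  for (i in seq_len(nrow(dwells))) {
    ti <- dwells$dwell_time_s[i]
    if (ti == 0) next
    dose <- dose + dose_rate_at(points, dwells[i, ], source, rakr) * ti / 3600
  }
  dplyr::mutate(points, dose_Gy = dose)
}

as_points <- function(points) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("x_mm", "y_mm", "z_mm") %in% names(points)))
  points
}
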