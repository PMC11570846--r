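#' TG-43 source characterization datasets
#'
#' A `source_dataset` holds the TG-43 characterization of one HDR source
#' model: the dose-rate constant \eqn{\Lambda} (cGy h^-1 U^-1), the active
#' length L (mm), the radial dose function g(r) as an ordered table, and the
#' 2-D anisotropy function F(r, theta) as a grid. The geometry model is
#' either `"point"` (G = 1/r^2) or `"line"` (G = beta / (L r sin theta)).
#'
#' @param label Short name for the dataset.
#' @param radionuclide One of `"Ir-192"`, `"Co-60"`, `"toy"`.
#' @param lambda_cGy_per_h_per_U Dose-rate constant in cGy h^-1 U^-1.
#' @param active_length_mm Active source length in mm (required for the line
#'   geometry model).
#' @param geometry_model `"point"` or `"line"`.
#' @param radial_dose Data frame with columns `r_cm` (strictly increasing,
#'   positive) and `g` (unitless); must contain g(1 cm) = 1.
#' @param anisotropy List with numeric vectors `r_cm`, `theta_deg` and a
#'   matrix `F` of dimension `length(r_cm) x length(theta_deg)`; the column
#'   at theta = 90 degrees must be 1 for all radii.
#' @param provenance Free-text provenance note stored with the dataset.
#'
#' @return An object of class `source_dataset`.
#' @seealso [brachy_source()] for the bundled datasets,
#'   [read_source_dataset()] for the JSON interchange format.
#' @export
source_dataset <- function(label,
                           radionuclide = c("Ir-192", "Co-60", "toy"),
                           lambda_cGy_per_h_per_U,
                           active_length_mm = NA_real_,
                           geometry_model = c("point", "line"),
                           radial_dose,
                           anisotropy = NULL,
                           provenance = "") {
  radionuclide <- match.arg(radionuclide)
  geometry_model <- match.arg(geometry_model)
  radial_dose <- tibble::as_tibble(radial_dose)

  if (!all(c("r_cm", "g") %in% names(radial_dose)) || nrow(radial_dose) == 0) {
    abort("`radial_dose` must be a non-empty table with columns r_cm and g.")
  }
  if (any(radial_dose$r_cm <= 0) || is.unsorted(radial_dose$r_cm, strictly = TRUE)) {
    abort("`radial_dose$r_cm` must be positive and strictly increasing.")
  }
  g1 <- radial_dose$g[match(1, radial_dose$r_cm)]
  if (is.na(g1) || abs(g1 - 1) > 1e-9) {
    abort("The radial dose table must contain g(1 cm) = 1 exactly.")
  }
  if (!is.finite(lambda_cGy_per_h_per_U) || lambda_cGy_per_h_per_U <= 0) {
    abort("`lambda_cGy_per_h_per_U` must be positive.")
  }
  if (geometry_model == "line") {
    if (!is.finite(active_length_mm) || active_length_mm <= 0) {
      abort("Line geometry requires a positive `active_length_mm`.")
    }
  }
  if (!is.null(anisotropy)) {
    stopifnot(
      is.numeric(anisotropy$r_cm), is.numeric(anisotropy$theta_deg),
      is.matrix(anisotropy$F),
      nrow(anisotropy$F) == length(anisotropy$r_cm),
      ncol(anisotropy$F) == length(anisotropy$theta_deg)
    )
    i90 <- match(90, anisotropy$theta_deg)
    if (is.na(i90) || any(abs(anisotropy$F[, i90] - 1) > 1e-9)) {
      abort("The anisotropy grid must contain theta = 90 deg with F = 1 for all radii.")
    }
  }

  structure(
    list(
      label = label,
      radionuclide = radionuclide,
      lambda_cGy_per_h_per_U = lambda_cGy_per_h_per_U,
      active_length_mm = active_length_mm,
      geometry_model = geometry_model,
      radial_dose = radial_dose,
      anisotropy = anisotropy,
      provenance = provenance
    ),
    class = "source_dataset"
  )
}

#' @export
print.source_dataset <- function(x, ...) {
  cat("<source_dataset> ", x$label, " (", x$radionuclide, ", ",
      x$geometry_model, " geometry)\n", sep = "")
  cat("  Lambda: ", x$lambda_cGy_per_h_per_U, " cGy/h/U",
      if (x$geometry_model == "line") paste0("; L = ", x$active_length_mm, " mm"),
      "\n", sep = "")
  cat("  g(r): ", nrow(x$radial_dose), " radii [",
      min(x$radial_dose$r_cm), ", ", max(x$radial_dose$r_cm), "] cm; ",
      if (is.null(x$anisotropy)) "F = 1 (isotropic)" else
        paste0("F grid ", length(x$anisotropy$r_cm), " x ",
               length(x$anisotropy$theta_deg)),
      "\n", sep = "")
  invisible(x)
}

#' Load a bundled source dataset
#'
#' Three datasets ship with the package: `"toy"` (unit-strength point source
#' with g = F = 1, used for analytically tractable checks), and generic
#' `"ir192"` / `"co60"` line sources with smooth consensus-style g(r) and
#' F(r, theta) tables. The Ir/Co tables are synthetic stand-ins assembled to
#' look like published consensus data for miniature HDR sources; they are not
#' the characterization of any commercial model (no such tables are bundled
#' with real provenance), and each file says so in its `provenance` field.
#'
#' @param name One of `"toy"`, `"ir192"`, `"co60"`.
#' @return A [source_dataset()].
#' @examples
#' src <- brachy_source("toy")
#' src
#' @export
brachy_source <- function(name = c("toy", "ir192", "co60")) {
  name <- match.arg(name)
  file <- c(
    toy = "toy_point_synthetic.json",
    ir192 = "ir192_generic_synthetic.json",
    co60 = "co60_generic_synthetic.json"
  )[[name]]
  read_source_dataset(system.file("extdata", file, package = "brachyaudit",
                                  mustWork = TRUE))
}

#' Read a source dataset from JSON
#'
#' The interchange format is a JSON object with keys `label`,
#' `radionuclide`, `lambda_cGy_per_h_per_U`, `active_length_mm`,
#' `geometry_model`, `radial_dose` (array of `[r_cm, g]` pairs) and
#' optionally `anisotropy` (`r_cm`, `theta_deg`, row-major matrix `F`).
#' The file is validated on load.
#'
#' @param path Path to the JSON file.
#' @return A [source_dataset()].
#' @export
read_source_dataset <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  rd <- x$radial_dose
  if (is.matrix(rd)) rd <- tibble::tibble(r_cm = rd[, 1], g = rd[, 2])
  aniso <- NULL
  if (!is.null(x$anisotropy)) {
    Fm <- x$anisotropy$F
    if (is.list(Fm)) Fm <- do.call(rbind, Fm)
    aniso <- list(
      r_cm = as.numeric(x$anisotropy$r_cm),
      theta_deg = as.numeric(x$anisotropy$theta_deg),
      F = matrix(as.numeric(t(Fm)), nrow = length(x$anisotropy$r_cm),
                 byrow = TRUE)
    )
  }
  source_dataset(
    label = x$label,
    radionuclide = x$radionuclide,
    lambda_cGy_per_h_per_U = x$lambda_cGy_per_h_per_U,
    active_length_mm = x$active_length_mm %||% NA_real_,
    geometry_model = x$geometry_model,
    radial_dose = rd,
    anisotropy = aniso,
    provenance = x$provenance %||% ""
  )
}

#' Write a source dataset to JSON
#'
#' @param source A [source_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_source_dataset <- function(source, path) {
  x <- list(
    label = source$label,
    radionuclide = source$radionuclide,
    lambda_cGy_per_h_per_U = source$lambda_cGy_per_h_per_U,
    active_length_mm = source$active_length_mm,
    geometry_model = source$geometry_model,
    provenance = source$provenance,
    radial_dose = unname(as.matrix(source$radial_dose[, c("r_cm", "g")]))
  )
  if (!is.null(source$anisotropy)) {
    x$anisotropy <- list(
      r_cm = source$anisotropy$r_cm,
      theta_deg = source$anisotropy$theta_deg,
      F = apply(source$anisotropy$F, 1, identity, simplify = FALSE)
    )
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Interpolate a radial dose function table
#'
#' Linear interpolation in r inside the tabulated range; outside the range
#' (up to a guard band of r_min/1.2 to r_max * 1.2) the nearest tabulated
#' value is used and a warning is raised, since extrapolating dose functions
#' is unsafe.
#'
#' @param table Data frame with columns `r_cm` and `g` (or any value column
#'   as the second column).
#' @param r Radii in cm (vectorized).
#' @return Interpolated values, same length as `r`.
#' @examples
#' tab <- data.frame(r_cm = c(1, 2), g = c(1.0, 0.9))
#' interpolate_radial(tab, 1.5) # 0.95
#' @export
interpolate_radial <- function(table, r) {
  if (is.null(table) || nrow(table) == 0) {
    abort("Empty radial table.")
  }
  rt <- table[[1]]
  vt <- table[[2]]
  if (any(r < min(rt) / 1.2 - 1e-12) || any(r > max(rt) * 1.2 + 1e-12)) {
    abort("Radius outside the supported range of the table (guard band 1.2x).")
  }
  if (any(r < min(rt) | r > max(rt))) {
    warn("Radius outside tabulated range; clamping to nearest tabulated value.")
  }
  if (length(rt) == 1) return(rep(vt, length(r)))
  stats::approx(rt, vt, xout = pmin(pmax(r, min(rt)), max(rt)),
                method = "linear", rule = 2)$y
}

# Bilinear interpolation of F(r, theta); clamps to the grid hull.
interpolate_anisotropy <- function(aniso, r, theta_deg) {
  if (is.null(aniso)) return(rep(1, length(r)))
  rg <- aniso$r_cm
  tg <- aniso$theta_deg
  Fm <- aniso$F
  r <- pmin(pmax(r, min(rg)), max(rg))
  theta_deg <- pmin(pmax(theta_deg, min(tg)), max(tg))
  if (length(rg) == 1) {
    ir <- rep(1L, length(r)); fr <- rep(0, length(r))
  } else {
    ir <- pmin(pmax(findInterval(r, rg, rightmost.closed = TRUE), 1), length(rg) - 1)
    fr <- (r - rg[ir]) / (rg[ir + 1] - rg[ir])
  }
  if (length(tg) == 1) {
    it <- rep(1L, length(theta_deg)); ft <- rep(0, length(theta_deg))
  } else {
    it <- pmin(pmax(findInterval(theta_deg, tg, rightmost.closed = TRUE), 1), length(tg) - 1)
    ft <- (theta_deg - tg[it]) / (tg[it + 1] - tg[it])
  }
  ir2 <- pmin(ir + 1L, length(rg))
  it2 <- pmin(it + 1L, length(tg))
  f00 <- Fm[cbind(ir, it)]
  f01 <- Fm[cbind(ir, it2)]
  f10 <- Fm[cbind(ir2, it)]
  f11 <- Fm[cbind(ir2, it2)]
  (1 - fr) * (1 - ft) * f00 + (1 - fr) * ft * f01 +
    fr * (1 - ft) * f10 + fr * ft * f11
}
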