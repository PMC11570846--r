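#' Radiochromic film strip image
#'
#' In-memory representation of a scanned radiochromic (RTQA2-style) film
#' strip used for source-position verification: a grayscale raster in
#' [0, 1] (reflective scan, so darker = more dose = lower pixel value),
#' its scan resolution, the along-catheter axis, the fiducial mark that
#' indicates the centre of the RPLD sensitive volume, and the direction of
#' the proximal end (towards the afterloader).
#'
#' @param pixels Numeric matrix in [0, 1]; rows run across the strip,
#'   columns along the catheter axis.
#' @param dpi Scan resolution in dots per inch (> 0; 300 nominal).
#' @param fiducial_col Column coordinate (pixels, may be fractional) of the
#'   fiducial mark along the axis.
#' @param proximal `"right"` if increasing column index points towards the
#'   afterloader, else `"left"`.
#' @return A `film_image` object.
#' @export
film_image <- function(pixels, dpi = 300, fiducial_col,
                       proximal = c("right", "left")) {
  proximal <- match.arg(proximal)
  stopifnot(is.matrix(pixels), dpi > 0)
  if (fiducial_col < 1 || fiducial_col > ncol(pixels)) {
    abort("Fiducial must lie inside the image bounds.")
  }
  structure(
    list(pixels = pixels, dpi = dpi, fiducial_col = fiducial_col,
         proximal = proximal),
    class = "film_image"
  )
}

#' @export
print.film_image <- function(x, ...) {
  cat(sprintf("<film_image> %d x %d px at %g dpi (%.1f x %.1f mm), fiducial at col %.1f, proximal %s\n",
              nrow(x$pixels), ncol(x$pixels), x$dpi,
              nrow(x$pixels) * 25.4 / x$dpi, ncol(x$pixels) * 25.4 / x$dpi,
              x$fiducial_col, x$proximal))
  invisible(x)
}

px_to_mm <- function(px, dpi) px * 25.4 / dpi

#' Detect the source track on a film strip
#'
#' Builds a per-column darkening profile (mean over rows of
#' `background - pixel`), locates the darkened band left by the stepping
#' source, and places its proximal and distal edges at 50 % of the
#' profile's plateau height with sub-pixel linear interpolation. Positions
#' are reported in mm along the axis (column 1 = 0 mm), converted at
#' 25.4 / dpi mm per pixel.
#'
#' @param film A [film_image()].
#' @param contrast_min Minimum plateau-over-background darkening (in pixel
#'   value units) required to accept a track.
#' @return One-row tibble: `proximal_edge_mm`, `distal_edge_mm`,
#'   `midpoint_mm` (class `track_measurement`).
#' @export
detect_track <- function(film, contrast_min = 0.05) {
  stopifnot(inherits(film, "film_image"))
  profile <- colMeans(film$pixels)
  # background = brightest (least-darkened) region; plateau = darkest
  baseline <- quantile(profile, 0.85, names = FALSE)
  plateau <- quantile(profile, 0.10, names = FALSE)
  contrast <- baseline - plateau
  if (!is.finite(contrast) || contrast < contrast_min) {
    abort("no track detected")
  }
  net <- baseline - profile # darkening, >= 0 on the track
  thr <- contrast / 2
  above <- net >= thr
  idx <- which(above)
  left <- cross_subpixel(net, min(idx), thr, side = "left")
  right <- cross_subpixel(net, max(idx), thr, side = "right")
  edges_mm <- px_to_mm(c(left, right) - 1, film$dpi)
  # proximal edge is the one nearer the afterloader
  prox_first <- film$proximal == "left"
  out <- tibble::tibble(
    proximal_edge_mm = if (prox_first) edges_mm[1] else edges_mm[2],
    distal_edge_mm = if (prox_first) edges_mm[2] else edges_mm[1],
    midpoint_mm = mean(edges_mm)
  )
  class(out) <- c("track_measurement", class(out))
  out
}

# Linear sub-pixel crossing of `thr` at the boundary of the above-threshold
# run starting/ending at index i.
cross_subpixel <- function(net, i, thr, side = c("left", "right")) {
  side <- match.arg(side)
  j <- if (side == "left") i - 1L else i + 1L
  if (j < 1L || j > length(net)) return(i)
  frac <- (net[i] - thr) / (net[i] - net[j])
  if (!is.finite(frac)) frac <- 0
  i + (j - i) * frac
}

#' Source-position shift of a detected track
#'
#' The measured shift is the track bisection (midpoint) minus the fiducial
#' position marking the centre of the RPLD sensitive volume, signed so that
#' positive means towards the proximal end of the catheter (towards the
#' afterloader).
#'
#' @param track A `track_measurement` from [detect_track()].
#' @param fiducial_mm Fiducial position in mm along the axis.
#' @param proximal `"right"` or `"left"`: the direction of the proximal
#'   end along increasing mm.
#' @return Signed shift in mm.
#' @export
measure_shift <- function(track, fiducial_mm, proximal = c("right", "left")) {
  proximal <- match.arg(proximal)
  raw <- track$midpoint_mm - fiducial_mm
  if (proximal == "left") raw <- -raw
  raw
}

#' Analyze a film strip end to end
#'
#' Runs [detect_track()] and [measure_shift()] using the film's own
#' fiducial and proximal-direction metadata.
#'
#' @param film A [film_image()].
#' @param contrast_min Passed to [detect_track()].
#' @return One-row tibble with the track edges, midpoint and `shift_mm`.
#' @export
analyze_film <- function(film, contrast_min = 0.05) {
  track <- detect_track(film, contrast_min = contrast_min)
  fid_mm <- px_to_mm(film$fiducial_col - 1, film$dpi)
  dplyr::mutate(track,
                shift_mm = measure_shift(track, fid_mm, film$proximal))
}

#' Combine the two film measurements of an audit set
#'
#' Each audit set exposes two films in two separate deliveries; their
#' measured shifts are averaged. The position uncertainty combines the
#' fixed uncertainty of the film analysis procedure (0.3 mm, Type B
#' floor) with the sample SD of the two measurements in quadrature, so
#' it can never fall below 0.3 mm.
#'
#' @param shift1_mm,shift2_mm The two film shifts (mm; vectorized
#'   pairwise).
#' @param procedure_u_mm Fixed analysis-procedure uncertainty (mm).
#' @return Tibble with `mean_shift_mm` and `u_mm` (k = 1).
#' @examples
#' combine_films(1.0, 2.0) # 1.5 +/- 0.768 mm
#' @export
combine_films <- function(shift1_mm, shift2_mm, procedure_u_mm = 0.3) {
  s <- abs(shift1_mm - shift2_mm) / sqrt(2) # sample SD of two values
  tibble::tibble(
    mean_shift_mm = (shift1_mm + shift2_mm) / 2,
    u_mm = sqrt(procedure_u_mm^2 + s^2)
  )
}

#' Classify a source-position shift against the audit tolerances
#'
#' Audit action levels are +/- 3 mm (optimal) and +/- 5 mm (acceptable);
#' boundary values are classified inclusively ("within"). The direction
#' flag reports whether the shift is towards the proximal (positive) or
#' distal (negative) end.
#'
#' @param shift_mm Mean shift(s) in mm.
#' @return Tibble with `shift_mm`, `class` (factor: `within_3mm`,
#'   `within_5mm`, `beyond_5mm`) and `direction` (`proximal`, `distal`,
#'   `none`).
#' @export
classify_shift <- function(shift_mm) {
  # inclusive boundaries, robust to floating-point representation
  cls <- dplyr::case_when(
    abs(shift_mm) <= 3 + 1e-9 ~ "within_3mm",
    abs(shift_mm) <= 5 + 1e-9 ~ "within_5mm",
    TRUE ~ "beyond_5mm"
  )
  tibble::tibble(
    shift_mm = shift_mm,
    class = factor(cls, levels = c("within_3mm", "within_5mm", "beyond_5mm")),
    direction = dplyr::case_when(
      shift_mm > 0 ~ "proximal",
      shift_mm < 0 ~ "distal",
      TRUE ~ "none"
    )
  )
}

#' Read / write film strips as PNG with a JSON sidecar
#'
#' The raster goes to a grayscale PNG; dpi, fiducial column and proximal
#' direction go to a JSON sidecar, so simulated films round-trip through
#' the same files a scanner workflow would produce.
#'
#' @param film A [film_image()].
#' @param png_path Path to the PNG raster.
#' @param meta_path Path to the JSON sidecar (default: `png_path` with a
#'   `.json` extension).
#' @return `read_film()` returns a [film_image()]; `write_film()` returns
#'   `png_path` invisibly.
#' @export
write_film <- function(film, png_path, meta_path = NULL) {
  meta_path <- meta_path %||% sub("\\.png$", ".json", png_path)
  png::writePNG(pmin(pmax(film$pixels, 0), 1), png_path)
  jsonlite::write_json(
    list(dpi = film$dpi, fiducial_col = film$fiducial_col,
         proximal = film$proximal),
    meta_path, auto_unbox = TRUE, digits = NA
  )
  invisible(png_path)
}

#' @rdname write_film
#' @export
read_film <- function(png_path, meta_path = NULL) {
  meta_path <- meta_path %||% sub("\\.png$", ".json", png_path)
  px <- png::readPNG(png_path)
  if (length(dim(px)) == 3) px <- px[, , 1] # luminance channel
  meta <- jsonlite::fromJSON(meta_path)
  film_image(px, dpi = meta$dpi, fiducial_col = meta$fiducial_col,
             proximal = meta$proximal)
}
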