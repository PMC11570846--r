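#' Simulate an RPLD measurement set
#'
#' Draws `n` dosimeter readings around a true dose with a stated
#' coefficient of variation. The default noise model is lognormal
#' (readings are strictly positive by construction, matching real glass
#' dosimeter behaviour); a truncated-normal alternative is available.
#' Deterministic for a fixed seed, and leaves the caller's RNG state
#' untouched.
#'
#' @param true_dose_Gy True delivered dose (Gy).
#' @param cv_pct Coefficient of variation in percent (>= 0).
#' @param n Number of dosimeters (>= 2).
#' @param seed Integer seed.
#' @param setup_label Setup tag stored in the output (`A`,
#'   `B_pmma_in_water`, `C_plasticwater_in_water`, `reference_co60`).
#' @param radionuclide Radionuclide tag.
#' @param dist `"lognormal"` or `"truncnorm"`.
#' @return Tibble with columns `setup_label`, `radionuclide`,
#'   `reading_Gy`.
#' @export
simulate_measurement_set <- function(true_dose_Gy, cv_pct, n, seed = 1,
                                     setup_label = "A",
                                     radionuclide = "Ir-192",
                                     dist = c("lognormal", "truncnorm")) {
  dist <- match.arg(dist)
  stopifnot(true_dose_Gy > 0, cv_pct >= 0, n >= 2)
  readings <- withr::with_seed(seed, {
    if (cv_pct == 0) {
      rep(true_dose_Gy, n)
    } else if (dist == "lognormal") {
      cv <- cv_pct / 100
      sdlog <- sqrt(log(1 + cv^2))
      rlnorm(n, meanlog = log(true_dose_Gy) - sdlog^2 / 2, sdlog = sdlog)
    } else {
      x <- rnorm(n, true_dose_Gy, true_dose_Gy * cv_pct / 100)
      pmax(x, .Machine$double.eps)
    }
  })
  tibble::tibble(setup_label = setup_label, radionuclide = radionuclide,
                 reading_Gy = readings)
}

#' Render a synthetic film strip with a known source-track shift
#'
#' Emulates a scanned radiochromic strip from the audit phantom: a
#' 32 x 140 mm raster at the requested dpi, uniformly bright background,
#' and a darkened band along the catheter axis whose midpoint is displaced
#' from the fiducial by a known shift. Track edges follow a logistic
#' profile (finite penumbra) and additive Gaussian pixel noise is applied.
#' The injected shift is returned as the ground truth attribute.
#'
#' @param shift_mm Injected shift of the track midpoint from the fiducial,
#'   positive towards the proximal end (mm).
#' @param dpi Raster resolution (dots per inch).
#' @param track_length_mm Length of the darkened band (mm); 60 mm matches
#'   the 13-dwell, 5 mm step reference plan span.
#' @param noise_sd Gaussian pixel noise SD, in pixel-value units.
#' @param seed Integer seed.
#' @param strip_mm Strip dimensions (across, along) in mm.
#' @param track_width_mm Width of the darkened band across the strip (mm).
#' @param contrast Darkening depth of the track (pixel-value units).
#' @param edge_scale_mm Logistic edge softness (mm).
#' @param proximal Direction of the proximal end along increasing column.
#' @return A [film_image()] with attribute `true_shift_mm`.
#' @export
simulate_film <- function(shift_mm, dpi = 300, track_length_mm = 60,
                          noise_sd = 0.01, seed = 1,
                          strip_mm = c(32, 140), track_width_mm = 8,
                          contrast = 0.4, edge_scale_mm = 0.3,
                          proximal = "right") {
  px_mm <- dpi / 25.4
  nr <- round(strip_mm[1] * px_mm)
  nc <- round(strip_mm[2] * px_mm)
  fid_col <- (nc + 1) / 2
  sgn <- if (proximal == "right") 1 else -1
  centre_col <- fid_col + sgn * shift_mm * px_mm
  half_len_px <- track_length_mm / 2 * px_mm
  if (centre_col - half_len_px < 1 || centre_col + half_len_px > nc) {
    abort("Track does not fit inside the film raster.")
  }
  cols <- seq_len(nc)
  k <- 1 / (edge_scale_mm * px_mm)
  along <- stats::plogis(k * (cols - (centre_col - half_len_px))) *
    stats::plogis(-k * (cols - (centre_col + half_len_px)))
  rows <- seq_len(nr)
  half_w_px <- track_width_mm / 2 * px_mm
  centre_row <- (nr + 1) / 2
  across <- as.numeric(abs(rows - centre_row) <= half_w_px)
  background <- 0.85
  img <- background - contrast * outer(across, along)
  if (noise_sd > 0) {
    img <- img + withr::with_seed(seed, matrix(rnorm(nr * nc, 0, noise_sd), nr, nc))
  }
  film <- film_image(pmin(pmax(img, 0), 1), dpi = dpi,
                     fiducial_col = fid_col, proximal = proximal)
  attr(film, "true_shift_mm") <- shift_mm
  film
}

#' Simulate a multicentre audit cohort
#'
#' Generates per-set audit records by drawing each set's dose ratio
#' (D_IAEA / D_user) and mean source-position shift from normal
#' distributions, then splitting into the observable pairs: two RPLD doses
#' with the stated intra-set relative difference, and two film shifts
#' scattered around the set mean. Defaults reproduce the operating point
#' of a typical international pilot cohort: 59 sets, dose ratio
#' 1.008 +/- 0.014, shift 1.2 +/- 2.5 mm, intra-set RPLD difference
#' 1.6 %.
#'
#' @param n_sets Number of dosimeter sets.
#' @param ratio_mean,ratio_sd Moments of the per-set dose-ratio
#'   distribution.
#' @param shift_mean_mm,shift_sd_mm Moments of the per-set mean-shift
#'   distribution (mm).
#' @param intra_diff_pct Mean absolute relative difference between the two
#'   RPLD doses of one set (%).
#' @param film_sd_mm SD of each film measurement about the set mean (mm).
#' @param d_user_Gy Dose stated by the participating centre (Gy).
#' @param frac_co60 Fraction of sets irradiated with a Co-60 source.
#' @param seed Integer seed.
#' @return Tibble of audit records: `centre_id`, `radionuclide`,
#'   `d_user_Gy`, `rpld1_Gy`, `rpld2_Gy`, `shift1_mm`, `shift2_mm`.
#' @export
simulate_cohort <- function(n_sets = 59, ratio_mean = 1.008,
                            ratio_sd = 0.014, shift_mean_mm = 1.2,
                            shift_sd_mm = 2.5, intra_diff_pct = 1.6,
                            film_sd_mm = 0.3, d_user_Gy = 2,
                            frac_co60 = 14 / 59, seed = 1) {
  stopifnot(n_sets >= 1, ratio_sd >= 0, shift_sd_mm >= 0)
  withr::with_seed(seed, {
    ratio <- rnorm(n_sets, ratio_mean, ratio_sd)
    shift <- rnorm(n_sets, shift_mean_mm, shift_sd_mm)
    # split the set dose into two RPLD doses: half-normal intra-set
    # difference with the requested mean absolute relative difference
    delta <- abs(rnorm(n_sets, 0, intra_diff_pct / 100 * sqrt(pi / 2)))
    sgn <- sample(c(-1, 1), n_sets, replace = TRUE)
    d_set <- ratio * d_user_Gy
    nuclide <- ifelse(seq_len(n_sets) <= round(frac_co60 * n_sets),
                      "Co-60", "Ir-192")
    tibble::tibble(
      centre_id = sprintf("C%03d", seq_len(n_sets)),
      radionuclide = sample(nuclide),
      d_user_Gy = d_user_Gy,
      rpld1_Gy = d_set * (1 + sgn * delta / 2),
      rpld2_Gy = d_set * (1 - sgn * delta / 2),
      shift1_mm = shift + rnorm(n_sets, 0, film_sd_mm),
      shift2_mm = shift + rnorm(n_sets, 0, film_sd_mm)
    )
  })
}
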