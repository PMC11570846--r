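#' Correction factor with standard uncertainty
#'
#' A value +/- standard uncertainty (k = 1) with a kind tag. The kinds are
#' the audit correction factors: `k_s` (lack of full scatter), `k_m`
#' (non-water equivalence of the PMMA phantom), `k_Q` (beam-quality
#' difference from the Co-60 calibration) and `k_tot` (their combination).
#'
#' @param value Factor value (> 0).
#' @param u Standard uncertainty (>= 0, k = 1).
#' @param kind One of `"k_s"`, `"k_m"`, `"k_Q"`, `"k_tot"`.
#' @param provenance `"experimental"`, `"mc"` or `"combined"`.
#' @return A `correction_factor` object.
#' @export
correction_factor <- function(value, u = 0,
                              kind = c("k_s", "k_m", "k_Q", "k_tot"),
                              provenance = c("experimental", "mc", "combined")) {
  kind <- match.arg(kind)
  provenance <- match.arg(provenance)
  if (!is.finite(value) || value <= 0) abort("Factor value must be positive.")
  if (!is.finite(u) || u < 0) abort("Standard uncertainty must be >= 0.")
  structure(list(value = value, u = u, kind = kind, provenance = provenance),
            class = "correction_factor")
}

#' @export
print.correction_factor <- function(x, ...) {
  cat(sprintf("<correction_factor> %s = %.4f +/- %.4f (%s)\n",
              x$kind, x$value, x$u, x$provenance))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.correction_factor <- function(x, ...) {
  tibble::tibble(kind = x$kind, value = x$value, u = x$u,
                 provenance = x$provenance)
}

cf_value <- function(x) if (inherits(x, "correction_factor")) x$value else as.numeric(x)
cf_u <- function(x) if (inherits(x, "correction_factor")) x$u else 0

#' Correction factor as a ratio of two measurement sets
#'
#' Each correction factor is the ratio of mean doses measured by two groups
#' of dosimeters irradiated in two setups: `k_s = D_rp / D_a` (reference
#' scatter over audit setup), `k_m = D_rw / D_rp` (water-equivalent over
#' PMMA phantom), `k_Q = D_ref / D_rw` (Co-60 reference beam over the
#' brachytherapy setup). The value is the ratio of set means; its standard
#' uncertainty propagates the standard errors of the two means in
#' quadrature of relative terms:
#' \deqn{u = v \sqrt{(SEM_n/\bar n)^2 + (SEM_d/\bar d)^2}}
#'
#' @param numerator,denominator Numeric vectors of dose readings (Gy), or
#'   data frames with a `reading_Gy` column. Each needs n >= 2 readings.
#' @param kind Factor kind tag, see [correction_factor()].
#' @param provenance Provenance tag, default `"experimental"`.
#' @return A [correction_factor()].
#' @examples
#' a <- c(2.001, 1.998, 2.003, 2.000)
#' b <- c(2.101, 2.099, 2.104, 2.102)
#' ratio_factor(b, a, kind = "k_s")
#' @export
ratio_factor <- function(numerator, denominator, kind = "k_s",
                         provenance = "experimental") {
  num <- readings_vector(numerator)
  den <- readings_vector(denominator)
  if (length(num) < 2 || length(den) < 2) {
    abort("Both measurement sets need at least two readings (SEM undefined otherwise).")
  }
  if (any(c(num, den) <= 0)) abort("All readings must be positive.")
  m_n <- mean(num); m_d <- mean(den)
  if (m_d == 0) abort("Zero denominator mean.")
  sem_n <- sd(num) / sqrt(length(num))
  sem_d <- sd(den) / sqrt(length(den))
  value <- m_n / m_d
  u <- value * sqrt((sem_n / m_n)^2 + (sem_d / m_d)^2)
  correction_factor(value, u, kind = kind, provenance = provenance)
}

readings_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("reading_Gy" %in% names(x))
    x <- x$reading_Gy
  }
  as.numeric(x)
}

#' Estimate all experimental correction factors from a readings table
#'
#' Convenience wrapper over [ratio_factor()] for a tidy table of dosimeter
#' readings across the four setups: `A` (phantom on table, audit
#' conditions), `B_pmma_in_water` (PMMA phantom submerged),
#' `C_plasticwater_in_water` (near water-equivalent phantom submerged) and
#' `reference_co60` (calibration-beam irradiation). Computes
#' k_s = mean(B)/mean(A), k_m = mean(C)/mean(B), k_Q = mean(ref)/mean(C).
#'
#' @param readings Data frame with columns `setup_label`, `reading_Gy` and
#'   optionally `radionuclide`.
#' @return Tibble with one row per factor: `kind`, `value`, `u`,
#'   `provenance`.
#' @export
estimate_factors <- function(readings) {
  stopifnot(all(c("setup_label", "reading_Gy") %in% names(readings)))
  pull_set <- function(lbl) {
    out <- readings$reading_Gy[readings$setup_label == lbl]
    if (length(out) == 0) abort(paste0("No readings for setup ", lbl, "."))
    out
  }
  a <- pull_set("A")
  b <- pull_set("B_pmma_in_water")
  cc <- pull_set("C_plasticwater_in_water")
  ref <- pull_set("reference_co60")
  dplyr::bind_rows(
    tidy(ratio_factor(b, a, kind = "k_s")),
    tidy(ratio_factor(cc, b, kind = "k_m")),
    tidy(ratio_factor(ref, cc, kind = "k_Q"))
  )
}

#' Combine correction factors into the total audit factor
#'
#' The total correction factor averages the experimental and Monte-Carlo
#' estimates of k_m and k_s and multiplies by the measured k_Q:
#' \deqn{k_{tot} = \frac{k_m^{exp}+k_m^{MC}}{2}\times
#'       \frac{k_s^{exp}+k_s^{MC}}{2}\times k_Q}
#' Each averaged pair carries `u_pair = sqrt(u1^2 + u2^2)/2` (uncorrelated
#' components); the relative uncertainties of the two pair means and of k_Q
#' then combine in quadrature.
#'
#' @param km_exp,km_mc,ks_exp,ks_mc,kQ [correction_factor()] objects or
#'   bare numerics (zero uncertainty).
#' @return A `correction_factor` of kind `"k_tot"`, provenance
#'   `"combined"`.
#' @examples
#' combine_total(0.993, 0.993, 1.054, 1.059, 0.981)$value # ~1.029
#' @export
combine_total <- function(km_exp, km_mc, ks_exp, ks_mc, kQ) {
  vals <- vapply(list(km_exp, km_mc, ks_exp, ks_mc, kQ), cf_value, numeric(1))
  if (any(vals <= 0)) abort("All factors must be positive.")
  us <- vapply(list(km_exp, km_mc, ks_exp, ks_mc, kQ), cf_u, numeric(1))
  km <- (vals[1] + vals[2]) / 2
  ks <- (vals[3] + vals[4]) / 2
  u_km <- sqrt(us[1]^2 + us[2]^2) / 2
  u_ks <- sqrt(us[3]^2 + us[4]^2) / 2
  value <- km * ks * vals[5]
  u <- value * sqrt((u_km / km)^2 + (u_ks / ks)^2 + (us[5] / vals[5])^2)
  correction_factor(value, u, kind = "k_tot", provenance = "combined")
}

#' Compare an experimental factor against a reference value
#'
#' Reports the relative difference of an experimentally determined factor
#' from a reference (typically Monte-Carlo) value, whether it is within a
#' stated percentage tolerance, and whether the difference is covered by
#' the combined expanded (k = 2) uncertainty of the pair.
#'
#' @param exp,ref [correction_factor()] objects of the same kind.
#' @param tolerance_pct Agreement tolerance in percent.
#' @return One-row tibble: `kind`, `exp_value`, `ref_value`, `diff_pct`,
#'   `within_tolerance`, `within_uncertainty`.
#' @export
validate_against_reference <- function(exp, ref, tolerance_pct = 0.5) {
  stopifnot(inherits(exp, "correction_factor"),
            inherits(ref, "correction_factor"))
  if (exp$kind != ref$kind) abort("Cannot compare factors of different kinds.")
  diff_pct <- abs(exp$value / ref$value - 1) * 100
  u_comb <- sqrt(exp$u^2 + ref$u^2)
  tibble::tibble(
    kind = exp$kind,
    exp_value = exp$value,
    ref_value = ref$value,
    diff_pct = diff_pct,
    within_tolerance = diff_pct <= tolerance_pct,
    within_uncertainty = abs(exp$value - ref$value) <= 2 * u_comb
  )
}
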