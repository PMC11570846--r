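#' GUM uncertainty budget
#'
#' An uncertainty budget is a table of named components, each with a
#' relative standard uncertainty in percent (k = 1) and a GUM type tag
#' ("A" statistical, "B" other). Components are treated as uncorrelated.
#'
#' @param components Data frame with columns `name` (unique), `percent`
#'   (>= 0) and optionally `gum_type` ("A"/"B", default "A").
#' @return A tibble of class `uncertainty_budget`.
#' @seealso [default_budget()] for the bundled RPLD audit budget,
#'   [combine_budget()].
#' @export
uncertainty_budget <- function(components) {
  components <- tibble::as_tibble(components)
  stopifnot(all(c("name", "percent") %in% names(components)))
  if (!"gum_type" %in% names(components)) components$gum_type <- "A"
  if (anyDuplicated(components$name)) abort("Component names must be unique.")
  if (any(components$percent < 0)) abort("Uncertainties must be >= 0.")
  if (!all(components$gum_type %in% c("A", "B"))) {
    abort("gum_type must be 'A' or 'B'.")
  }
  class(components) <- c("uncertainty_budget", class(components))
  components
}

#' Bundled RPLD audit uncertainty budget
#'
#' The default measurement uncertainty budget for RPLD-based postal
#' brachytherapy audits: the dosimetry-system components shared with the
#' external-beam audit service (calibration coefficient, dosimeter reading,
#' sensitivity, readout positioning, non-linearity, fading) plus the
#' brachytherapy-specific components (reference air kerma rate, dose
#' calculation over the RPLD volume, and the total correction factor).
#' A single budget is used for both radionuclides, carrying the larger
#' value where they differ.
#'
#' @return An [uncertainty_budget()].
#' @export
default_budget <- function() {
  path <- system.file("extdata", "rpld_budget.csv", package = "brachyaudit",
                      mustWork = TRUE)
  uncertainty_budget(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Combine an uncertainty budget in quadrature
#'
#' Standard GUM combination of uncorrelated relative standard
#' uncertainties: the square root of the sum of squared component
#' percentages.
#'
#' @param budget An [uncertainty_budget()] or compatible data frame with at
#'   least one component.
#' @return Combined relative standard uncertainty in percent (k = 1).
#' @examples
#' combine_budget(data.frame(name = c("a", "b"), percent = c(0.3, 0.4))) # 0.5
#' @export
combine_budget <- function(budget) {
  if (!inherits(budget, "uncertainty_budget")) budget <- uncertainty_budget(budget)
  if (nrow(budget) == 0) abort("Empty uncertainty budget.")
  sqrt(sum(budget$percent^2))
}

#' Expanded uncertainty
#'
#' Scales a combined standard uncertainty by a coverage factor k.
#'
#' @param combined_pct Combined relative standard uncertainty (%, k = 1).
#' @param coverage_k Coverage factor (> 0), e.g. 2 for ~95 % coverage.
#' @return Expanded relative uncertainty in percent.
#' @export
expand_uncertainty <- function(combined_pct, coverage_k = 2) {
  stopifnot(coverage_k > 0)
  combined_pct * coverage_k
}

#' @exportS3Method generics::glance
glance.uncertainty_budget <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x),
    n_type_b = sum(x$gum_type == "B"),
    combined_pct = combine_budget(x),
    expanded_k2_pct = expand_uncertainty(combine_budget(x), 2)
  )
}
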