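#' Segment-wise volumetric mass correction
#'
#' Corrects a whole-body volumetric mass estimate when the axial (torso)
#' segment of the underlying 3-D model is too long by a known factor.
#' Axial volume scales linearly with torso length at fixed cross-section,
#' so the corrected total is `axial / factor + appendicular` with the
#' appendicular remainder untouched.
#'
#' @param total Total model mass, kg.
#' @param axial Axial (torso) segment mass, kg.
#' @param axial_length_factor Factor by which the model torso is too long.
#' @return Corrected total mass, kg.
#' @examples
#' segmentwise_correction(544, 474, 2.77)  # ~241 kg
#' @export
segmentwise_correction <- function(total, axial, axial_length_factor) {
  stopifnot(total >= 0, axial >= 0)
  if (axial > total) stop("axial mass cannot exceed total mass")
  if (axial_length_factor <= 0) stop("length factor must be positive")
  axial / axial_length_factor + (total - axial)
}

#' Span-mass power-law regression
#'
#' `mass = coeff * span^exponent`, invertible for positive spans. The
#' default is the unique power law through the two anchor points
#' (6.65 m, 70 kg) and (4.2 m, 22 kg) from 'heavy' pterosaur mass
#' datasets, giving exponent ~2.52; alternative published regressions can
#' be substituted via the arguments.
#'
#' @param coeff Coefficient, kg per m^exponent.
#' @param exponent Scaling exponent.
#' @return An object of class `span_mass_regression`.
#' @export
span_mass_regression <- function(coeff = NULL, exponent = NULL) {
  if (is.null(coeff) || is.null(exponent)) {
    cal <- calibrate_span_mass(c(6.65, 4.2), c(70, 22))
    if (is.null(exponent)) exponent <- cal$exponent
    if (is.null(coeff)) coeff <- cal$coeff
  }
  stopifnot(coeff > 0, exponent > 0)
  structure(list(coeff = coeff, exponent = exponent),
            class = "span_mass_regression")
}

#' Calibrate a span-mass power law through two points
#'
#' @param spans Length-2 vector of spans, m.
#' @param masses Length-2 vector of masses, kg.
#' @return A [span_mass_regression()].
#' @export
calibrate_span_mass <- function(spans, masses) {
  stopifnot(length(spans) == 2, length(masses) == 2,
            all(spans > 0), all(masses > 0), spans[1] != spans[2])
  exponent <- log(masses[1] / masses[2]) / log(spans[1] / spans[2])
  structure(list(coeff = masses[1] / spans[1]^exponent, exponent = exponent),
            class = "span_mass_regression")
}

#' Predict mass from wingspan
#'
#' @param span Wingspan, m (vectorised).
#' @param reg A [span_mass_regression()].
#' @return Mass, kg.
#' @export
mass_from_span <- function(span, reg = span_mass_regression()) {
  if (any(span <= 0)) stop("span must be positive")
  reg$coeff * span^reg$exponent
}

#' Predict wingspan from mass (exact inverse of [mass_from_span()])
#'
#' @param mass Body mass, kg (vectorised).
#' @param reg A [span_mass_regression()].
#' @return Wingspan, m.
#' @export
span_from_mass <- function(mass, reg = span_mass_regression()) {
  if (any(mass <= 0)) stop("mass must be positive")
  (mass / reg$coeff)^(1 / reg$exponent)
}

#' Mass ratio implied by two wingspans
#'
#' `(span2 / span1)^exponent` — e.g. a 13 m individual masses nearly
#' twice a 10 m one under the default calibration.
#'
#' @param span1,span2 Wingspans, m.
#' @param reg A [span_mass_regression()].
#' @return Dimensionless mass ratio (mass at `span2` over mass at `span1`).
#' @export
mass_ratio_between_spans <- function(span1, span2,
                                     reg = span_mass_regression()) {
  if (any(span1 <= 0) || any(span2 <= 0)) stop("spans must be positive")
  (span2 / span1)^reg$exponent
}

#' Body-density plausibility check
#'
#' Density in g/cm^3 (numerically kg/L) from a mass and a body volume,
#' judged against a plausibility band for volant animals: birds run
#' 0.6-0.9 g/cm^3 and non-volant animals about 1, so the default band is
#' (0.6, 1.0), open at both ends.
#'
#' @param mass Body mass, kg.
#' @param volume Body volume, L.
#' @param band Length-2 plausible density band, g/cm^3.
#' @return A list of class `density_check` with `density`,
#'   `plausible_band` and `verdict` (`"plausible"` or `"implausible"`).
#' @examples
#' density_check(93, 40)  # 2.325 g/cm^3: far too dense for a flier
#' @export
density_check <- function(mass, volume, band = c(0.6, 1.0)) {
  stopifnot(mass >= 0, length(band) == 2, band[1] < band[2])
  if (volume <= 0) stop("volume must be positive")
  d <- mass / volume
  structure(list(
    density = d, plausible_band = band,
    verdict = if (d > band[1] && d < band[2]) "plausible" else "implausible"),
    class = "density_check")
}
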