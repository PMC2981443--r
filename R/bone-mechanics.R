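#' Bone cross-section description
#'
#' Constructs a validated record of a long-bone (or tubular cervical
#' vertebra) midshaft cross-section, modelled as a hollow ellipse. Radii are
#' the dorsoventral (`a`) and anteroposterior (`b`) half-diameters of the
#' outer and medullary contours, in mm. Cortical geometry may be given
#' either as inner radii or as a uniform cortical wall thickness, in which
#' case `a_in = a_out - thickness` and `b_in = b_out - thickness`, floored
#' at zero (wall thickness in fossil material is typically measured from
#' broken elements rather than imaged sections).
#'
#' @param taxon Taxon label.
#' @param element Element label, e.g. `"humerus"`, `"femur"`, `"cervical"`.
#' @param a_out,b_out Outer radii, mm.
#' @param a_in,b_in Inner (medullary) radii, mm. Supply either these or
#'   `cortical_thickness`.
#' @param cortical_thickness Uniform cortical wall thickness, mm.
#' @param length Element length, mm (used as the cantilever moment arm).
#' @param body_mass_candidates Numeric vector of candidate body masses, kg.
#' @param wingspan Optional wingspan, m (carried for reporting only).
#' @return An object of class `bone_section`.
#' @examples
#' bone_section("Quetzalcoatlus sp.", "humerus",
#'   a_out = 20, b_out = 16, cortical_thickness = 3,
#'   length = 240, body_mass_candidates = 22.34)
#' @export
bone_section <- function(taxon, element, a_out, b_out,
                         a_in = NULL, b_in = NULL,
                         cortical_thickness = NULL,
                         length, body_mass_candidates,
                         wingspan = NA_real_) {
  if (!is.null(cortical_thickness)) {
    if (!is.null(a_in) || !is.null(b_in))
      stop("give either inner radii or a cortical thickness, not both")
    if (cortical_thickness < 0) stop("cortical thickness must be >= 0")
    a_in <- max(a_out - cortical_thickness, 0)
    b_in <- max(b_out - cortical_thickness, 0)
  }
  if (is.null(a_in) || is.null(b_in))
    stop("inner geometry missing: supply a_in/b_in or cortical_thickness")
  stopifnot(a_out >= 0, b_out >= 0, a_in >= 0, b_in >= 0)
  if (a_in > a_out || b_in > b_out)
    stop("inner radii must not exceed outer radii")
  if (length <= 0) stop("element length must be positive")
  body_mass_candidates <- as.numeric(body_mass_candidates)
  if (!any(body_mass_candidates > 0))
    stop("at least one body-mass candidate must be positive")
  structure(
    list(taxon = taxon, element = element,
         a_out = a_out, b_out = b_out, a_in = a_in, b_in = b_in,
         length = length, body_mass_candidates = body_mass_candidates,
         wingspan = wingspan),
    class = "bone_section")
}

#' Material and loading parameters for failure-force estimation
#'
#' @param sigma_max Breaking stress of bone, MPa. The default 175 MPa is
#'   the experimental breaking limit of avian bone, a conservative figure
#'   relative to most vertebrate long bone.
#' @param bending_share Fraction of the polar section modulus credited to
#'   single-plane bending strength. The polar modulus measures torsional
#'   and (twice) average bending strength, hence the 0.5 default; it is
#'   exposed because absolute failure forces depend on this convention
#'   while strength ratios do not.
#' @param g Gravitational acceleration, m/s^2.
#' @return An object of class `material_params`.
#' @export
material_params <- function(sigma_max = 175, bending_share = 0.5, g = 9.81) {
  stopifnot(sigma_max > 0, bending_share > 0, bending_share <= 1, g > 0)
  structure(list(sigma_max = sigma_max, bending_share = bending_share, g = g),
            class = "material_params")
}

#' Polar second moment of area of a solid ellipse
#'
#' `J = pi * a * b * (a^2 + b^2) / 4` for an ellipse with semi-axes `a`
#' and `b`. Exact for symmetric sections; a strong approximation for
#' near-elliptical bone midshafts. Reduces to `pi r^4 / 2` for a circle.
#'
#' @param a,b Semi-axis radii, mm (vectorised).
#' @return J in mm^4.
#' @export
polar_second_moment_ellipse <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stop("radii must be non-negative")
  pi * a * b * (a^2 + b^2) / 4
}

#' Cortical polar second moment of a hollow elliptical section
#'
#' Computes J for the outer contour and the medullary cavity and subtracts:
#' the cortical J governs the torsional/bending strength of the bone wall.
#'
#' @param section A [bone_section()].
#' @return A list with `J_solid`, `J_medullary`, `J_cortical`, mm^4.
#' @export
cortical_J <- function(section) {
  stopifnot(inherits(section, "bone_section"))
  J_solid <- polar_second_moment_ellipse(section$a_out, section$b_out)
  J_medullary <- polar_second_moment_ellipse(section$a_in, section$b_in)
  list(J_solid = J_solid, J_medullary = J_medullary,
       J_cortical = J_solid - J_medullary)
}

#' Polar section modulus of a hollow elliptical midshaft
#'
#' `Zp = J_cortical / mean(outer radii)`: cortical polar second moment
#' divided by the average section radius in the two measurement planes.
#'
#' @param section A [bone_section()].
#' @return Zp in mm^3.
#' @export
polar_section_modulus <- function(section) {
  r_mean <- (section$a_out + section$b_out) / 2
  if (r_mean <= 0) stop("outer radii must not both be zero")
  cortical_J(section)$J_cortical / r_mean
}

#' Section properties of a bone midshaft
#'
#' Convenience wrapper returning J components, Zp, and the length-corrected
#' modulus `Zp / L` (structural strength is proportional to `Z / (B * L)`,
#' so dividing by element length gives the comparable per-specimen index).
#'
#' @param section A [bone_section()].
#' @return A list of class `section_properties`.
#' @export
section_properties <- function(section) {
  J <- cortical_J(section)
  Zp <- polar_section_modulus(section)
  structure(c(J, list(Zp = Zp, Zp_per_length = Zp / section$length)),
            class = "section_properties")
}

#' Cantilever failure force of a bone loaded in bending
#'
#' Treats the whole element as a cantilever beam (total length = moment
#' arm). With stress at failure `sigma_max`, the tip force at failure is
#' `F = sigma_max * (bending_share * Zp) / L`; MPa times mm^3 per mm gives
#' newtons directly.
#'
#' @param Zp Polar section modulus, mm^3.
#' @param length Moment arm (element length), mm.
#' @param material A [material_params()].
#' @return Failure force, N.
#' @export
cantilever_failure_force <- function(Zp, length, material = material_params()) {
  if (any(length <= 0)) stop("moment arm must be positive")
  material$sigma_max * (material$bending_share * Zp) / length
}

#' Relative failure force
#'
#' Failure force expressed in multiples of body weight — the size-corrected
#' robustness index used to compare elements across taxa. An RFF below 1
#' means the element would fail under its own body weight in pure
#' cantilever bending.
#'
#' @param F Failure force, N.
#' @param mass Body mass, kg.
#' @param material A [material_params()] (supplies g).
#' @return RFF, body weights (dimensionless).
#' @export
relative_failure_force <- function(F, mass, material = material_params()) {
  if (any(mass <= 0)) stop("body mass must be positive")
  F / (mass * material$g)
}

#' Avian structural-scaling model for expected RFF
#'
#' A log-log power law `RFF_expected = 10^(intercept + exponent *
#' log10(mass))` giving the relative failure force predicted for a bird of
#' the same body mass. Coefficients are supplied per element; see
#' [fit_avian_scaling()] for the packaged calibration.
#'
#' @param intercept Log10-scale intercept.
#' @param exponent Slope on log-log axes (negative: bird bones become
#'   relatively weaker with size).
#' @param source Label recording where the coefficients came from.
#' @return An object of class `avian_scaling_model`.
#' @export
avian_scaling_model <- function(intercept, exponent, source = "calibrated") {
  stopifnot(is.finite(intercept), is.finite(exponent))
  structure(list(intercept = intercept, exponent = exponent, source = source),
            class = "avian_scaling_model")
}

#' Expected avian RFF at a given body mass
#'
#' @param mass Body mass, kg (vectorised).
#' @param model An [avian_scaling_model()].
#' @return Expected RFF, body weights.
#' @export
avian_expected_rff <- function(mass, model) {
  if (!inherits(model, "avian_scaling_model"))
    stop("an avian_scaling_model is required")
  if (any(mass <= 0)) stop("body mass must be positive")
  10^(model$intercept + model$exponent * log10(mass))
}

#' Calibrate avian scaling models from (mass, expectation) pairs
#'
#' Least-squares fit of `log10(expectation)` on `log10(mass)`, one model
#' per element. Elements represented by a single pair cannot identify a
#' slope of their own; they borrow the humerus slope and anchor the
#' intercept through their one point.
#'
#' @param masses Body masses, kg.
#' @param expectations Expected RFF values at those masses.
#' @param elements Element label per pair.
#' @return Named list of [avian_scaling_model()] objects, one per element.
#' @export
fit_avian_scaling <- function(masses, expectations,
                              elements = rep("humerus", length(masses))) {
  stopifnot(length(masses) == length(expectations),
            length(masses) == length(elements),
            all(masses > 0), all(expectations > 0))
  out <- list()
  slopes <- c()
  for (el in unique(elements)) {
    i <- elements == el
    if (sum(i) >= 2) {
      fit <- stats::lm(log10(expectations[i]) ~ log10(masses[i]))
      out[[el]] <- avian_scaling_model(unname(coef(fit)[1]),
                                       unname(coef(fit)[2]),
                                       source = "least-squares calibration")
      slopes[el] <- unname(coef(fit)[2])
    }
  }
  # single-pair elements: borrow the humerus slope (fall back to the mean
  # fitted slope if no humerus model exists)
  ref_slope <- if ("humerus" %in% names(slopes)) slopes[["humerus"]]
               else mean(slopes)
  for (el in unique(elements)) {
    i <- elements == el
    if (sum(i) == 1) {
      if (!length(slopes)) stop("cannot calibrate: all elements have one pair")
      intercept <- log10(expectations[i]) - ref_slope * log10(masses[i])
      out[[el]] <- avian_scaling_model(intercept, ref_slope,
                                       source = "single-point anchor")
    }
  }
  out
}

#' Ratio of observed to expected relative failure force
#'
#' @param rff Observed RFF, body weights.
#' @param expectation Avian-expected RFF at the same mass.
#' @return Dimensionless ratio; values above 1 indicate an element stronger
#'   than the avian trend predicts.
#' @export
rff_ratio <- function(rff, expectation) {
  if (any(expectation <= 0, na.rm = TRUE)) stop("expectation must be positive")
  rff / expectation
}

#' Full failure assessment for one section and mass
#'
#' @param section A [bone_section()].
#' @param mass Body mass, kg.
#' @param material A [material_params()].
#' @param model Optional [avian_scaling_model()] for the element.
#' @return A list of class `failure_assessment` with `failure_force` (N),
#'   `rff`, `avian_expectation`, and `ratio_observed_expected`.
#' @export
assess_failure <- function(section, mass, material = material_params(),
                           model = NULL) {
  Zp <- polar_section_modulus(section)
  F <- cantilever_failure_force(Zp, section$length, material)
  rff <- relative_failure_force(F, mass, material)
  expectation <- if (is.null(model)) NA_real_ else avian_expected_rff(mass, model)
  structure(list(
    failure_force = F, rff = rff, avian_expectation = expectation,
    ratio_observed_expected = if (is.na(expectation)) NA_real_
                              else rff_ratio(rff, expectation)),
    class = "failure_assessment")
}

#' Round half-up at a given number of decimals
#'
#' Table comparisons use conventional half-up rounding (0.305 -> 0.31 at
#' two decimals), not banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimals to keep.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
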