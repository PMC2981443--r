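#' Wing planform
#'
#' A static planform: span, lifting area and all-up mass, from which
#' weight, aspect ratio and wing loading follow.
#'
#' @param span Wingspan b, m.
#' @param area Wing area S, m^2.
#' @param mass All-up body mass M, kg.
#' @param label Text label.
#' @param g Gravitational acceleration used for the derived weight, m/s^2.
#' @return An object of class `planform` with derived `weight` (N),
#'   `aspect_ratio` and `wing_loading` (N/m^2).
#' @examples
#' planform(span = 10.39, area = 9.55, mass = 70, label = "Quetzalcoatlus")
#' @export
planform <- function(span, area, mass, label = "", g = 9.81) {
  stopifnot(span > 0, area > 0, mass > 0)
  structure(list(span = span, area = area, mass = mass, label = label,
                 weight = mass * g,
                 aspect_ratio = span^2 / area,
                 wing_loading = mass * g / area),
            class = "planform")
}

#' Glide-polar parameters
#'
#' Aerodynamic constants of the two-term drag polar plus the membrane-wing
#' lift limits. Defaults follow standard flight-mechanics conventions for
#' animal glide polars: sea-level air density 1.23 kg/m^3, induced-drag
#' factor 1.1, wing profile drag coefficient 0.014, body drag coefficient
#' 0.1 on an allometric frontal area `0.00813 * M^0.666` m^2. The maximum
#' unsteady lift coefficient of 2.2 reflects compliant membrane wings
#' (about a third above the avian maximum); 1.8 is the steady-state
#' ceiling measured for birds. Span reduction during fast glides is capped
#' at 80% of resting span (membranes flutter when slack), reached at twice
#' the stall speed. The flap:glide ratio 0.2 is carried as metadata on
#' reports; no intermittent-flight energy model is attached to it.
#'
#' @param rho Air density, kg/m^3.
#' @param k_induced Induced-drag factor (1 for an ideal elliptical wing).
#' @param cd_profile Wing profile drag coefficient.
#' @param cd_body Body (parasite) drag coefficient.
#' @param body_area_coeff,body_area_exp Allometric body frontal area:
#'   `Sb = body_area_coeff * M^body_area_exp`, m^2.
#' @param cl_max_steady,cl_max_unsteady Maximum steady / unsteady lift
#'   coefficients.
#' @param min_span_fraction Hard floor on effective span fraction.
#' @param flap_glide_ratio Flap:glide cycle ratio (metadata).
#' @param g Gravitational acceleration, m/s^2.
#' @return An object of class `glide_polar_params`.
#' @export
glide_polar_params <- function(rho = 1.23, k_induced = 1.1,
                               cd_profile = 0.014, cd_body = 0.1,
                               body_area_coeff = 0.00813,
                               body_area_exp = 0.666,
                               cl_max_steady = 1.8, cl_max_unsteady = 2.2,
                               min_span_fraction = 0.8,
                               flap_glide_ratio = 0.2, g = 9.81) {
  stopifnot(rho > 0, k_induced > 0, cd_profile > 0, cd_body > 0,
            body_area_coeff > 0, body_area_exp >= 0,
            cl_max_steady > 0, cl_max_unsteady >= cl_max_steady,
            min_span_fraction > 0, min_span_fraction <= 1,
            flap_glide_ratio >= 0, g > 0)
  structure(as.list(environment()), class = "glide_polar_params")
}

#' Anaerobic burst-muscle model
#'
#' @param muscle_fraction Fraction of body mass that is flight muscle.
#' @param specific_power Burst (anaerobic) power output, W per kg muscle.
#' @param burst_duration Sustainable burst duration, s.
#' @param climb_rate Climb-out altitude gain, m/s.
#' @return An object of class `burst_model`.
#' @export
burst_model <- function(muscle_fraction, specific_power,
                        burst_duration = 60, climb_rate = 1) {
  stopifnot(muscle_fraction >= 0, muscle_fraction < 1, specific_power >= 0,
            burst_duration >= 0, climb_rate >= 0)
  structure(list(muscle_fraction = muscle_fraction,
                 specific_power = specific_power,
                 burst_duration = burst_duration,
                 climb_rate = climb_rate),
            class = "burst_model")
}

#' Allometric body frontal area
#'
#' @param M Body mass, kg.
#' @param params A [glide_polar_params()].
#' @return Frontal area Sb, m^2.
#' @export
body_frontal_area <- function(M, params = glide_polar_params()) {
  if (any(M <= 0)) stop("mass must be positive")
  params$body_area_coeff * M^params$body_area_exp
}

# Coefficients of the two-term polar D(V) = A V^2 + B / V^2:
# A collects the speed-squared (profile + body) drag, B the induced drag.
polar_coefficients <- function(pf, params) {
  Sb <- body_frontal_area(pf$mass, params)
  W <- pf$mass * params$g
  list(A = 0.5 * params$rho * (pf$area * params$cd_profile + Sb * params$cd_body),
       B = 2 * params$k_induced * W^2 / (params$rho * pi * pf$span^2))
}

#' Total aerodynamic drag in a glide
#'
#' `D(V) = q S cd_profile + q Sb cd_body + k W^2 / (q pi b^2)` with
#' dynamic pressure `q = 0.5 rho V^2`; equivalently `A V^2 + B / V^2`.
#' Diverges at both very low speed (induced drag) and high speed
#' (profile/parasite drag), so a unique minimum exists.
#'
#' @param V Airspeed, m/s (vectorised).
#' @param pf A [planform()].
#' @param params A [glide_polar_params()].
#' @return Drag, N.
#' @export
glide_drag <- function(V, pf, params = glide_polar_params()) {
  if (any(V <= 0)) stop("airspeed must be positive")
  co <- polar_coefficients(pf, params)
  co$A * V^2 + co$B / V^2
}

#' Best glide speed
#'
#' The drag-minimising (maximum lift:drag, maximum still-air range) speed
#' of the two-term polar, `(B/A)^(1/4)`. Of all glide quantities this is
#' the most robust across flying animals: it depends only on planform,
#' mass and wing efficiency, not physiology.
#'
#' @param pf A [planform()].
#' @param params A [glide_polar_params()].
#' @return Best glide speed, m/s.
#' @export
best_glide_speed <- function(pf, params = glide_polar_params()) {
  co <- polar_coefficients(pf, params)
  (co$B / co$A)^0.25
}

#' Minimum sink speed and sink rate
#'
#' Minimises the sink rate `D(V) * V / W` (small-angle glide), giving the
#' closed form `(B / (3A))^(1/4)` — a factor `3^(-1/4)` below the best
#' glide speed for any two-term polar.
#'
#' @param pf A [planform()].
#' @param params A [glide_polar_params()].
#' @return List with `v_min_sink` (m/s) and `sink_rate` (m/s).
#' @export
minimum_sink_speed <- function(pf, params = glide_polar_params()) {
  co <- polar_coefficients(pf, params)
  v <- (co$B / (3 * co$A))^0.25
  W <- pf$mass * params$g
  list(v_min_sink = v, sink_rate = glide_drag(v, pf, params) * v / W)
}

#' Stall speed at a given lift coefficient
#'
#' `V_stall = sqrt(2 W / (rho S cl))`: the minimum airspeed at which lift
#' can balance weight.
#'
#' @param pf A [planform()].
#' @param params A [glide_polar_params()].
#' @param cl Lift coefficient; defaults to the unsteady membrane maximum.
#' @return Stall speed, m/s.
#' @export
stall_speed <- function(pf, params = glide_polar_params(),
                        cl = params$cl_max_unsteady) {
  if (any(cl <= 0)) stop("lift coefficient must be positive")
  sqrt(2 * pf$mass * params$g / (params$rho * pf$area * cl))
}

#' Effective span fraction during a glide
#'
#' Membrane wings cannot be flexed as far as bird wings: the effective
#' span declines linearly from 100% at stall speed to the hard floor
#' (default 80%) at twice the stall speed and is clamped there at any
#' higher speed.
#'
#' @param V Airspeed, m/s (vectorised); must be at or above stall.
#' @param pf A [planform()].
#' @param params A [glide_polar_params()].
#' @return Span fraction in `[min_span_fraction, 1]`.
#' @export
effective_span_fraction <- function(V, pf, params = glide_polar_params()) {
  vs <- stall_speed(pf, params)
  if (any(V < vs - 1e-9)) stop("airspeed below stall")
  frac <- 1 - (1 - params$min_span_fraction) * (V - vs) / vs
  pmax(frac, params$min_span_fraction)
}

#' Flapping frequency from mass, span and wing area
#'
#' The dimensional scaling law with span and area entering as separate
#' terms: `f = M^(3/8) g^(1/2) b^(-23/24) S^(-1/3) rho^(-3/8)`. At fixed
#' planform, frequency rises with the 3/8 power of body mass; under
#' geometric similarity the net exponent is -1/6, so comparisons across
#' species only track the simple mass trend when the taxa are close to
#' geometrically similar.
#'
#' @param M Body mass, kg.
#' @param b Wingspan, m.
#' @param S Wing area, m^2.
#' @param params A [glide_polar_params()] (supplies g and rho).
#' @return Flapping frequency, Hz.
#' @export
flapping_frequency <- function(M, b, S, params = glide_polar_params()) {
  if (any(M <= 0) || any(b <= 0) || any(S <= 0))
    stop("mass, span and area must be positive")
  M^(3 / 8) * params$g^(1 / 2) * b^(-23 / 24) * S^(-1 / 3) * params$rho^(-3 / 8)
}

#' Available anaerobic burst power
#'
#' @param M Body mass, kg.
#' @param burst A [burst_model()].
#' @return Power, W.
#' @export
anaerobic_power <- function(M, burst) {
  stopifnot(inherits(burst, "burst_model"))
  M * burst$muscle_fraction * burst$specific_power
}

#' Burst (maximum range) speed under a fixed power budget
#'
#' Solves `D(V) * V + W * climb_rate = power` for the largest root: the
#' fastest level-plus-climb speed sustainable on the given power. The
#' power required curve `A V^3 + B/V + W c` is U-shaped with its minimum
#' at the minimum sink speed, so a feasible budget gives two roots; the
#' larger (fast) solution is the maximum range speed.
#'
#' @param pf A [planform()].
#' @param params A [glide_polar_params()].
#' @param power Available power, W.
#' @param climb_rate Required climb rate, m/s.
#' @param v_max Upper bracket for the root search, m/s.
#' @return Speed, m/s.
#' @export
burst_speed <- function(pf, params = glide_polar_params(), power,
                        climb_rate = 1, v_max = 100) {
  W <- pf$mass * params$g
  req <- function(V) glide_drag(V, pf, params) * V + W * climb_rate
  v_ms <- minimum_sink_speed(pf, params)$v_min_sink
  p_min <- req(v_ms)
  if (power < p_min)
    stop(sprintf("insufficient power: %.0f W available, %.0f W required",
                 power, p_min))
  if (abs(power - p_min) < 1e-9 * p_min) return(v_ms)
  if (req(v_max) < power)
    stop("upper bracket too low for this power budget; raise v_max")
  stats::uniroot(function(V) req(V) - power, lower = v_ms, upper = v_max,
                 tol = 1e-6 * v_ms)$root
}

#' Distance covered during an anaerobic burst
#'
#' `range = speed * burst_duration`. Distance lost to climb-out altitude
#' gain is reported separately by callers, not subtracted here.
#'
#' @param speed Burst speed, m/s.
#' @param burst A [burst_model()].
#' @return Range, m.
#' @export
burst_range <- function(speed, burst) {
  stopifnot(speed >= 0)
  speed * burst$burst_duration
}

#' Glide performance summary for a planform
#'
#' @param pf A [planform()].
#' @param params A [glide_polar_params()].
#' @param burst Optional [burst_model()]; if supplied, burst speed and
#'   range are included.
#' @return A list of class `glide_performance`: stall speeds (steady and
#'   unsteady CL), best glide and minimum sink speeds, sink rate, best
#'   glide ratio, and (optionally) burst power/speed/range.
#' @export
glide_performance <- function(pf, params = glide_polar_params(),
                              burst = NULL) {
  v_bg <- best_glide_speed(pf, params)
  ms <- minimum_sink_speed(pf, params)
  W <- pf$mass * params$g
  perf <- list(
    label = pf$label,
    v_stall = stall_speed(pf, params, params$cl_max_unsteady),
    v_stall_steady = stall_speed(pf, params, params$cl_max_steady),
    v_best_glide = v_bg,
    v_min_sink = ms$v_min_sink,
    min_sink_rate = ms$sink_rate,
    best_glide_ratio = W / glide_drag(v_bg, pf, params),
    flap_glide_ratio = params$flap_glide_ratio)
  if (!is.null(burst)) {
    P <- anaerobic_power(pf$mass, burst)
    v <- burst_speed(pf, params, P, burst$climb_rate)
    perf$burst_power <- P
    perf$burst_speed <- v
    perf$burst_range <- burst_range(v, burst)
  }
  structure(perf, class = "glide_performance")
}
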