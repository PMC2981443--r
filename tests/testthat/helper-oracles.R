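# Independent oracles used across tests.

# 2-D numerical integration of r^2 dA over an ellipse (independent of the
# closed form used by the package).
numeric_polar_J <- function(a, b) {
  if (a == 0 || b == 0) return(0)
  pracma::integral2(function(x, y) x^2 + y^2,
                    -a, a,
                    function(x) -b * sqrt(pmax(0, 1 - x^2 / a^2)),
                    function(x)  b * sqrt(pmax(0, 1 - x^2 / a^2)),
                    reltol = 1e-10)$Q
}

# Dense grid search for the drag-minimising speed.
grid_best_glide <- function(pf, params, n = 1000, v_max = 60) {
  v <- exp(seq(log(0.5), log(v_max), length.out = n))
  d <- glide_drag(v, pf, params)
  v[which.min(d)]
}

# Dense grid search for the sink-rate-minimising speed.
grid_min_sink <- function(pf, params, n = 1000, v_max = 60) {
  v <- exp(seq(log(0.5), log(v_max), length.out = n))
  s <- glide_drag(v, pf, params) * v / (pf$mass * params$g)
  v[which.min(s)]
}

# Random planform within the envelope real fliers occupy: wing loading
# grows roughly with the cube root of mass (small passerine ~20 N/m^2 up
# to giant azhdarchid ~220 N/m^2).
random_planform <- function() {
  mass <- exp(stats::runif(1, log(0.3), log(260)))
  ar <- stats::runif(1, 6, 20)
  loading <- 25 * mass^(1 / 3) * 10^stats::runif(1, -0.15, 0.15)
  area <- mass * 9.81 / loading
  planform(span = sqrt(ar * area), area = area, mass = mass)
}
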