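chatterjee <- planform(span = 10.39, area = 9.55, mass = 70, label = "narrow")
witton <- planform(span = 9.64, area = 11.36, mass = 259.06, label = "broad")
defaults <- glide_polar_params()

test_that("body frontal area follows the allometric closure", {
  expect_equal(body_frontal_area(1), 0.00813)
  expect_equal(body_frontal_area(70), 0.00813 * 70^0.666)
  flat <- glide_polar_params(body_area_exp = 0)
  expect_equal(body_frontal_area(c(1, 10, 100), flat), rep(0.00813, 3))
  expect_error(body_frontal_area(0), "positive")
})

test_that("glide drag decomposes as A V^2 + B / V^2", {
  pf <- chatterjee
  Sb <- body_frontal_area(pf$mass, defaults)
  A <- 0.5 * defaults$rho *
    (pf$area * defaults$cd_profile + Sb * defaults$cd_body)
  B <- 2 * defaults$k_induced * pf$weight^2 /
    (defaults$rho * pi * pf$span^2)
  V <- c(5, 10, 20, 40)
  expect_equal(glide_drag(V, pf, defaults), A * V^2 + B / V^2)
  expect_error(glide_drag(0, pf, defaults), "positive")
})

test_that("closed-form optima agree with grid search on random planforms", {
  withr::with_seed(11, {
    for (i in 1:100) {
      pf <- random_planform()
      v_bg <- best_glide_speed(pf, defaults)
      v_ms <- minimum_sink_speed(pf, defaults)$v_min_sink
      v_hi <- max(60, 3 * v_bg)
      expect_equal(v_bg, grid_best_glide(pf, defaults, v_max = v_hi),
                   tolerance = 1e-2)
      expect_equal(v_ms, grid_min_sink(pf, defaults, v_max = v_hi),
                   tolerance = 1e-2)
    }
  })
})

test_that("speed ordering v_stall < v_min_sink < v_best_glide holds", {
  withr::with_seed(12, {
    for (i in 1:50) {
      pf <- random_planform()
      vs_u <- stall_speed(pf, defaults, defaults$cl_max_unsteady)
      vs_s <- stall_speed(pf, defaults, defaults$cl_max_steady)
      v_ms <- minimum_sink_speed(pf, defaults)$v_min_sink
      v_bg <- best_glide_speed(pf, defaults)
      expect_lt(vs_u, vs_s)
      expect_lt(vs_s, v_ms)
      expect_lt(v_ms, v_bg)
    }
  })
})

test_that("best glide to minimum sink ratio is 3^(1/4) for any polar", {
  withr::with_seed(13, {
    for (i in 1:20) {
      pf <- random_planform()
      expect_equal(best_glide_speed(pf, defaults) /
                     minimum_sink_speed(pf, defaults)$v_min_sink,
                   3^0.25)
    }
  })
})

test_that("best glide speed rises with wing loading at fixed shape", {
  # quadrupling weight (holding body area fixed) doubles v_bg: B ~ W^2
  pf1 <- chatterjee
  pf4 <- planform(pf1$span, pf1$area, 4 * pf1$mass)
  fixed_body <- glide_polar_params(body_area_coeff = 0.1, body_area_exp = 0)
  expect_equal(best_glide_speed(pf4, fixed_body),
               2 * best_glide_speed(pf1, fixed_body))
  # monotonicity across a loading sweep at fixed aspect ratio
  loadings <- seq(40, 240, by = 40)
  v <- vapply(loadings, function(wl) {
    area <- 2; mass <- wl * area / 9.81
    best_glide_speed(planform(sqrt(10 * area), area, mass), defaults)
  }, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("best glide ratio is weight-invariant when body area is fixed", {
  fixed_body <- glide_polar_params(body_area_coeff = 0.1, body_area_exp = 0)
  gr <- function(pf) pf$weight / glide_drag(best_glide_speed(pf, fixed_body),
                                            pf, fixed_body)
  expect_equal(gr(planform(10.39, 9.55, 70)),
               gr(planform(10.39, 9.55, 700)))
})

test_that("stall speed follows the lift balance", {
  expect_equal(stall_speed(chatterjee, defaults, cl = 2.2),
               sqrt(2 * 686.7 / (1.23 * 9.55 * 2.2)))
  expect_equal(stall_speed(chatterjee, defaults, cl = 2.2), 7.29,
               tolerance = 1e-3)
  # halving CL scales the speed by sqrt(2)
  expect_equal(stall_speed(chatterjee, defaults, cl = 1.1),
               sqrt(2) * stall_speed(chatterjee, defaults, cl = 2.2))
  expect_error(stall_speed(chatterjee, defaults, cl = 0), "positive")
})

test_that("effective span declines linearly to the 80% hard stop", {
  vs <- stall_speed(chatterjee, defaults)
  expect_equal(effective_span_fraction(vs, chatterjee, defaults), 1)
  expect_equal(effective_span_fraction(2 * vs, chatterjee, defaults), 0.8)
  expect_equal(effective_span_fraction(10 * vs, chatterjee, defaults), 0.8)
  expect_equal(effective_span_fraction(1.5 * vs, chatterjee, defaults), 0.9)
  expect_error(effective_span_fraction(0.5 * vs, chatterjee, defaults),
               "stall")
})

test_that("flapping frequency follows the 3/8-power mass scaling", {
  # wandering albatross record: direct evaluation of the power law
  expect_equal(flapping_frequency(8.73, 3.03, 0.61), 2.6618,
               tolerance = 1e-4)
  expect_equal(flapping_frequency(2 * 8.73, 3.03, 0.61),
               2^(3 / 8) * flapping_frequency(8.73, 3.03, 0.61))
  # under geometric similarity (b ~ M^(1/3), S ~ M^(2/3)) f ~ M^(-1/6)
  f_of <- function(M) flapping_frequency(M, 3 * M^(1 / 3), 0.6 * M^(2 / 3))
  expect_equal(f_of(8) / f_of(1), 8^(-1 / 6))
  expect_error(flapping_frequency(-1, 3, 0.6), "positive")
})

test_that("anaerobic power is linear in mass, fraction and specific power", {
  expect_equal(anaerobic_power(200, burst_model(0.25, 400)), 20000)
  expect_equal(anaerobic_power(200, burst_model(0, 400)), 0)
  expect_equal(anaerobic_power(400, burst_model(0.25, 400)), 40000)
  expect_equal(anaerobic_power(200, burst_model(0.25, 800)), 40000)
})

test_that("burst speed is the larger root of the power balance", {
  pf <- witton
  W <- pf$mass * defaults$g
  req <- function(V) glide_drag(V, pf, defaults) * V + W * 1
  v_ms <- minimum_sink_speed(pf, defaults)$v_min_sink
  p_min <- req(v_ms)
  # tangency: power exactly at the minimum returns the minimum-sink speed
  expect_equal(burst_speed(pf, defaults, p_min, 1), v_ms, tolerance = 1e-6)
  # 1% above the minimum: root-finder agrees with a dense grid oracle
  p <- 1.01 * p_min
  v <- burst_speed(pf, defaults, p, 1)
  grid <- seq(v_ms, 100, length.out = 200000)
  v_grid <- max(grid[req(grid) <= p])
  expect_equal(v, v_grid, tolerance = 1e-3)
  expect_gt(v, v_ms)
  # the found speed satisfies the power balance
  expect_equal(req(v), p, tolerance = 1e-6 * p)
  expect_error(burst_speed(pf, defaults, 0.5 * p_min, 1),
               "insufficient power")
})

test_that("burst speed is monotone in power and climb rate", {
  pf <- witton
  powers <- seq(2e4, 8e4, length.out = 5)
  v <- vapply(powers, function(p) burst_speed(pf, defaults, p, 1),
              numeric(1))
  expect_true(all(diff(v) > 0))
  climbs <- seq(0, 3, length.out = 4)
  v2 <- vapply(climbs, function(c) burst_speed(pf, defaults, 4e4, c),
               numeric(1))
  expect_true(all(diff(v2) < 0))
})

test_that("burst range is speed times duration", {
  b <- burst_model(0.3, 400, burst_duration = 60)
  expect_equal(burst_range(48.3, b), 2898)
  expect_equal(burst_range(10, b), 600)
  expect_equal(burst_range(10, burst_model(0.3, 400, burst_duration = 0)), 0)
})

test_that("glide_performance assembles a consistent report", {
  b <- burst_model(0.3, 400)
  perf <- glide_performance(witton, defaults, b)
  expect_lt(perf$v_stall, perf$v_stall_steady)
  expect_lt(perf$v_stall_steady, perf$v_min_sink)
  expect_lt(perf$v_min_sink, perf$v_best_glide)
  expect_equal(perf$flap_glide_ratio, 0.2)
  expect_equal(perf$burst_range, perf$burst_speed * 60)
  expect_gt(perf$best_glide_ratio, 1)
})
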