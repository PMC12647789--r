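test_that("predict evaluates the tanh curve and respects its bounds", {
  p <- neuron_params(57.5, 1.17, -2.12, 86.8)
  # at the inflection abscissa z = 0, so the response equals B
  expect_equal(predict(p, 2.12 / 1.17), 86.8)
  expect_equal(predict(p, 2), 99.25, tolerance = 1e-2 / 99.25)

  # tanh saturation: approaches A + B from below (exactly A + B once
  # tanh saturates in double precision)
  p2 <- neuron_params(32.4, 1.91, -5.14, 54.6)
  expect_lt(predict(p2, 8), 32.4 + 54.6)
  expect_lte(predict(p2, 100), 32.4 + 54.6)
  expect_equal(predict(p2, 100), 87.0, tolerance = 1e-9)

  x <- seq(-50, 50, length.out = 201)
  y <- predict(p, x)
  expect_true(all(y >= p$B - abs(p$A) & y <= p$B + abs(p$A)))

  expect_error(predict(p, NaN), class = "nrfit_invalid_input")
  expect_error(predict(p, c(1, Inf)), class = "nrfit_invalid_input")
  expect_error(neuron_params(1, NA, 0, 0), class = "nrfit_invalid_input")
})

test_that("first derivative is A*c*(1 - tanh^2) and matches finite differences", {
  expect_equal(nr_slope(neuron_params(2, 3, 0, 5), 0), 6)
  p <- neuron_params(57.5, 1.17, -2.12, 86.8)
  expect_equal(nr_slope(p, 2.12 / 1.17), 67.275)

  for (q in random_canonical(20, seed = 301)) {
    # grid in z-units around the inflection; beyond |z| ~ 19 tanh
    # saturates to exactly 1 in double precision and the slope
    # underflows to an exact 0
    x <- -q$b / q$c + seq(-6, 6, length.out = 17) / q$c
    expect_equal(nr_slope(q, x), fd_slope(q, x), tolerance = 1e-6)
    expect_true(all(nr_slope(q, x) > 0))  # strictly positive, A*c > 0
  }
})

test_that("canonicalize flips the odd-function sign ambiguity and is idempotent", {
  p <- canonicalize(neuron_params(-2, -0.5, 1, 3))
  expect_equal(unlist(p), c(A = 2, c = 0.5, b = -1, B = 3))
  expect_equal(unlist(canonicalize(p)), unlist(p))

  grid <- seq(-10, 10, length.out = 50)
  for (q in random_raw(100, seed = 302)) {
    cq <- canonicalize(q)
    expect_true(cq$A > 0 && cq$c > 0)
    expect_equal(predict(cq, grid), predict(q, grid), tolerance = 1e-14)
  }

  expect_error(canonicalize(neuron_params(0, 1, 0, 0)),
               class = "nrfit_degenerate_model")
  expect_error(canonicalize(neuron_params(1, 0, 0, 0)),
               class = "nrfit_degenerate_model")
  expect_error(canonicalize(neuron_params(1, -1, 0, 0)),
               class = "nrfit_degenerate_model")
})

test_that("derive_metrics reproduces the closed forms", {
  m <- derive_metrics(neuron_params(1, 1, 0, 0), nutrient_min = -2)
  v <- metric_vector(m)
  expect_equal(v[["nutrient_star"]], 0)
  expect_equal(v[["r_max"]], 1)
  expect_equal(v[["response_inf"]], 1)
  expect_equal(v[["half_life"]], 0.549306, tolerance = 1e-6)     # atanh(1/2) = ln(3)/2
  expect_equal(v[["req_0.95"]], 1.831781, tolerance = 1e-6)      # ln(39)/2
  expect_equal(v[["req_0.99"]], 2.646652, tolerance = 1e-6)      # ln(199)/2
  expect_equal(v[["nutrient_lag"]], -0.964028, tolerance = 1e-6) # tanh(-2)

  # published worked examples, at the printed precision
  m12 <- metric_vector(derive_metrics(neuron_params(57.5, 1.17, -2.12, 86.8)))
  expect_equal(round(m12[["response_inf"]], 1), 144.3)
  expect_equal(round(m12[["nutrient_star"]], 2), 1.81)
  expect_equal(round(m12[["half_life"]], 2), 1.59)
  m7 <- metric_vector(derive_metrics(neuron_params(32.0, 2.19, -6.21, 50.0)))
  expect_equal(round(m7[["response_inf"]], 0), 82)
  expect_equal(round(m7[["half_life"]], 1), 2.7)
})

test_that("metrics outside the arctanh domain are tagged undefined, not errors", {
  # B/A >= 3 pushes the half-life arctanh argument to <= -1
  m <- derive_metrics(neuron_params(1, 1, 0, 4), nutrient_min = 0)
  expect_true(is.na(metric_vector(m)[["half_life"]]))
  expect_match(m$undefined[["half_life"]], "arctanh")
  # B/A <= -1 kills the requirement levels too
  m2 <- derive_metrics(neuron_params(1, 1, 0, -2), nutrient_min = 0)
  expect_true(all(is.na(m2$requirements)))
  expect_length(m2$undefined, 3)  # half_life + both requirements

  expect_error(derive_metrics(neuron_params(-1, -1, 0, 0)),
               class = "nrfit_canonicalization_required")
  expect_error(derive_metrics(neuron_params(1, 1, 0, 0), levels = c(0.5, 1.2)),
               class = "nrfit_invalid_level")
})

test_that("requirement and half-life formulas invert the curve exactly", {
  for (q in random_canonical(30, seed = 303)) {
    m <- derive_metrics(q, nutrient_min = 0, levels = c(0.5, 0.8, 0.95, 0.99))
    tot <- q$A + q$B
    for (lev in names(m$requirements)) {
      r <- m$requirements[[lev]]
      if (!is.na(r))
        expect_equal(predict(q, r), as.numeric(lev) * tot,
                     tolerance = 1e-9)
    }
    hl <- m$values[["half_life"]]
    if (!is.na(hl)) expect_equal(predict(q, hl), 0.5 * tot, tolerance = 1e-9)
    # the inflection maximizes the derivative
    ns <- m$values[["nutrient_star"]]
    # 99-point grid contains z = 0, i.e. the inflection itself
    grid <- ns + seq(-10, 10, length.out = 99) / q$c
    expect_equal(grid[which.max(nr_slope(q, grid))], ns)
    # strict monotonicity (within the numerically unsaturated range)
    expect_true(all(diff(predict(q, grid)) > 0))
    # defined requirements are ordered when the plateau is positive
    r95 <- m$requirements[["0.95"]]; r99 <- m$requirements[["0.99"]]
    if (!is.na(r95) && !is.na(r99) && tot > 0) expect_lt(r95, r99)
  }
})

test_that("goodness_of_fit computes RMSE and R2", {
  g <- goodness_of_fit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(g$rmse, 0)
  expect_equal(g$r2, 1)
  g2 <- goodness_of_fit(c(1, 2, 3), c(1, 2, 4))
  expect_equal(g2$rmse, 0.57735, tolerance = 1e-5)
  expect_equal(g2$r2, 0.5)
  expect_equal(goodness_of_fit(c(1, 2, 3), rep(2, 3))$r2, 0)
  expect_true(is.na(goodness_of_fit(c(2, 2), c(1, 2))$r2))
  expect_error(goodness_of_fit(1:3, 1:4), class = "nrfit_invalid_input")
})
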