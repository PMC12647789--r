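test_that("min-max normalization maps to [-1, 1] and inverts exactly", {
  d <- nr_data(c(0, 10), c(3, 7))
  n <- nr_normalize(d)
  expect_equal(n$data$nutrient, c(-1, 1))
  d2 <- nr_data(c(2, 6, 10), c(1, 2, 3))
  expect_equal(nr_normalize(d2)$data$nutrient, c(-1, 0, 1))

  d3 <- simulate_nr(sim_design(TRUTH, seed = 5))
  n3 <- nr_normalize(d3)
  sc <- n3$scaling
  back_x <- (n3$data$nutrient + 1) / 2 * (sc$x_max - sc$x_min) + sc$x_min
  back_y <- (n3$data$response + 1) / 2 * (sc$y_max - sc$y_min) + sc$y_min
  expect_equal(back_x, d3$nutrient, tolerance = 1e-12)
  expect_equal(back_y, d3$response, tolerance = 1e-12)

  expect_error(nr_normalize(nr_data(c(1, 1), c(2, 3))),
               class = "nrfit_degenerate_data")
  expect_error(nr_normalize(nr_data(c(1, 2), c(3, 3))),
               class = "nrfit_degenerate_data")
})

test_that("denormalization is the exact affine composition of the network", {
  # identity scaling: weights pass straight through
  sc_id <- list(x_min = -1, x_max = 1, y_min = -1, y_max = 1)
  p <- denormalize_params(c(0.7, 0.2, 0.9, 0.1), sc_id)
  expect_equal(unlist(p), c(A = 0.9, c = 0.7, b = 0.2, B = 0.1))

  # round-trip oracle: original-unit curve == unscale(network(scale(x)))
  set.seed(401)
  for (i in 1:25) {
    s <- sample(c(-1, 1), 1)
    w <- c(s * runif(1, 0.1, 3), runif(1, -2, 2),
           s * runif(1, 0.1, 3), runif(1, -2, 2))
    sc <- list(x_min = runif(1, 0, 5), y_min = runif(1, -10, 10))
    sc$x_max <- sc$x_min + runif(1, 1, 20)
    sc$y_max <- sc$y_min + runif(1, 1, 50)
    p <- denormalize_params(w, sc)
    expect_true(p$A > 0 && p$c > 0)   # canonical even when w2 < 0
    x <- seq(sc$x_min - 1, sc$x_max + 1, length.out = 50)
    xn <- 2 * (x - sc$x_min) / (sc$x_max - sc$x_min) - 1
    yn <- w[3] * tanh(w[1] * xn + w[2]) + w[4]
    y <- (yn + 1) / 2 * (sc$y_max - sc$y_min) + sc$y_min
    expect_equal(predict(p, x), y, tolerance = 1e-10)
  }

  expect_error(denormalize_params(c(1, 0, 1, 0),
                                  list(x_min = 2, x_max = 2, y_min = 0, y_max = 1)),
               class = "nrfit_degenerate_data")
})

test_that("noiseless parameter recovery is exact to better than 1%", {
  d <- simulate_nr(sim_design(TRUTH, levels = seq(2, 20, length.out = 30),
                              replicates = 1L, noise = 0, seed = 1))
  f <- nr_fit(d, train_config(seed = 2))
  rel <- abs(unlist(f$params) - unlist(TRUTH)) / abs(unlist(TRUTH))
  expect_true(all(rel < 0.01))
})

test_that("with 5% noise the training RMSE sits at the noise scale", {
  d <- simulate_nr(sim_design(TRUTH, levels = seq(2, 20, length.out = 30),
                              replicates = 1L, noise = 0.05, seed = 21))
  f <- nr_fit(d, train_config(seed = 22))
  noise_scale <- 0.05 * mean(predict(TRUTH, d$nutrient))
  expect_gt(f$gof_train$rmse, 0.7 * noise_scale)
  expect_lt(f$gof_train$rmse, 1.3 * noise_scale)
})

test_that("fit is deterministic given its seed and validates input", {
  d <- simulate_nr(sim_design(TRUTH, seed = 31))
  f1 <- nr_fit(d, train_config(seed = 32))
  f2 <- nr_fit(d, train_config(seed = 32))
  expect_identical(unlist(f1$params), unlist(f2$params))

  expect_error(nr_fit(nr_data(1:4, c(1, 2, 3, 4))),
               class = "nrfit_invalid_input")      # < 5 points
  expect_error(nr_fit(nr_data(rep(1, 6), 1:6)),
               class = "nrfit_degenerate_data")    # one nutrient level
  expect_error(nr_fit(nr_data(1:6, rep(2, 6))),
               class = "nrfit_degenerate_data")    # constant response
})

test_that("evidence-framework state is sane and accepted steps decrease F", {
  d <- simulate_nr(sim_design(TRUTH, seed = 41))
  norm <- nr_normalize(d)
  set.seed(42)
  for (i in 1:5) {
    tr <- nrfit:::cpp_br_train(norm$data$nutrient, norm$data$response,
                               runif(4, -1, 1), 300L, 1e-7, 1e-7,
                               0.005, 10, 0.1, TRUE)$trace
    expect_true(all(tr[, 2] < tr[, 1]))            # F_accepted < F_before
    expect_true(all(tr[, 3] > 0 & tr[, 4] > 0))    # alpha, beta positive
    expect_true(all(tr[, 5] >= 0 & tr[, 5] <= 4))  # gamma in [0, 4]
  }
})

test_that("regularization shrinks weights relative to plain least squares", {
  d <- simulate_nr(sim_design(TRUTH, seed = 42))
  norm <- nr_normalize(d)
  set.seed(99)
  shrunk <- logical(0)
  for (i in 1:5) {
    init <- runif(4, -1, 1)
    br <- nrfit:::cpp_br_train(norm$data$nutrient, norm$data$response, init,
                               300L, 1e-7, 1e-7, 0.005, 10, 0.1, TRUE)
    ls <- nr_fit_unregularized(d, init)
    shrunk <- c(shrunk, br$ew < ls$ew)
  }
  expect_true(all(shrunk))
})
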