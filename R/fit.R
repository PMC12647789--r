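#' Training settings for the Bayesian-regularized trainer
#'
#' The single neuron is trained in min-max-normalized space by
#' Levenberg-Marquardt on the evidence-framework objective
#' `F = beta * E_D + alpha * E_W` (`E_D` half the residual sum of
#' squares, `E_W` half the squared-weight sum over all four normalized
#' weights, biases included). After every accepted step the
#' hyperparameters are re-estimated: `gamma = k - alpha * tr(H^-1)` with
#' `H = beta * J'J + alpha * I`, then `alpha = gamma / (2 E_W)` and
#' `beta = (N - gamma) / (2 E_D)`. Weight decay shrinks the normalized
#' weights, preventing overfitting on the small datasets typical of
#' nutrition trials.
#'
#' @param max_iterations maximum accepted LM iterations per restart.
#' @param grad_tol stop when the objective gradient norm falls below this.
#' @param obj_tol stop when the relative objective change stays below
#'   this for 5 consecutive accepted steps.
#' @param restarts number of seeded random initializations; the restart
#'   with the lowest final `E_D` wins (ties: lowest index).
#' @param seed RNG seed for the initialization sub-stream.
#' @param mu0,mu_inc,mu_dec initial LM damping and its increase/decrease
#'   factors (defaults mirror the customary 0.005 / x10 / x0.1 schedule).
#' @return a `train_config` object.
#' @export
train_config <- function(max_iterations = 300L, grad_tol = 1e-7,
                         obj_tol = 1e-7, restarts = 5L, seed = NULL,
                         mu0 = 0.005, mu_inc = 10, mu_dec = 0.1) {
  if (max_iterations < 1L || restarts < 1L)
    stop_nrfit("max_iterations and restarts must be >= 1", "nrfit_invalid_input")
  if (grad_tol <= 0 || obj_tol <= 0)
    stop_nrfit("tolerances must be positive", "nrfit_invalid_input")
  structure(list(max_iterations = as.integer(max_iterations),
                 grad_tol = grad_tol, obj_tol = obj_tol,
                 restarts = as.integer(restarts), seed = seed,
                 mu0 = mu0, mu_inc = mu_inc, mu_dec = mu_dec),
            class = "train_config")
}

#' Min-max normalize a dataset to `[-1, 1]`
#'
#' Affine map of each coordinate onto `[-1, 1]`, the range in which the
#' tanh unit and weight decay are well scaled. The returned scaling
#' record holds the four extrema for exact inversion.
#'
#' @param data an [nr_data] object with at least 2 distinct nutrient
#'   values and 2 distinct responses.
#' @return list with `data` (normalized `nr_data`) and `scaling`
#'   (`x_min`, `x_max`, `y_min`, `y_max`).
#' @export
nr_normalize <- function(data) {
  stopifnot(inherits(data, "nr_data"))
  sc <- list(x_min = min(data$nutrient), x_max = max(data$nutrient),
             y_min = min(data$response), y_max = max(data$response))
  if (sc$x_min == sc$x_max)
    stop_nrfit("degenerate data: all nutrient values identical", "nrfit_degenerate_data")
  if (sc$y_min == sc$y_max)
    stop_nrfit("degenerate data: all responses identical", "nrfit_degenerate_data")
  xn <- 2 * (data$nutrient - sc$x_min) / (sc$x_max - sc$x_min) - 1
  yn <- 2 * (data$response - sc$y_min) / (sc$y_max - sc$y_min) - 1
  list(data = nr_data(xn, yn, group = data$group), scaling = sc)
}

#' Convert normalized network weights to original-unit parameters
#'
#' The normalized network `y_n = w2 * tanh(w1 * x_n + b1) + b2` composed
#' with the affine min-max maps is again a single-neuron curve in
#' original units:
#' `A = w2 * (y_max - y_min) / 2`,
#' `B = b2 * (y_max - y_min) / 2 + (y_max + y_min) / 2`,
#' `c = 2 * w1 / (x_max - x_min)`,
#' `b = b1 - w1 * (x_max + x_min) / (x_max - x_min)`.
#' The result is canonicalized (`A > 0`, `c > 0`).
#'
#' @param weights numeric `(w1, b1, w2, b2)`.
#' @param scaling scaling record from [nr_normalize()].
#' @return canonical [neuron_params].
#' @export
denormalize_params <- function(weights, scaling) {
  stopifnot(length(weights) == 4L)
  if (scaling$x_min == scaling$x_max || scaling$y_min == scaling$y_max)
    stop_nrfit("zero-width scaling range", "nrfit_degenerate_data")
  w1 <- weights[[1]]; b1 <- weights[[2]]; w2 <- weights[[3]]; b2 <- weights[[4]]
  ys <- (scaling$y_max - scaling$y_min) / 2
  A <- w2 * ys
  B <- b2 * ys + (scaling$y_max + scaling$y_min) / 2
  cc <- 2 * w1 / (scaling$x_max - scaling$x_min)
  b <- b1 - w1 * (scaling$x_max + scaling$x_min) / (scaling$x_max - scaling$x_min)
  canonicalize(neuron_params(A, cc, b, B))
}

#' Fit the single-neuron model with Bayesian regularization
#'
#' Runs `config$restarts` seeded random initializations (all four
#' normalized weights from Uniform(-1, 1)); each is optimized by
#' Levenberg-Marquardt on the evidence-framework objective (see
#' [train_config()]); the restart with the lowest final half residual
#' sum of squares `E_D` is returned. Deterministic given `config$seed`.
#'
#' @param data an [nr_data] object (>= 5 points, >= 2 distinct nutrient
#'   levels) — typically the augmented pool.
#' @param config a [train_config] object.
#' @param original optional [nr_data] of the un-augmented points;
#'   goodness of fit is reported on both, and downstream reporting uses
#'   the original points.
#' @return an object of class `nr_fit`: `params` (canonical
#'   [neuron_params]), `weights`, `scaling`, `converged`, `iterations`,
#'   `state` (final `alpha`, `beta`, `gamma`, `E_D`, `E_W`, objective),
#'   `gof_train`, `gof_original`, and the accepted-step `trace`.
#' @examples
#' d <- simulate_nr(sim_design(neuron_params(100, 0.5, -4, 150),
#'                             levels = seq(2, 20, length.out = 8),
#'                             replicates = 2, noise = 0.05, seed = 1))
#' f <- nr_fit(d, train_config(seed = 1))
#' f$params
#' @export
nr_fit <- function(data, config = train_config(), original = NULL) {
  stopifnot(inherits(data, "nr_data"), inherits(config, "train_config"))
  if (nrow(data) < 5L)
    stop_nrfit("at least 5 points are required", "nrfit_invalid_input")
  if (length(unique(data$nutrient)) < 2L)
    stop_nrfit("degenerate data: fewer than 2 distinct nutrient levels",
               "nrfit_degenerate_data")
  norm <- nr_normalize(data)
  xn <- norm$data$nutrient
  yn <- norm$data$response

  if (!is.null(config$seed))
    set.seed(derive_seed(config$seed, STAGE_INIT))
  inits <- matrix(runif(4L * config$restarts, -1, 1), ncol = 4L)

  best <- NULL
  best_ed <- Inf
  for (r in seq_len(config$restarts)) {
    res <- tryCatch(
      cpp_br_train(xn, yn, inits[r, ], config$max_iterations,
                   config$grad_tol, config$obj_tol,
                   config$mu0, config$mu_inc, config$mu_dec, TRUE),
      error = function(e) NULL)
    if (is.null(res) || !all(is.finite(res$w))) next
    if (res$ed < best_ed) { best_ed <- res$ed; best <- res; best$restart <- r }
  }
  if (is.null(best))
    stop_nrfit("fit failure: all restarts diverged or returned non-finite weights",
               "nrfit_fit_failure")

  params <- tryCatch(denormalize_params(best$w, norm$scaling),
                     error = function(e) NULL)
  if (is.null(params))
    stop_nrfit("fit failure: fitted curve is flat or decreasing in nutrient",
               "nrfit_fit_failure")

  gof_train <- goodness_of_fit(data$response, predict(params, data$nutrient))
  gof_original <- if (!is.null(original))
    goodness_of_fit(original$response, predict(params, original$nutrient))
  else NULL

  structure(list(params = params, weights = as.numeric(best$w),
                 scaling = norm$scaling, converged = best$converged,
                 iterations = best$iterations, restart = best$restart,
                 state = list(alpha = best$alpha, beta = best$beta,
                              gamma = best$gamma, ed = best$ed, ew = best$ew,
                              objective = best$objective,
                              reason = best$reason),
                 trace = best$trace,
                 gof_train = gof_train, gof_original = gof_original),
            class = "nr_fit")
}

#' @export
print.nr_fit <- function(x, ...) {
  cat("<nr_fit> ", format(x$params), "\n", sep = "")
  cat(sprintf("  converged: %s (%d iterations, restart %d, %s)\n",
              x$converged, x$iterations, x$restart, x$state$reason))
  cat(sprintf("  training RMSE %.4g, R2 %.4g\n", x$gof_train$rmse, x$gof_train$r2))
  if (!is.null(x$gof_original))
    cat(sprintf("  original-points RMSE %.4g, R2 %.4g\n",
                x$gof_original$rmse, x$gof_original$r2))
  invisible(x)
}

#' Unregularized least-squares fit (diagnostic)
#'
#' Same Levenberg-Marquardt engine with `alpha` pinned at 0 and
#' `beta = 1` (plain nonlinear least squares). Used to demonstrate the
#' weight-shrinkage effect of the evidence framework; not part of the
#' standard pipeline.
#'
#' @inheritParams nr_fit
#' @param init numeric `(w1, b1, w2, b2)` starting weights in
#'   normalized space.
#' @return list with `weights`, `ed`, `ew` in normalized space.
#' @export
nr_fit_unregularized <- function(data, init, config = train_config()) {
  norm <- nr_normalize(data)
  res <- cpp_br_train(norm$data$nutrient, norm$data$response, init,
                      config$max_iterations, config$grad_tol, config$obj_tol,
                      config$mu0, config$mu_inc, config$mu_dec, FALSE)
  list(weights = as.numeric(res$w), ed = res$ed, ew = res$ew)
}
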