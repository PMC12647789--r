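#' Bootstrap settings
#'
#' Non-parametric bootstrap over the augmented pool: each iteration
#' draws, with replacement, a sample whose size matches the original
#' dataset (`"original_n"`, the default protocol), the augmented pool
#' (`"augmented_n"`), or an explicit count; fits the neuron; and derives
#' all metrics. Percentile confidence bounds default to the 2.5th and
#' 97.5th percentiles of the per-quantity distributions (asymmetric by
#' construction), computed by linear interpolation between order
#' statistics (R quantile type 7), a fixed documented rule so bounds are
#' bit-reproducible.
#'
#' @param n_iterations number of bootstrap refits (default 100).
#' @param sample_size `"original_n"`, `"augmented_n"`, or an integer.
#' @param percentiles lower/upper percentile bounds (default 2.5, 97.5).
#' @param seed RNG seed for the bootstrap sub-stream.
#' @return a `boot_config` object.
#' @export
boot_config <- function(n_iterations = 100L, sample_size = "original_n",
                        percentiles = c(2.5, 97.5), seed = NULL) {
  if (n_iterations < 1L)
    stop_nrfit("n_iterations must be >= 1", "nrfit_invalid_input")
  if (length(percentiles) != 2L || percentiles[1] <= 0 ||
      percentiles[2] >= 100 || percentiles[1] >= percentiles[2])
    stop_nrfit("percentiles must satisfy 0 < lower < upper < 100",
               "nrfit_invalid_input")
  structure(list(n_iterations = as.integer(n_iterations),
                 sample_size = sample_size, percentiles = percentiles,
                 seed = seed),
            class = "boot_config")
}

boot_sample_size <- function(policy, n_original, n_augmented) {
  if (is.numeric(policy)) return(as.integer(policy))
  switch(policy,
         original_n = n_original,
         augmented_n = n_augmented,
         stop_nrfit("unknown sample_size policy", "nrfit_invalid_input"))
}

#' Bootstrap ensemble of single-neuron fits
#'
#' Runs the resample-refit-derive loop: per iteration a with-replacement
#' sample of the configured size is drawn from the augmented pool, the
#' neuron is fitted ([nr_fit()]), canonical parameters are extracted and
#' all metrics are derived using the *original* dataset's minimum
#' nutrient (augmentation jitters the minimum stochastically, so the lag
#' anchor comes from the data as measured). Failed fits are recorded and
#' skipped in summaries, never retried (retries would bias the
#' distribution). Deterministic given `boot_cfg$seed`.
#'
#' @param augmented the augmented [nr_data] pool (from [augment()]).
#' @param original the original [nr_data] the pool was derived from.
#' @param train_cfg a [train_config].
#' @param boot_cfg a [boot_config].
#' @param levels requirement fractions passed to [derive_metrics()].
#' @return an object of class `nr_boot`: `fits` (per-iteration `nr_fit`
#'   or `NULL`), `distributions` (matrix `n_iterations` x quantities,
#'   `NA` for failed/undefined entries), `n_failed`, `selected`
#'   (index, fit, selection RMSE vs the ensemble mean prediction, and
#'   reporting RMSE vs the observed data), plus the inputs needed to
#'   reproduce the run.
#' @export
nr_bootstrap <- function(augmented, original, train_cfg = train_config(),
                         boot_cfg = boot_config(), levels = c(0.95, 0.99)) {
  stopifnot(inherits(augmented, "nr_data"), inherits(original, "nr_data"))
  m <- boot_sample_size(boot_cfg$sample_size, nrow(original), nrow(augmented))
  if (m < 5L)
    stop_nrfit("bootstrap sample size must be >= 5", "nrfit_invalid_input")
  n_it <- boot_cfg$n_iterations
  x_min <- min(original$nutrient)

  quantities <- c("A", "c", "b", "B", "r_max", "nutrient_star",
                  "response_star", "nutrient_lag", "half_life",
                  "response_inf", paste0("req_", sprintf("%g", levels)))
  dist <- matrix(NA_real_, nrow = n_it, ncol = length(quantities),
                 dimnames = list(NULL, quantities))
  fits <- vector("list", n_it)

  seed0 <- if (is.null(boot_cfg$seed)) NULL else boot_cfg$seed
  for (i in seq_len(n_it)) {
    if (!is.null(seed0)) set.seed(derive_seed(seed0, STAGE_BOOT, i))
    idx <- sample.int(nrow(augmented), m, replace = TRUE)
    samp <- nr_data(augmented$nutrient[idx], augmented$response[idx])
    it_train <- train_cfg
    it_train$seed <- if (is.null(seed0)) NULL else derive_seed(seed0, STAGE_INIT, i)
    fit <- tryCatch(nr_fit(samp, it_train, original = original),
                    error = function(e) NULL)
    if (is.null(fit)) next
    fits[[i]] <- fit
    met <- derive_metrics(fit$params, nutrient_min = x_min, levels = levels)
    v <- c(A = fit$params$A, c = fit$params$c, b = fit$params$b,
           B = fit$params$B, metric_vector(met, drop_response_min = TRUE))
    dist[i, ] <- v[quantities]
  }

  ok <- !vapply(fits, is.null, logical(1))
  if (sum(!ok) > n_it / 2)
    stop_nrfit(sprintf("ensemble failure: %d of %d bootstrap fits failed",
                       sum(!ok), n_it), "nrfit_ensemble_failure")

  ens <- structure(list(fits = fits, distributions = dist,
                        quantities = quantities, n_failed = sum(!ok),
                        config = boot_cfg, train_config = train_cfg,
                        original = original, augmented = augmented,
                        levels = levels),
                   class = "nr_boot")
  sel <- select_model(ens, original$nutrient)
  sel_fit <- fits[[sel$index]]
  report_rmse <- goodness_of_fit(original$response,
                                 predict(sel_fit$params, original$nutrient))$rmse
  ens$selected <- list(index = sel$index, fit = sel_fit,
                       selection_rmse = sel$rmse, rmse = report_rmse)
  ens
}

#' @export
print.nr_boot <- function(x, ...) {
  cat(sprintf("<nr_boot> %d iterations (%d failed), selected model #%d\n",
              x$config$n_iterations, x$n_failed, x$selected$index))
  cat("selected: ", format(x$selected$fit$params), "\n", sep = "")
  cat(sprintf("  RMSE vs observed: %.4g\n", x$selected$rmse))
  invisible(x)
}

#' The "selected model" rule
#'
#' The reported equation comes from the single bootstrap iteration whose
#' predictions have the lowest RMSE relative to the pointwise mean
#' prediction of all successful models, evaluated at the original
#' nutrient values (configurable grid). The selection RMSE (vs the
#' ensemble mean) and the reporting RMSE (vs the observed responses) are
#' distinct quantities; both are exposed on the ensemble.
#'
#' @param ensemble an `nr_boot` object (>= 1 successful iteration).
#' @param evaluation_x nonempty nutrient vector on which predictions are
#'   compared.
#' @return list with `index` (ties resolved to the lowest index), `rmse`
#'   (the winning selection RMSE) and `all_rmse`.
#' @export
select_model <- function(ensemble, evaluation_x) {
  stopifnot(inherits(ensemble, "nr_boot"))
  evaluation_x <- check_nutrient(evaluation_x)
  ok <- which(!vapply(ensemble$fits, is.null, logical(1)))
  if (length(ok) == 0L)
    stop_nrfit("no successful bootstrap iterations", "nrfit_ensemble_failure")
  preds <- vapply(ok, function(i)
    predict(ensemble$fits[[i]]$params, evaluation_x),
    numeric(length(evaluation_x)))
  preds <- matrix(preds, nrow = length(evaluation_x))
  mean_pred <- rowMeans(preds)
  rmses <- apply(preds, 2L, function(p) sqrt(mean((p - mean_pred)^2)))
  best <- which.min(rmses)   # which.min keeps the lowest index on ties
  all_rmse <- rep(NA_real_, length(ensemble$fits))
  all_rmse[ok] <- rmses
  list(index = ok[best], rmse = rmses[best], all_rmse = all_rmse)
}

#' Summarize a bootstrap ensemble
#'
#' Per parameter and metric: mean over the defined values, percentile
#' confidence bounds (quantile type 7 at the configured percentiles),
#' and the count of undefined entries (failed fits plus arctanh domain
#' violations). A quantity undefined in every iteration is flagged.
#'
#' @param object an `nr_boot` object.
#' @param ... unused.
#' @return data frame with columns `quantity`, `mean`, `lower`, `upper`,
#'   `n_defined`, `n_undefined`.
#' @export
summary.nr_boot <- function(object, ...) {
  pct <- object$config$percentiles / 100
  rows <- lapply(object$quantities, function(q) {
    v <- object$distributions[, q]
    def <- v[!is.na(v)]
    if (length(def) == 0L)
      return(data.frame(quantity = q, mean = NA_real_, lower = NA_real_,
                        upper = NA_real_, n_defined = 0L,
                        n_undefined = length(v)))
    qs <- quantile(def, pct, names = FALSE, type = 7)
    data.frame(quantity = q, mean = mean(def), lower = qs[1], upper = qs[2],
               n_defined = length(def), n_undefined = sum(is.na(v)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentile summary of a plain numeric distribution
#'
#' The same mean/percentile rule [summary.nr_boot()] applies per
#' quantity, exposed for raw vectors (used by the enhanced boxplot and
#' in tests).
#'
#' @param values numeric vector, possibly with `NA` (undefined entries).
#' @param percentiles lower/upper percentiles.
#' @return list with `mean`, `lower`, `upper`, `n_defined`, `n_undefined`.
#' @export
summarize_distribution <- function(values, percentiles = c(2.5, 97.5)) {
  def <- values[!is.na(values)]
  if (length(def) == 0L)
    return(list(mean = NA_real_, lower = NA_real_, upper = NA_real_,
                n_defined = 0L, n_undefined = length(values)))
  qs <- quantile(def, percentiles / 100, names = FALSE, type = 7)
  list(mean = mean(def), lower = qs[1], upper = qs[2],
       n_defined = length(def), n_undefined = sum(is.na(values)))
}
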