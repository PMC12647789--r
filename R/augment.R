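#' Augmentation settings
#'
#' Proportional ("multiplicative") Gaussian noise on both coordinates:
#' each original point `(x, y)` spawns `replicates` synthetic points
#' `(x + e_x, y + e_y)` with `e_x ~ N(0, sd = frac_x * x)` and
#' `e_y ~ N(0, sd = frac_y * y)`. The defaults (10 replicates, 2\% on the
#' nutrient, 5\% on the response) emulate typical within-pen variability
#' in nutrition trials: 2\% on a 10 g/kg lysine diet is a 0.2 g/kg
#' standard deviation, within assay precision. A coordinate equal to
#' zero receives zero noise (proportional scaling is literal).
#'
#' @param replicates synthetic replicates per original point (>= 0).
#' @param frac_x,frac_y noise fractions (>= 0) for nutrient and response.
#' @param include_originals keep every original point verbatim in the pool.
#' @param seed RNG seed (integer) for reproducibility.
#' @param nonneg_policy what to do when a perturbed nutrient goes
#'   negative: `"resample"` (redraw, at most 100 attempts), `"clamp"`
#'   (truncate at 0) or `"allow"`.
#' @return an `augment_config` object.
#' @export
augment_config <- function(replicates = 10L, frac_x = 0.02, frac_y = 0.05,
                           include_originals = TRUE, seed = NULL,
                           nonneg_policy = c("resample", "clamp", "allow")) {
  nonneg_policy <- match.arg(nonneg_policy)
  if (replicates < 0 || frac_x < 0 || frac_y < 0)
    stop_nrfit("replicates and noise fractions must be non-negative",
               "nrfit_invalid_input")
  structure(list(replicates = as.integer(replicates), frac_x = frac_x,
                 frac_y = frac_y, include_originals = include_originals,
                 seed = seed, nonneg_policy = nonneg_policy),
            class = "augment_config")
}

#' Augment a dataset with proportional Gaussian noise
#'
#' Densifies a small dataset by jittering every point as described in
#' [augment_config()]. Originals (when kept) come first and verbatim;
#' group labels are inherited by the replicates. Deterministic for a
#' given `config$seed`.
#'
#' @param data an [nr_data] object with non-negative nutrient values.
#' @param config an [augment_config] object.
#' @return an [nr_data] pool of `n * (1 + replicates)` points (when
#'   `include_originals`), with a logical `augmented` column.
#' @export
augment <- function(data, config = augment_config()) {
  stopifnot(inherits(data, "nr_data"), inherits(config, "augment_config"))
  if (nrow(data) == 0L)
    stop_nrfit("dataset is empty", "nrfit_invalid_input")
  if (any(data$nutrient < 0))
    stop_nrfit("negative nutrient values cannot be augmented", "nrfit_invalid_input")
  if (!is.null(config$seed))
    set.seed(derive_seed(config$seed, STAGE_AUGMENT))

  n <- nrow(data)
  reps <- config$replicates
  draw_coord <- function(value, frac, enforce_nonneg) {
    sdv <- frac * value                       # 0 when value == 0: no noise
    out <- value + rnorm(1L, 0, sdv)
    if (enforce_nonneg && out < 0) {
      if (config$nonneg_policy == "clamp") return(0)
      if (config$nonneg_policy == "resample") {
        for (attempt in seq_len(100L)) {
          out <- value + rnorm(1L, 0, sdv)
          if (out >= 0) return(out)
        }
        stop_nrfit(sprintf(
          "augmentation failed: 100 resampling attempts left nutrient %g negative",
          value), "nrfit_augmentation_failure")
      }
    }
    out
  }

  xs <- ys <- numeric(n * reps)
  gs <- character(n * reps)
  k <- 0L
  for (i in seq_len(n)) {
    for (r in seq_len(reps)) {
      k <- k + 1L
      xs[k] <- draw_coord(data$nutrient[i], config$frac_x,
                          config$nonneg_policy != "allow")
      ys[k] <- draw_coord(data$response[i], config$frac_y, FALSE)
      gs[k] <- if (is.null(data$group)) NA_character_ else data$group[i]
    }
  }

  if (config$include_originals) {
    nutrient <- c(data$nutrient, xs)
    response <- c(data$response, ys)
    group <- if (is.null(data$group)) NULL else c(data$group, gs)
    augmented <- c(rep(FALSE, n), rep(TRUE, n * reps))
  } else {
    nutrient <- xs; response <- ys
    group <- if (is.null(data$group)) NULL else gs
    augmented <- rep(TRUE, n * reps)
  }
  out <- nr_data(nutrient, response, group = group,
                 units = attr(data, "units"), metadata = attr(data, "metadata"))
  out$augmented <- augmented
  out
}
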