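#' Run the full pipeline on one or more groups
#'
#' augment -> bootstrap -> summarize, per group, from one master seed.
#' The master seed deterministically derives independent sub-streams for
#' augmentation, every bootstrap draw, and every restart initialization,
#' so two runs with the same inputs produce identical numbers.
#'
#' @param data an [nr_data] object (optionally with a `group` column).
#' @param augment_cfg an [augment_config] (its `seed` is overridden by
#'   the derived sub-stream seed when `seed` is given).
#' @param train_cfg a [train_config].
#' @param boot_cfg a [boot_config].
#' @param levels requirement fractions.
#' @param seed master seed; `NULL` leaves the RNG state alone.
#' @return named list of `nr_boot` ensembles, one per group, with the
#'   run configuration attached as an attribute.
#' @export
nr_run <- function(data, augment_cfg = augment_config(),
                   train_cfg = train_config(), boot_cfg = boot_config(),
                   levels = c(0.95, 0.99), seed = NULL) {
  groups <- nr_split_groups(data)
  ensembles <- vector("list", length(groups))
  names(ensembles) <- names(groups)
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    a_cfg <- augment_cfg; t_cfg <- train_cfg; b_cfg <- boot_cfg
    if (!is.null(seed)) {
      # distinct sub-streams per group and stage
      a_cfg$seed <- derive_seed(seed, STAGE_AUGMENT, gi)
      t_cfg$seed <- derive_seed(seed, STAGE_INIT, gi)
      b_cfg$seed <- derive_seed(seed, STAGE_BOOT, gi)
    }
    pool <- augment(g, a_cfg)
    ensembles[[gi]] <- nr_bootstrap(pool, g, t_cfg, b_cfg, levels = levels)
  }
  attr(ensembles, "run_config") <- list(
    augment = unclass(augment_cfg), train = unclass(train_cfg),
    bootstrap = unclass(boot_cfg), levels = levels, seed = seed)
  ensembles
}

#' Write the standard result reports
#'
#' Emits, into `out_dir`:
#' \itemize{
#'   \item `parameters.csv` — per group, mean/lower/upper/undefined-count
#'     for A, c, b, B;
#'   \item `metrics.csv` — the same for every derived metric;
#'   \item `selected_model.json` — the selected equation per group with
#'     parameters at 3 significant digits, its RMSE vs the observed
#'     points and selection RMSE;
#'   \item `curves.csv` — dense grid with mean prediction, percentile
#'     band, mean derivative and its band;
#'   \item `comparisons.csv` — ANOVA/Tukey/letters (when >= 2 groups);
#'   \item `manifest.json` — full configuration, seeds and versions.
#' }
#'
#' @param ensembles named list of `nr_boot` (from [nr_run()]).
#' @param out_dir output directory (created if missing).
#' @param comparison optional `nr_comparison`; computed automatically
#'   when two or more groups are present.
#' @param grid_n number of grid points for `curves.csv`.
#' @return invisible character vector of the files written.
#' @export
write_report <- function(ensembles, out_dir, comparison = NULL, grid_n = 101L) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_nrfit(sprintf("cannot create output directory %s", out_dir),
               "nrfit_io_error")
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    files <<- c(files, p)
  }

  summaries <- lapply(names(ensembles), function(g) {
    s <- summary(ensembles[[g]])
    s$group <- g
    s
  })
  all_sum <- do.call(rbind, summaries)
  par_rows <- all_sum[all_sum$quantity %in% c("A", "c", "b", "B"), ]
  met_rows <- all_sum[!all_sum$quantity %in% c("A", "c", "b", "B"), ]
  emit(par_rows[, c("group", "quantity", "mean", "lower", "upper",
                    "n_defined", "n_undefined")], "parameters.csv")
  emit(met_rows[, c("group", "quantity", "mean", "lower", "upper",
                    "n_defined", "n_undefined")], "metrics.csv")

  sel <- lapply(names(ensembles), function(g) {
    e <- ensembles[[g]]
    p <- e$selected$fit$params
    list(group = g, equation = format(p, digits = 3),
         parameters = list(A = p$A, c = p$c, b = p$b, B = p$B),
         index = e$selected$index, rmse = e$selected$rmse,
         selection_rmse = e$selected$selection_rmse,
         r2 = e$selected$fit$gof_original$r2,
         n_failed = e$n_failed)
  })
  names(sel) <- names(ensembles)
  sel_path <- file.path(out_dir, "selected_model.json")
  jsonlite::write_json(sel, sel_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, sel_path)

  curve_rows <- lapply(names(ensembles), function(g) {
    cv <- ensemble_curves(ensembles[[g]], grid_n = grid_n)
    cv$group <- g
    cv
  })
  emit(do.call(rbind, curve_rows), "curves.csv")

  if (is.null(comparison) && length(ensembles) >= 2L)
    comparison <- compare_groups(ensembles)
  if (!is.null(comparison))
    emit(comparison_table(comparison), "comparisons.csv")

  manifest <- list(
    package = "nrfit", version = as.character(packageVersion("nrfit")),
    r_version = as.character(getRversion()),
    created = "run manifest (timestamps omitted for reproducibility)",
    run_config = attr(ensembles, "run_config"),
    groups = names(ensembles),
    n_points = vapply(ensembles, function(e) nrow(e$original), 1L))
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, man_path)
  invisible(files)
}

#' Ensemble curves on a dense grid
#'
#' Pointwise mean and percentile band of the response and of the
#' marginal-efficiency (first-derivative) curve across all successful
#' bootstrap models.
#'
#' @param ensemble an `nr_boot` object.
#' @param grid_n grid size over the observed nutrient range.
#' @return data frame `x`, `mean`, `lower`, `upper`, `d_mean`,
#'   `d_lower`, `d_upper`.
#' @export
ensemble_curves <- function(ensemble, grid_n = 101L) {
  stopifnot(inherits(ensemble, "nr_boot"))
  xr <- range(ensemble$original$nutrient)
  grid <- seq(xr[1], xr[2], length.out = grid_n)
  ok <- which(!vapply(ensemble$fits, is.null, logical(1)))
  pred <- vapply(ok, function(i) predict(ensemble$fits[[i]]$params, grid),
                 numeric(grid_n))
  der <- vapply(ok, function(i) nr_slope(ensemble$fits[[i]]$params, grid),
                numeric(grid_n))
  pred <- matrix(pred, nrow = grid_n); der <- matrix(der, nrow = grid_n)
  pct <- ensemble$config$percentiles / 100
  band <- function(m) t(apply(m, 1L, quantile, probs = pct, names = FALSE,
                              type = 7))
  pb <- band(pred); db <- band(der)
  data.frame(x = grid, mean = rowMeans(pred), lower = pb[, 1], upper = pb[, 2],
             d_mean = rowMeans(der), d_lower = db[, 1], d_upper = db[, 2])
}
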