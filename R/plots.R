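#' Response and marginal-efficiency curve plot
#'
#' Two stacked panels: observed points (augmented points lighter), the
#' ensemble mean curve with its percentile band; and the mean
#' first-derivative curve with its band, whose peak sits at the selected
#' model's inflection point.
#'
#' @param ensemble an `nr_boot` object.
#' @param data optional [nr_data] pool to draw as points (defaults to
#'   the ensemble's augmented pool).
#' @param out_path output file; extension selects the device (`.png` or
#'   `.svg`).
#' @param grid_n curve grid size.
#' @return invisibly, the curve data frame that was drawn.
#' @export
plot_curves <- function(ensemble, data = NULL, out_path, grid_n = 201L) {
  stopifnot(inherits(ensemble, "nr_boot"))
  if (is.null(data)) data <- ensemble$augmented
  cv <- ensemble_curves(ensemble, grid_n = grid_n)
  open_device(out_path, width = 7, height = 8)
  on.exit(grDevices.dev_off())
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))

  band_col <- grDevices::adjustcolor("steelblue", 0.3)
  aug <- if (!is.null(data$augmented)) data$augmented else rep(FALSE, nrow(data))
  plot(data$nutrient, data$response, pch = 16,
       col = ifelse(aug, grDevices::adjustcolor("grey40", 0.35), "black"),
       xlab = "nutrient", ylab = "response", main = "response")
  graphics::polygon(c(cv$x, rev(cv$x)), c(cv$lower, rev(cv$upper)),
                    col = band_col, border = NA)
  graphics::lines(cv$x, cv$mean, col = "steelblue4", lwd = 2)

  plot(cv$x, cv$d_mean, type = "n", xlab = "nutrient",
       ylab = "dResponse/dNutrient", main = "marginal efficiency",
       ylim = range(cv$d_lower, cv$d_upper))
  graphics::polygon(c(cv$x, rev(cv$x)), c(cv$d_lower, rev(cv$d_upper)),
                    col = band_col, border = NA)
  graphics::lines(cv$x, cv$d_mean, col = "steelblue4", lwd = 2)
  invisible(cv)
}

#' Enhanced boxplot of bootstrap distributions per group
#'
#' Per group: IQR box with median line, notch at
#' `median +/- 1.57 * IQR / sqrt(n)` (McGill's approximate 95\% CI of
#' the median), whiskers to the most extreme non-outliers (1.5 IQR
#' rule), outliers as points, the mean as an asterisk, a rectangle for
#' the mean's 95\% CI from 100 bootstrap resamples of the distribution,
#' and the compact letter annotated above.
#'
#' @param distributions named list of numeric vectors (one per group);
#'   `NA`s dropped.
#' @param letters_map optional named character vector of compact letters.
#' @param out_path output file (`.png` or `.svg`).
#' @param seed seed for the mean-CI resampling.
#' @param main plot title.
#' @return invisibly, a list of the per-group drawing statistics.
#' @export
plot_enhanced_boxplot <- function(distributions, letters_map = NULL, out_path,
                                  seed = 1L, main = "") {
  if (length(distributions) == 0L)
    stop_nrfit("need at least one group distribution", "nrfit_invalid_input")
  stats_list <- lapply(distributions, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      stop_nrfit("empty distribution", "nrfit_invalid_input")
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr; hi_fence <- q[3] + 1.5 * iqr
    inside <- v[v >= lo_fence & v <= hi_fence]
    notch <- 1.57 * iqr / sqrt(length(v))
    list(v = v, q = q, iqr = iqr,
         whisk = c(min(inside), max(inside)),
         outliers = v[v < lo_fence | v > hi_fence],
         notch = c(q[2] - notch, q[2] + notch), mean = mean(v))
  })
  set.seed(derive_seed(seed, STAGE_PLOT))
  for (i in seq_along(stats_list)) {
    v <- stats_list[[i]]$v
    bm <- replicate(100L, mean(sample(v, replace = TRUE)))
    stats_list[[i]]$mean_ci <- quantile(bm, c(0.025, 0.975), names = FALSE,
                                        type = 7)
  }

  open_device(out_path, width = 1.5 + 1.5 * length(distributions), height = 5)
  on.exit(grDevices.dev_off())
  all_v <- unlist(lapply(stats_list, `[[`, "v"))
  pad <- diff(range(all_v)) * 0.12 + 1e-9
  plot(NA, xlim = c(0.5, length(distributions) + 0.5),
       ylim = range(all_v) + c(-pad, pad), xaxt = "n",
       xlab = "", ylab = "value", main = main)
  graphics::axis(1, at = seq_along(distributions),
                 labels = names(distributions))
  hw <- 0.3
  for (i in seq_along(stats_list)) {
    s <- stats_list[[i]]
    graphics::rect(i - hw, s$q[1], i + hw, s$q[3], border = "black")
    graphics::segments(i - hw, s$q[2], i + hw, s$q[2], lwd = 2)
    graphics::segments(i - hw / 2, s$notch[1], i + hw / 2, s$notch[1],
                       lty = 3, col = "grey40")
    graphics::segments(i - hw / 2, s$notch[2], i + hw / 2, s$notch[2],
                       lty = 3, col = "grey40")
    graphics::segments(i, s$q[3], i, s$whisk[2])
    graphics::segments(i, s$q[1], i, s$whisk[1])
    if (length(s$outliers))
      graphics::points(rep(i, length(s$outliers)), s$outliers, pch = 1)
    graphics::rect(i - hw / 3, s$mean_ci[1], i + hw / 3, s$mean_ci[2],
                   col = grDevices::adjustcolor("grey60", 0.5), border = NA)
    graphics::points(i, s$mean, pch = 8, col = "red")
    if (!is.null(letters_map) && !is.null(names(distributions)))
      graphics::text(i, max(all_v) + pad / 2,
                     letters_map[[names(distributions)[i]]])
  }
  invisible(stats_list)
}

open_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") grDevices::svg(path, width = width, height = height)
  else grDevices::png(path, width = width * 100, height = height * 100,
                      res = 100)
}

grDevices.dev_off <- function() grDevices::dev.off()
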