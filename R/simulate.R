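#' Design of a simulated nutrient-response experiment
#'
#' Describes the stated world of a synthetic trial: a true single-neuron
#' curve evaluated at graded nutrient levels, with proportional
#' (heteroscedastic) response noise — larger responses vary more, as in
#' real feeding trials. Used for parameter-recovery and coverage
#' testing; the true parameters travel in the dataset metadata and are
#' never visible to fitting code.
#'
#' @param true_params a [neuron_params] object (the generating curve).
#' @param levels numeric vector of >= 2 nutrient levels, or `NULL` to
#'   use `seq(range[1], range[2], length.out = n_levels)`.
#' @param range,n_levels alternative specification of graded levels.
#' @param replicates observations per level (>= 1).
#' @param noise proportional response noise fraction (>= 0); each
#'   response is `predict(true_params, level) * (1 + e)`,
#'   `e ~ N(0, noise)`.
#' @param seed RNG seed.
#' @param group optional group label attached to every point.
#' @return a `sim_design` object.
#' @export
sim_design <- function(true_params, levels = NULL, range = c(2, 20),
                       n_levels = 8L, replicates = 3L, noise = 0.05,
                       seed = NULL, group = NULL) {
  stopifnot(inherits(true_params, "neuron_params"))
  if (is.null(levels))
    levels <- seq(range[1], range[2], length.out = n_levels)
  if (length(levels) < 2L)
    stop_nrfit("need >= 2 nutrient levels", "nrfit_invalid_input")
  if (replicates < 1L || noise < 0)
    stop_nrfit("replicates must be >= 1 and noise >= 0", "nrfit_invalid_input")
  structure(list(true_params = true_params, levels = as.numeric(levels),
                 replicates = as.integer(replicates), noise = noise,
                 seed = seed, group = group),
            class = "sim_design")
}

#' Simulate a nutrient-response dataset
#'
#' @param design a [sim_design] object.
#' @return an [nr_data] with `replicates` rows per level; the generating
#'   parameters are recorded in `attr(, "metadata")$true_params` for
#'   recovery scoring only.
#' @examples
#' d <- simulate_nr(sim_design(neuron_params(100, 0.5, -4, 150), seed = 7))
#' @export
simulate_nr <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(design$seed)) set.seed(as.integer(design$seed))
  x <- rep(design$levels, each = design$replicates)
  mu <- predict(design$true_params, x)
  y <- mu * (1 + rnorm(length(x), 0, design$noise))
  grp <- if (is.null(design$group)) NULL else rep(design$group, length(x))
  nr_data(x, y, group = grp,
          metadata = list(true_params = design$true_params,
                          noise = design$noise))
}

#' Deterministic fixture suite
#'
#' A named collection of small datasets spanning the regimes the
#' framework must handle: a 5-level unreplicated trial (the "small
#' data" regime), a replicated 8x3 design, a near-degenerate narrow
#' nutrient range, steep and shallow curves, and four noiseless curves
#' evaluated from published single-neuron reference fits (broiler lysine
#' accretion, broiler methionine/normal-protein, laying-hen threonine,
#' rainbow-trout phosphorus) for exact metric tests. Regenerating the
#' suite yields byte-identical data.
#'
#' @return named list of [nr_data] objects.
#' @export
nr_fixture_suite <- function() {
  ref <- reference_fits()
  noiseless <- function(row, levels) {
    p <- neuron_params(row$A, row$c, row$b, row$B)
    simulate_nr(sim_design(p, levels = levels, replicates = 1L, noise = 0))
  }
  list(
    small_n = simulate_nr(sim_design(
      neuron_params(100, 0.5, -4, 150), levels = seq(4, 16, length.out = 5),
      replicates = 1L, noise = 0.05, seed = 101)),
    replicated = simulate_nr(sim_design(
      neuron_params(100, 0.5, -4, 150), range = c(2, 20), n_levels = 8L,
      replicates = 3L, noise = 0.05, seed = 102)),
    narrow_range = simulate_nr(sim_design(
      neuron_params(100, 0.5, -4, 150), levels = seq(7.5, 8.5, length.out = 6),
      replicates = 2L, noise = 0.05, seed = 103)),
    steep = simulate_nr(sim_design(
      neuron_params(30, 2.2, -6.2, 50), levels = seq(1, 5, length.out = 7),
      replicates = 2L, noise = 0.05, seed = 104)),
    shallow = simulate_nr(sim_design(
      neuron_params(12, 0.2, -1.1, 16), levels = seq(1, 15, length.out = 8),
      replicates = 2L, noise = 0.05, seed = 105)),
    ref_broiler_lysine = noiseless(ref[ref$id == "4_broilers", ],
                                   seq(4, 16, length.out = 9)),
    ref_broiler_methionine_np = noiseless(ref[ref$id == "7_NP", ],
                                          seq(1, 5, length.out = 9)),
    ref_hen_threonine = noiseless(ref[ref$id == "10_hens", ],
                                  seq(50, 600, length.out = 9)),
    ref_trout_phosphorus = noiseless(ref[ref$id == "12_trout", ],
                                     seq(0.5, 4.5, length.out = 9))
  )
}

#' Published single-neuron reference fits
#'
#' Parameter sets (and the printed summary metrics) of single-neuron
#' tanh fits published for 23 poultry and fish nutrient-response
#' curves, shipped as a plain-text table. Used for worked-example metric
#' tests: the closed-form metrics of [derive_metrics()] can be
#' recomputed from the `A`, `c`, `b`, `B` columns and compared against
#' the printed values.
#'
#' @return data frame with identification columns, the four parameters,
#'   and the printed metric columns.
#' @export
reference_fits <- function() {
  path <- system.file("extdata", "reference_fits.csv", package = "nrfit")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
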