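#' Single-neuron model parameters
#'
#' The four trainable parameters of
#' `Response = A * tanh(c * Nutrient + b) + B`, in original data units:
#' `A` is the amplitude above/below the inflection (response units), `c`
#' the steepness per nutrient unit, `b` a dimensionless horizontal
#' offset, and `B` the response at the inflection point.
#'
#' Because tanh is odd, `(A, c, b)` and `(-A, -c, -b)` describe the same
#' curve; [canonicalize()] resolves the ambiguity to `A > 0, c > 0`
#' (monotone increasing), the form all metric formulas assume.
#'
#' @param A,c,b,B finite numeric scalars.
#' @return an object of class `neuron_params`.
#' @examples
#' p <- neuron_params(A = 57.5, c = 1.17, b = -2.12, B = 86.8)
#' predict(p, 2)
#' @export
neuron_params <- function(A, c, b, B) {
  v <- c(A = A, c = c, b = b, B = B)
  if (length(v) != 4L || !all(is.finite(v)))
    stop_nrfit("all four parameters must be finite scalars", "nrfit_invalid_input")
  structure(as.list(v), class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("Response = %.4g tanh(%.4g Nutrient %+.4g) %+.4g\n",
              x$A, x$c, x$b, x$B))
  invisible(x)
}

#' @export
format.neuron_params <- function(x, digits = 3, ...) {
  sprintf("Response = %s tanh(%s Nutrient %s %s) + %s",
          signif(x$A, digits), signif(x$c, digits),
          ifelse(x$b < 0, "-", "+"), signif(abs(x$b), digits),
          signif(x$B, digits))
}

check_nutrient <- function(nutrient) {
  if (!is.numeric(nutrient) || length(nutrient) == 0L || any(!is.finite(nutrient)))
    stop_nrfit("nutrient must be finite numeric", "nrfit_invalid_input")
  as.numeric(nutrient)
}

#' Predicted response of the single-neuron model
#'
#' Evaluates `A * tanh(c * nutrient + b) + B` elementwise. Output is
#' bounded in `[B - |A|, B + |A|]`.
#'
#' @param object a [neuron_params] object.
#' @param nutrient finite numeric scalar or vector.
#' @param ... unused.
#' @return numeric vector of predicted responses.
#' @export
predict.neuron_params <- function(object, nutrient, ...) {
  nutrient <- check_nutrient(nutrient)
  object$A * tanh(object$c * nutrient + object$b) + object$B
}

#' Marginal utilization efficiency (first derivative)
#'
#' `dResponse/dNutrient = A * c * (1 - tanh^2(c * nutrient + b))`: the
#' additional response per unit of additional nutrient. For a canonical
#' (increasing) curve it is strictly positive and peaks at the
#' inflection point `nutrient = -b/c`, where it equals `A * c`.
#'
#' @inheritParams predict.neuron_params
#' @param params a [neuron_params] object.
#' @return numeric vector of slopes.
#' @export
nr_slope <- function(params, nutrient) {
  stopifnot(inherits(params, "neuron_params"))
  nutrient <- check_nutrient(nutrient)
  t <- tanh(params$c * nutrient + params$b)
  params$A * params$c * (1 - t^2)
}

#' Resolve the tanh sign ambiguity
#'
#' Returns the parameter set with `A > 0` and `c > 0` describing the
#' identical curve (tanh is odd, so flipping the signs of `A`, `c`, `b`
#' together leaves predictions unchanged). Idempotent.
#'
#' @param params a [neuron_params] object with `A != 0`, `c != 0`.
#' @return a canonical [neuron_params] object.
#' @export
canonicalize <- function(params) {
  stopifnot(inherits(params, "neuron_params"))
  if (params$A == 0 || params$c == 0)
    stop_nrfit("degenerate model: A or c is zero", "nrfit_degenerate_model")
  A <- params$A; cc <- params$c; b <- params$b
  if (sign(A) != sign(cc))
    stop_nrfit("curve is decreasing (A*c < 0); no increasing canonical form exists",
               "nrfit_degenerate_model")
  if (A < 0) { A <- -A; cc <- -cc; b <- -b }   # joint flip through the odd tanh
  neuron_params(A, cc, b, params$B)
}

is_canonical <- function(params) params$A > 0 && params$c > 0

#' Closed-form nutritional metrics of a fitted curve
#'
#' Derives, from canonical parameters, the standard descriptors of an
#' increasing saturating nutrient-response curve:
#' \describe{
#'   \item{r_max}{maximum marginal efficiency `A*c`, attained at the
#'     inflection point.}
#'   \item{nutrient_star / response_star}{inflection point `(-b/c, B)`.}
#'   \item{nutrient_lag}{back-extrapolation of the inflection tangent to
#'     the model-predicted response at the lowest observed nutrient:
#'     `nutrient_star - (response_star - response_min) / r_max`.}
#'   \item{half_life}{nutrient level reaching 50\% of the asymptote:
#'     `(arctanh(0.5 - 0.5*B/A) - b) / c`.}
#'   \item{response_inf}{asymptotic response `A + B`.}
#'   \item{requirements}{nutrient levels reaching fraction `q` of the
#'     asymptote, `(arctanh(q - (1-q)*B/A) - b) / c`, by default
#'     `q = 0.95, 0.99`.}
#' }
#' A metric whose arctanh argument falls outside `(-1, 1)` — e.g. the
#' half-life when `B/A >= 1` because the curve starts above half its own
#' plateau — is reported as `NA` with a machine-readable reason in
#' `$undefined`, never as an error, so bootstrap summaries can count and
#' skip such iterations.
#'
#' @param params canonical [neuron_params] (use [canonicalize()] first).
#' @param nutrient_min smallest nutrient level of the *original*
#'   (pre-augmentation) dataset; needed only for `nutrient_lag`
#'   (`NA` marks the lag undefined).
#' @param levels requirement fractions, each in (0, 1).
#' @return an object of class `nr_metrics`: list with `$values` (named
#'   numeric), `$requirements` (named by level) and `$undefined` (named
#'   character reasons).
#' @examples
#' p <- neuron_params(57.5, 1.17, -2.12, 86.8)
#' derive_metrics(p, nutrient_min = 0.5)
#' @export
derive_metrics <- function(params, nutrient_min = NA_real_,
                           levels = c(0.95, 0.99)) {
  stopifnot(inherits(params, "neuron_params"))
  if (!is_canonical(params))
    stop_nrfit("parameters must be canonical (A > 0, c > 0); call canonicalize()",
               "nrfit_canonicalization_required")
  if (length(levels) && (any(!is.finite(levels)) || any(levels <= 0) || any(levels >= 1)))
    stop_nrfit("requirement levels must lie in (0, 1)", "nrfit_invalid_level")
  A <- params$A; cc <- params$c; b <- params$b; B <- params$B

  undefined <- character(0)
  inv_at <- function(arg, what) {
    # nutrient level where tanh(c*x+b) equals 'arg'
    if (!is.finite(arg) || arg <= -1 || arg >= 1) {
      undefined[[what]] <<- sprintf("arctanh argument %.6g outside (-1, 1)", arg)
      return(NA_real_)
    }
    (atanh(arg) - b) / cc
  }

  r_max <- A * cc
  nutrient_star <- -b / cc
  response_star <- B
  response_inf <- A + B
  half_life <- inv_at(0.5 - 0.5 * B / A, "half_life")
  requirements <- vapply(levels, function(q)
    inv_at(q - (1 - q) * B / A, sprintf("req_%g", q)), numeric(1))
  names(requirements) <- sprintf("%g", levels)

  if (is.na(nutrient_min)) {
    response_min <- NA_real_
    nutrient_lag <- NA_real_
    undefined[["nutrient_lag"]] <- "nutrient_min not supplied"
  } else {
    response_min <- predict(params, nutrient_min)
    nutrient_lag <- nutrient_star - (response_star - response_min) / r_max
  }

  values <- c(r_max = r_max, nutrient_star = nutrient_star,
              response_star = response_star, nutrient_lag = nutrient_lag,
              half_life = half_life, response_inf = response_inf,
              response_min = response_min)
  structure(list(values = values, requirements = requirements,
                 undefined = undefined, levels = levels),
            class = "nr_metrics")
}

#' @export
print.nr_metrics <- function(x, ...) {
  v <- metric_vector(x)
  cat("<nr_metrics>\n")
  print(round(v, 4))
  if (length(x$undefined)) {
    cat("undefined:\n")
    for (nm in names(x$undefined)) cat(sprintf("  %s: %s\n", nm, x$undefined[[nm]]))
  }
  invisible(x)
}

#' Flatten an `nr_metrics` object to a named numeric vector
#'
#' Requirement entries are named `req_<level>` (e.g. `req_0.95`);
#' undefined metrics appear as `NA`.
#'
#' @param metrics an `nr_metrics` object.
#' @param drop_response_min drop the bookkeeping `response_min` entry.
#' @return named numeric vector.
#' @export
metric_vector <- function(metrics, drop_response_min = FALSE) {
  stopifnot(inherits(metrics, "nr_metrics"))
  v <- metrics$values
  if (drop_response_min) v <- v[setdiff(names(v), "response_min")]
  req <- metrics$requirements
  if (length(req)) names(req) <- paste0("req_", names(req))
  c(v, req)
}

#' Goodness of fit of predictions against observations
#'
#' @param observed,predicted numeric vectors of equal nonzero length.
#' @return list with `rmse` (root mean square error, response units) and
#'   `r2` (1 - SS_res/SS_tot about the observed mean; `NA` when the
#'   observations are constant).
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (!is.numeric(observed) || !is.numeric(predicted) ||
      length(observed) == 0L || length(observed) != length(predicted))
    stop_nrfit("observed and predicted must be equal-length nonzero numeric vectors",
               "nrfit_invalid_input")
  res <- observed - predicted
  rmse <- sqrt(mean(res^2))
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(res^2) / ss_tot
  list(rmse = rmse, r2 = r2)
}
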