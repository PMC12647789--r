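#' Construct a nutrient-response dataset
#'
#' The basic container for observed dose-response points: a data frame
#' with numeric columns `nutrient` and `response` and an optional factor
#' `group`, plus units metadata carried as attributes.
#'
#' @param nutrient numeric vector of nutrient levels (e.g. g/kg diet).
#' @param response numeric vector of responses (e.g. g/bird).
#' @param group optional character/factor of group labels.
#' @param units named character vector, e.g.
#'   `c(nutrient = "g/kg diet", response = "g/bird")`.
#' @param metadata optional list (e.g. the generating parameters of a
#'   simulated dataset); never consulted by fitting code.
#' @return an object of class `nr_data` (a data frame).
#' @examples
#' d <- nr_data(c(2, 4, 6), c(10, 30, 35))
#' @export
nr_data <- function(nutrient, response, group = NULL,
                    units = c(nutrient = "", response = ""),
                    metadata = list()) {
  nutrient <- as.numeric(nutrient)
  response <- as.numeric(response)
  if (length(nutrient) != length(response))
    stop_nrfit("nutrient and response must have equal length", "nrfit_invalid_input")
  if (length(nutrient) == 0L)
    stop_nrfit("dataset is empty", "nrfit_invalid_input")
  if (any(!is.finite(nutrient)) || any(!is.finite(response)))
    stop_nrfit("non-finite nutrient or response value", "nrfit_invalid_input")
  df <- data.frame(nutrient = nutrient, response = response)
  if (!is.null(group)) {
    if (length(group) != length(nutrient))
      stop_nrfit("group must match data length", "nrfit_invalid_input")
    df$group <- as.character(group)
  }
  structure(df, units = units, metadata = metadata,
            class = c("nr_data", "data.frame"))
}

#' @export
print.nr_data <- function(x, ...) {
  cat(sprintf("<nr_data> %d points", nrow(x)))
  if (!is.null(x$group))
    cat(sprintf(", %d group(s): %s", length(unique(x$group)),
                paste(unique(x$group), collapse = ", ")))
  u <- attr(x, "units")
  if (!is.null(u) && any(nzchar(u)))
    cat(sprintf(" [nutrient: %s; response: %s]", u[["nutrient"]], u[["response"]]))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Split a multi-group dataset into one `nr_data` per group
#'
#' @param data an [nr_data] object.
#' @return a named list of `nr_data` (a single unnamed-group list when no
#'   group column is present), in order of first appearance.
#' @export
nr_split_groups <- function(data) {
  stopifnot(inherits(data, "nr_data"))
  if (is.null(data$group)) return(list(all = data))
  out <- lapply(unique(data$group), function(g) {
    idx <- data$group == g
    nr_data(data$nutrient[idx], data$response[idx], group = data$group[idx],
            units = attr(data, "units"), metadata = attr(data, "metadata"))
  })
  names(out) <- unique(data$group)
  out
}

#' Read a nutrient-response CSV file
#'
#' Expects a header with columns `nutrient`, `response` and optionally a
#' group column; UTF-8, '.' decimal separator. Malformed cells are
#' reported with their row number.
#'
#' @param path path to the CSV file.
#' @param group_column name of the optional grouping column.
#' @return an [nr_data] object (with a `group` column when present).
#' @export
read_nr_csv <- function(path, group_column = "group") {
  if (!file.exists(path))
    stop_nrfit(sprintf("file not found: %s", path), "nrfit_io_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L)
    stop_nrfit(sprintf("empty file: %s", path), "nrfit_parse_error")
  for (col in c("nutrient", "response")) {
    if (!col %in% names(raw))
      stop_nrfit(sprintf("missing required column '%s' in %s", col, path),
                 "nrfit_parse_error")
  }
  parse_num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop_nrfit(sprintf("non-numeric value '%s' in column '%s', row %d",
                         raw[[col]][bad[1]], col, bad[1]),
                 "nrfit_parse_error")
    if (anyNA(v))
      stop_nrfit(sprintf("missing value in column '%s', row %d",
                         col, which(is.na(v))[1]), "nrfit_parse_error")
    v
  }
  nutrient <- parse_num("nutrient")
  response <- parse_num("response")
  if (any(nutrient < 0))
    stop_nrfit(sprintf("negative nutrient value in row %d",
                       which(nutrient < 0)[1]), "nrfit_invalid_input")
  grp <- if (group_column %in% names(raw)) raw[[group_column]] else NULL
  nr_data(nutrient, response, group = grp)
}

#' Write a dataset in the CSV dialect the reader consumes
#'
#' @param data an [nr_data] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nr_csv <- function(data, path) {
  stopifnot(inherits(data, "nr_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
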