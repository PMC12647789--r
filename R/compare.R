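#' One-way ANOVA on a list of group vectors
#'
#' Classical fixed-effects decomposition: between-group and within-group
#' sums of squares, `F = MSB / MSW`, p-value from the F distribution.
#' Intended for bootstrap distributions of a parameter or metric across
#' groups; each bootstrap replicate is treated as an observation, so
#' this is a bootstrap-distribution comparison, not experimental-unit
#' inference.
#'
#' @param groups named list of >= 2 numeric vectors, each with >= 2
#'   values (`NA`s dropped).
#' @return list with `F`, `p`, `df` (between, within), `ms_within`,
#'   `means`, `ns`.
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (length(groups) < 2L || any(vapply(groups, length, 1L) < 2L))
    stop_nrfit("need >= 2 groups with >= 2 values each", "nrfit_invalid_input")
  ns <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  grand <- sum(ns * means) / sum(ns)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1))
  df1 <- length(groups) - 1L
  df2 <- sum(ns) - length(groups)
  msw <- ssw / df2
  f <- if (msw == 0) { if (ssb == 0) 0 else Inf } else (ssb / df1) / msw
  p <- pf(f, df1, df2, lower.tail = FALSE)
  list(F = f, p = p, df = c(between = df1, within = df2),
       ms_within = msw, means = means, ns = ns)
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise mean differences with studentized-range adjusted
#' p-values; unequal group sizes use the Tukey-Kramer standard error
#' `sqrt(MSW/2 * (1/ni + 1/nj))` (failed bootstrap iterations can
#' unbalance groups).
#'
#' @param groups named list of numeric vectors (as [one_way_anova()]).
#' @param alpha significance level (default 0.05).
#' @return data frame with one row per pair: `group1`, `group2`, `diff`
#'   (mean2 - mean1), `p_adj`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  an <- one_way_anova(groups)
  k <- length(groups)
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2L)
  rows <- apply(pairs, 2L, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- an$means[j] - an$means[i]
    se <- sqrt(an$ms_within / 2 * (1 / an$ns[i] + 1 / an$ns[j]))
    q <- if (se == 0) { if (d == 0) 0 else Inf } else abs(d) / se
    p <- ptukey(q, nmeans = k, df = an$df[["within"]], lower.tail = FALSE)
    data.frame(group1 = nms[i], group2 = nms[j], diff = d,
               p_adj = p, significant = p < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compact letter display from a pairwise comparison table
#'
#' Insert-and-absorb assignment: groups that are *not* significantly
#' different share at least one letter; significant pairs never do. The
#' letter set is minimal for the standard algorithm and deterministic
#' given the group order.
#'
#' @param pairwise data frame with columns `group1`, `group2`,
#'   `significant` covering every unordered pair once.
#' @param group_order character vector fixing group (and letter) order.
#' @return named character vector of letter strings, one per group.
#' @export
compact_letters <- function(pairwise, group_order) {
  need <- c("group1", "group2", "significant")
  if (!all(need %in% names(pairwise)))
    stop_nrfit("pairwise table must have group1, group2, significant",
               "nrfit_invalid_input")
  k <- length(group_order)
  sig <- matrix(FALSE, k, k, dimnames = list(group_order, group_order))
  for (r in seq_len(nrow(pairwise))) {
    g1 <- as.character(pairwise$group1[r]); g2 <- as.character(pairwise$group2[r])
    if (!g1 %in% group_order || !g2 %in% group_order)
      stop_nrfit("pairwise table names a group absent from group_order",
                 "nrfit_invalid_input")
    if (g1 == g2 || (sig[g1, g2] != sig[g2, g1] && !is.na(sig[g1, g2])))
      stop_nrfit("inconsistent pairwise input", "nrfit_invalid_input")
    sig[g1, g2] <- sig[g2, g1] <- isTRUE(pairwise$significant[r])
  }
  if (nrow(pairwise) < choose(k, 2))
    stop_nrfit("pairwise table must cover all pairs", "nrfit_invalid_input")

  # columns are letters: logical membership vectors over groups
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    if (!sig[i, j]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        c1 <- col; c1[i] <- FALSE
        c2 <- col; c2[j] <- FALSE
        cols[[ci]] <- c1
        cols[[length(cols) + 1L]] <- c2
      }
    }
    # absorb: drop columns whose membership is a subset of another's
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] &&
          all(cols[[a]] <= cols[[b]]) && any(cols[[a]] < cols[[b]]))
        keep[a] <- FALSE
      if (a != b && keep[a] && keep[b] && identical(cols[[a]], cols[[b]]) && a > b)
        keep[a] <- FALSE
    }
    cols <- cols[keep]
  }
  # letters follow group order: the column whose first member comes first
  # gets "a", and so on
  cols <- cols[order(vapply(cols, function(col) min(which(col)), 1L))]
  letters_out <- vapply(seq_len(k), function(g) {
    mem <- vapply(cols, function(col) col[g], TRUE)
    paste(letters[which(mem)], collapse = "")
  }, character(1))
  names(letters_out) <- group_order
  letters_out
}

#' Compare bootstrap distributions across groups
#'
#' For each parameter/metric shared by the supplied ensembles (or raw
#' distribution matrices): one-way ANOVA on the bootstrap distributions,
#' Tukey HSD pairwise table, and compact letters. Group skewness is
#' reported as a normality diagnostic but nothing is gated on it.
#'
#' @param ensembles named list of `nr_boot` objects (or of matrices with
#'   identical column names), one per group.
#' @param alpha significance level.
#' @return an object of class `nr_comparison`: per-quantity list with
#'   `anova`, `tukey`, `letters`, `skewness`, plus `alpha`.
#' @export
compare_groups <- function(ensembles, alpha = 0.05) {
  mats <- lapply(ensembles, function(e)
    if (inherits(e, "nr_boot")) e$distributions else as.matrix(e))
  quantities <- Reduce(intersect, lapply(mats, colnames))
  if (length(quantities) == 0L)
    stop_nrfit("no shared quantities across groups", "nrfit_invalid_input")
  group_order <- names(ensembles)
  if (is.null(group_order)) group_order <- paste0("g", seq_along(ensembles))

  skew <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3L || sd(v) == 0) return(NA_real_)
    mean(((v - mean(v)) / sd(v))^3)
  }
  per_q <- lapply(quantities, function(q) {
    groups <- lapply(mats, function(m) m[, q])
    names(groups) <- group_order
    usable <- vapply(groups, function(v) sum(!is.na(v)) >= 2L, TRUE)
    if (!all(usable) || length(groups) < 2L)
      return(list(anova = NULL, tukey = NULL, letters = NULL,
                  skewness = vapply(groups, skew, 1)))
    tuk <- tukey_hsd(groups, alpha = alpha)
    list(anova = one_way_anova(groups), tukey = tuk,
         letters = compact_letters(tuk, group_order),
         skewness = vapply(groups, skew, 1))
  })
  names(per_q) <- quantities
  structure(list(results = per_q, alpha = alpha, groups = group_order),
            class = "nr_comparison")
}

#' @export
print.nr_comparison <- function(x, ...) {
  cat(sprintf("<nr_comparison> %d quantities, groups: %s (alpha = %g)\n",
              length(x$results), paste(x$groups, collapse = ", "), x$alpha))
  for (q in names(x$results)) {
    r <- x$results[[q]]
    if (is.null(r$anova)) next
    cat(sprintf("  %-14s F = %8.3f  p = %.3g  letters: %s\n", q,
                r$anova$F, r$anova$p,
                paste(sprintf("%s:%s", names(r$letters), r$letters),
                      collapse = " ")))
  }
  invisible(x)
}

#' Tabulate a group comparison for serialization
#'
#' @param comparison an `nr_comparison` object.
#' @return data frame with one row per quantity/pair.
#' @export
comparison_table <- function(comparison) {
  stopifnot(inherits(comparison, "nr_comparison"))
  rows <- list()
  for (q in names(comparison$results)) {
    r <- comparison$results[[q]]
    if (is.null(r$tukey)) next
    tab <- r$tukey
    tab$quantity <- q
    tab$F <- r$anova$F
    tab$p_anova <- r$anova$p
    tab$letters1 <- unname(r$letters[as.character(tab$group1)])
    tab$letters2 <- unname(r$letters[as.character(tab$group2)])
    rows[[q]] <- tab
  }
  if (length(rows) == 0L) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("quantity", "group1", "group2", "diff", "p_adj", "significant",
          "F", "p_anova", "letters1", "letters2")]
}
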