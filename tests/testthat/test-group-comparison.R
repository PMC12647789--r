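test_that("one-way ANOVA matches hand computation and limiting cases", {
  an <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(an$F, 1.5)                      # SSB = 1.5, SSW = 4, df = (1, 4)
  expect_equal(unname(an$df), c(1, 4))

  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  set.seed(601)
  g1 <- rnorm(100); g2 <- rnorm(100) + 100     # 100 within-sd units apart
  expect_lt(one_way_anova(list(g1, g2))$p, 1e-10)

  # two-group ANOVA is the squared pooled t test
  set.seed(602)
  a <- rnorm(15); b <- rnorm(12, 0.5)
  t2 <- stats::t.test(a, b, var.equal = TRUE)$statistic^2
  expect_equal(one_way_anova(list(a, b))$F, unname(t2), tolerance = 1e-9)

  expect_error(one_way_anova(list(1, c(1, 2))), class = "nrfit_invalid_input")
})

test_that("Tukey HSD agrees with the stats reference implementation", {
  set.seed(611)
  groups <- list(a = rnorm(8, 0), b = rnorm(12, 0.8), c = rnorm(10, 2))
  tk <- tukey_hsd(groups)
  ref <- stats::TukeyHSD(stats::aov(y ~ g, data.frame(
    y = unlist(groups),
    g = factor(rep(names(groups), lengths(groups))))))$g
  # reference rows are named "b-a", "c-a", "c-b"
  key <- paste(tk$group2, tk$group1, sep = "-")
  expect_equal(tk$p_adj, unname(ref[key, "p adj"]), tolerance = 1e-6)
  expect_equal(tk$diff, unname(ref[key, "diff"]), tolerance = 1e-9)
})

test_that("Tukey HSD flags exactly the separated group", {
  set.seed(612)
  base <- rnorm(30)
  groups <- list(g1 = base, g2 = base + rnorm(30, 0, 1e-3), g3 = base + 50)
  tk <- tukey_hsd(groups)
  sig <- tk[tk$significant, ]
  expect_equal(nrow(sig), 2)
  expect_true(all(sig$group1 == "g3" | sig$group2 == "g3"))

  ident <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_false(any(ident$significant))
})

test_that("compact letters encode the significance partition", {
  pw <- function(g1, g2, sig) data.frame(group1 = g1, group2 = g2,
                                         significant = sig)
  none <- pw(c("A", "A", "B"), c("B", "C", "C"), c(FALSE, FALSE, FALSE))
  expect_equal(unname(compact_letters(none, c("A", "B", "C"))),
               c("a", "a", "a"))

  all_sig <- pw(c("A", "A", "B"), c("B", "C", "C"), c(TRUE, TRUE, TRUE))
  expect_equal(unname(compact_letters(all_sig, c("A", "B", "C"))),
               c("a", "b", "c"))

  chain <- pw(c("A", "A", "B"), c("B", "C", "C"), c(FALSE, TRUE, FALSE))
  expect_equal(compact_letters(chain, c("A", "B", "C")),
               c(A = "a", B = "ab", C = "b"))

  expect_error(compact_letters(pw("A", "B", TRUE), c("A", "B", "C")),
               class = "nrfit_invalid_input")  # incomplete table
})

test_that("letters are consistent with the pairwise tests on random patterns", {
  set.seed(621)
  for (trial in 1:25) {
    k <- sample(3:6, 1)
    nms <- LETTERS[1:k]
    pairs <- t(utils::combn(nms, 2))
    # random significance patterns need not be transitive; the CLD
    # invariant must hold regardless
    sig <- runif(nrow(pairs)) < 0.4
    pw <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                     significant = sig)
    lt <- compact_letters(pw, nms)
    expect_true(all(nchar(lt) >= 1))
    for (r in seq_len(nrow(pw))) {
      s1 <- strsplit(lt[[pw$group1[r]]], "")[[1]]
      s2 <- strsplit(lt[[pw$group2[r]]], "")[[1]]
      if (pw$significant[r]) expect_length(intersect(s1, s2), 0)
      else expect_gt(length(intersect(s1, s2)), 0)
    }
    # permuting the group order relabels but preserves the partition
    perm <- sample(nms)
    lt_perm <- compact_letters(pw, perm)
    shared <- function(lets, g1, g2)
      length(intersect(strsplit(lets[[g1]], "")[[1]],
                       strsplit(lets[[g2]], "")[[1]])) > 0
    for (r in seq_len(nrow(pw)))
      expect_equal(shared(lt_perm, pw$group1[r], pw$group2[r]),
                   shared(lt, pw$group1[r], pw$group2[r]))
  }
})

test_that("compare_groups assembles ANOVA, Tukey and letters per quantity", {
  set.seed(631)
  mk <- function(shift) {
    m <- cbind(A = rnorm(60, 100 + shift, 3), B = rnorm(60, 150, 3))
    m
  }
  cmp <- compare_groups(list(low = mk(0), mid = mk(1), high = mk(30)))
  expect_setequal(names(cmp$results), c("A", "B"))
  rA <- cmp$results$A
  expect_lt(rA$anova$p, 0.001)
  expect_equal(sum(rA$tukey$significant), 2)     # only pairs involving 'high'
  expect_length(intersect(strsplit(rA$letters[["low"]], "")[[1]],
                          strsplit(rA$letters[["mid"]], "")[[1]]) , 1)
  expect_true(is.finite(rA$skewness[["low"]]))
  tab <- comparison_table(cmp)
  expect_equal(nrow(tab), 2 * 3)                 # 2 quantities x 3 pairs
})
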