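# Descriptive summaries, Welch's t, the ANOVA variants and Dunnett T3.

test_that("group summaries reproduce the box-plot five-number summary", {
  s <- summarize_group(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3); expect_equal(s$min, 1); expect_equal(s$max, 5)
  one <- summarize_group(7)
  expect_equal(c(one$min, one$q1, one$median, one$q3, one$max), rep(7, 5))
  q <- summarize_group(c(1, 2, 3, 4))
  expect_equal(q$q1, 1.75)
  expect_equal(q$q3, 3.25)
  expect_error(summarize_group(numeric(0)), "empty")
})

test_that("Welch's t matches the closed-form hand computation", {
  ht <- welch_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(ht$statistic, -1 / sqrt(5 / 6), tolerance = 1e-10)
  expect_equal(ht$df, 6)
  expect_equal(ht$p_value, 2 * stats::pt(-1 / sqrt(5 / 6), 6),
               tolerance = 1e-10)
  expect_equal(ht$label, "ns")
})

test_that("identical groups give t = 0 and p = 1", {
  ht <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ht$statistic, 0)
  expect_equal(ht$p_value, 1)
  deg <- welch_t(c(2, 2, 2), c(2, 2))
  expect_equal(deg$p_value, 1)
  expect_error(welch_t(c(2, 2), c(3, 3)), "unequal means")
})

test_that("welch_t is symmetric up to the sign of t", {
  a <- c(1.2, 3.4, 2.2, 5.0); b <- c(2.0, 2.5, 4.1)
  f <- welch_t(a, b); r <- welch_t(b, a)
  expect_equal(f$statistic, -r$statistic)
  expect_equal(f$p_value, r$p_value)
})

test_that("significance labels follow the threshold scheme exactly", {
  expect_equal(significance_label(c(0.2, 0.05, 0.05 + 1e-9, 0.01, 0.001,
                                    1e-4, 1e-5)),
               c("ns", "*", "ns", "**", "***", "****", "****"))
  expect_error(significance_label(1.2), "\\[0, 1\\]")
})

test_that("identical groups give omnibus p = 1 and all-ns pairwise", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- welch_anova_dunnett_t3(g)
  expect_equal(res$welch$p_value, 1)
  expect_equal(res$brown_forsythe$p_value, 1)
  expect_true(all(res$pairwise$label == "ns"))
})

test_that("Dunnett T3 adjusted p never undercuts the raw Welch p", {
  set.seed(10)
  for (r in 1:20) {
    g <- list(a = rnorm(6), b = rnorm(6, 0.8), c = rnorm(6, 0, 3))
    pw <- dunnett_t3(g)
    expect_true(all(pw$p_value >= pw$p_raw - 1e-12))
  }
})

test_that("the permutation evaluation tracks its family-scaled raw p", {
  set.seed(3)
  g <- list(a = rnorm(10), b = rnorm(10, 1.5), c = rnorm(10, 0, 2))
  smm <- dunnett_t3(g, method = "smm")
  perm <- dunnett_t3(g, method = "permutation", n_perm = 4000, seed = 5)
  # the permutation route scales each raw p by the family size
  expect_lt(max(abs(perm$p_value - pmin(1, 3 * smm$p_raw))), 0.1)
  # both routes agree on which pairs are clearly significant
  expect_identical(perm$p_value < 0.05, smm$p_value < 0.05)
})

test_that("Brown-Forsythe statistic matches a direct computation", {
  g <- list(x = c(1, 3, 5, 7), y = c(2, 2.5, 3), z = c(10, 11, 12, 13, 14))
  n <- lengths(g); N <- sum(n)
  m <- sapply(g, mean); v <- sapply(g, var)
  Fstar <- sum(n * (m - sum(n * m) / N)^2) / sum((1 - n / N) * v)
  res <- brown_forsythe_anova(g)
  expect_equal(res$statistic, Fstar)
  expect_true(res$p_value < 0.01)
})

test_that("groups of fewer than two observations are rejected", {
  expect_error(welch_anova(list(1, c(2, 3))), "at least 2")
  expect_error(welch_t(1, c(2, 3)), "at least 2")
  expect_error(welch_anova_dunnett_t3(list(c(1, 2), c(3, 4))), "3 groups")
})
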