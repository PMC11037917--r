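# Statistical summaries and tests used to report quantification results:
# box-plot descriptives, Welch's t test, Brown-Forsythe and Welch's ANOVA,
# and Dunnett's T3 multiple comparisons, with the conventional significance
# labels (ns, *, **, ***, ****).

#' Significance label for a p value
#'
#' Thresholds: `p > 0.05` ns, `p <= 0.05` *, `<= 0.01` **, `<= 0.001` ***,
#' `<= 0.0001` ****.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
significance_label <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_param("p values must lie in [0, 1]")
  ifelse(p <= 1e-4, "****",
         ifelse(p <= 1e-3, "***",
                ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*", "ns"))))
}

#' Descriptive summary of one group
#'
#' The five-number summary shown by box-and-whisker plots: median (central
#' line), quartiles (box edges, linear interpolation) and minimum/maximum
#' (whiskers), plus n, mean and SD.
#'
#' @param values numeric vector (length >= 1, finite).
#' @return An object of class `group_summary`.
#' @export
summarize_group <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop_param("empty input")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  structure(list(n = length(values), mean = mean(values),
                 sd = if (length(values) > 1) stats::sd(values) else 0,
                 median = q[2], q1 = q[1], q3 = q[3],
                 min = min(values), max = max(values)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf(
    "n=%d mean=%.4g sd=%.4g | min=%.4g q1=%.4g median=%.4g q3=%.4g max=%.4g\n",
    x$n, x$mean, x$sd, x$min, x$q1, x$median, x$q3, x$max))
  invisible(x)
}

new_test_result <- function(statistic, df, p, method, extra = list()) {
  structure(c(list(statistic = statistic, df = df, p_value = p,
                   label = significance_label(p), method = method), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  df <- if (length(x$df) == 2)
    sprintf("df1=%.4g, df2=%.4g", x$df[1], x$df[2])
  else sprintf("df=%.4g", x$df)
  cat(sprintf("%s: statistic=%.4g, %s, p=%.4g (%s)\n",
              x$method, x$statistic, df, x$p_value, x$label))
  invisible(x)
}

#' Welch's two-sample t test
#'
#' Unequal-variance t test with Satterthwaite degrees of freedom and a
#' two-sided p value. When both groups have zero variance, equal means give
#' `p = 1` by convention and unequal means are an error (the statistic is
#' undefined).
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return A `test_result` with `statistic`, fractional `df`, `p_value` and
#'   significance `label`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop_param("each group needs at least 2 observations")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(new_test_result(0, Inf, 1, "Welch's t test"))
    stop_param("zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  new_test_result(unname(ht$statistic), unname(ht$parameter),
                  ht$p.value, "Welch's t test",
                  list(mean_diff = mean(a) - mean(b)))
}

#' Welch's one-way ANOVA
#'
#' Welch's heteroscedastic F test across k groups (as computed by
#' [stats::oneway.test()] with `var.equal = FALSE`).
#'
#' @param groups list of numeric vectors (k >= 2, each n >= 2).
#' @return A `test_result` with `df = c(df1, df2)`.
#' @export
welch_anova <- function(groups) {
  check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (all(vapply(groups, stats::var, 0) == 0) &&
      length(unique(vapply(groups, mean, 0))) == 1)
    return(new_test_result(0, c(length(groups) - 1, Inf), 1,
                           "Welch's ANOVA"))
  ht <- stats::oneway.test(x ~ g, var.equal = FALSE)
  new_test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
                  "Welch's ANOVA")
}

#' Brown-Forsythe one-way ANOVA
#'
#' The Brown-Forsythe adjusted F statistic
#' `F* = sum n_i (xbar_i - xbar)^2 / sum (1 - n_i/N) s_i^2`, referred to an
#' F distribution with `k - 1` and Satterthwaite-approximated denominator
#' degrees of freedom.
#'
#' @param groups list of numeric vectors (k >= 2, each n >= 2).
#' @return A `test_result` with `df = c(df1, df2)`.
#' @export
brown_forsythe_anova <- function(groups) {
  check_groups(groups)
  n <- lengths(groups); N <- sum(n); k <- length(groups)
  m <- vapply(groups, mean, 0); v <- vapply(groups, stats::var, 0)
  grand <- sum(n * m) / N
  denom <- sum((1 - n / N) * v)
  if (denom == 0) {
    if (length(unique(m)) == 1)
      return(new_test_result(0, c(k - 1, Inf), 1, "Brown-Forsythe ANOVA"))
    stop_param("zero within-group variance with unequal means")
  }
  Fstar <- sum(n * (m - grand)^2) / denom
  c_i <- (1 - n / N) * v / denom
  df2 <- 1 / sum(c_i^2 / (n - 1))
  p <- stats::pf(Fstar, k - 1, df2, lower.tail = FALSE)
  new_test_result(Fstar, c(k - 1, df2), p, "Brown-Forsythe ANOVA")
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop_param("'groups' must be a list of at least 2 samples")
  if (any(lengths(groups) < 2))
    stop_param("every group needs at least 2 observations")
  invisible(TRUE)
}

# Studentized maximum modulus tail: distribution of max(|T_1|, ..., |T_m|)
# for independent t variates; used as the reference for Dunnett T3.
smm_p <- function(q, m, df) {
  1 - (2 * stats::pt(q, df) - 1)^m
}

#' Dunnett's T3 all-pairs comparisons
#'
#' Pairwise Welch-type t statistics with Satterthwaite degrees of freedom,
#' referred to the studentized maximum modulus distribution with `m =
#' k(k-1)/2` comparisons (evaluated through the independence form
#' `1 - (2 pt(|t|, df) - 1)^m`). A seeded permutation approximation is
#' available as a cross-check.
#'
#' @param groups named list of numeric vectors.
#' @param method `"smm"` (default) or `"permutation"`.
#' @param n_perm permutations per pair for `method = "permutation"`.
#' @param seed seed for the permutation method.
#' @return Data frame with one row per pair: group labels, `statistic`,
#'   `df`, raw Welch `p_raw`, adjusted `p_value` and `label`.
#' @export
dunnett_t3 <- function(groups, method = c("smm", "permutation"),
                       n_perm = 2000, seed = 1) {
  method <- match.arg(method)
  check_groups(groups)
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- vector("list", m)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    a <- groups[[i1]]; b <- groups[[i2]]
    se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
    if (se2 == 0) {
      tstat <- 0; df <- Inf
      p_raw <- if (mean(a) == mean(b)) 1 else 0
    } else {
      tstat <- (mean(a) - mean(b)) / sqrt(se2)
      df <- se2^2 / ((stats::var(a) / length(a))^2 / (length(a) - 1) +
                       (stats::var(b) / length(b))^2 / (length(b) - 1))
      p_raw <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    }
    p_adj <- if (method == "smm") {
      min(smm_p(abs(tstat), m, df), 1)
    } else {
      perm_pair_p(a, b, n_perm, derive_seed(seed, j), m)
    }
    p_adj <- max(p_adj, p_raw)    # adjusted p can never undercut the raw p
    out[[j]] <- data.frame(group1 = names(groups)[i1],
                           group2 = names(groups)[i2],
                           statistic = tstat, df = df, p_raw = p_raw,
                           p_value = p_adj,
                           label = significance_label(p_adj),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "method") <- method
  res
}

# Permutation reference for one pair, Bonferroni-style scaled to the family
# size, capped at 1.
perm_pair_p <- function(a, b, n_perm, seed, m) {
  obs <- abs(welch_stat(a, b))
  x <- c(a, b); na <- length(a)
  cnt <- with_seed(seed, {
    s <- 0L
    for (r in seq_len(n_perm)) {
      idx <- sample.int(length(x), na)
      if (abs(welch_stat(x[idx], x[-idx])) >= obs) s <- s + 1L
    }
    s
  })
  min(1, m * (cnt + 1) / (n_perm + 1))
}

welch_stat <- function(a, b) {
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  if (se2 == 0) return(0)
  (mean(a) - mean(b)) / sqrt(se2)
}

#' Omnibus ANOVA plus Dunnett T3 comparisons
#'
#' The combined testing scheme for three or more groups: both the
#' Brown-Forsythe and Welch omnibus variants are computed, followed by
#' all-pairs Dunnett T3 comparisons with family-wise labels.
#'
#' @param groups named list of numeric vectors (k >= 3, each n >= 2).
#' @param t3_method passed to [dunnett_t3()].
#' @return A list with `welch` and `brown_forsythe` omnibus `test_result`s
#'   and the `pairwise` data frame.
#' @export
welch_anova_dunnett_t3 <- function(groups, t3_method = "smm") {
  if (length(groups) < 3) stop_param("need at least 3 groups")
  list(welch = welch_anova(groups),
       brown_forsythe = brown_forsythe_anova(groups),
       pairwise = dunnett_t3(groups, method = t3_method))
}
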