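#' Run the statistics module on a tidy CSV
#'
#' Reads a tidy table (one row per observation, columns `value` and
#' `group`), writes per-group summaries and, depending on the number of
#' groups, either Welch's t test (2 groups) or the Brown-Forsythe/Welch
#' ANOVA plus Dunnett T3 pairwise table (3 or more).
#'
#' @param config list or YAML/JSON path with fields `input` (CSV path),
#'   `out_dir`, optional `value_col` and `group_col`.
#' @return Named vector of output paths, invisibly.
#' @export
run_stats <- function(config) {
  cfg <- load_config(config)
  out <- ensure_outdir(cfg$out_dir)
  df <- utils::read.csv(cfg$input, stringsAsFactors = FALSE)
  vc <- cfg$value_col %||% "value"; gc <- cfg$group_col %||% "group"
  if (!all(c(vc, gc) %in% names(df)))
    stop_param("input must have columns '", vc, "' and '", gc, "'")
  groups <- split(df[[vc]], df[[gc]])
  sums <- do.call(rbind, lapply(names(groups), function(g) {
    s <- summarize_group(groups[[g]])
    data.frame(group = g, n = s$n, mean = s$mean, sd = s$sd, min = s$min,
               q1 = s$q1, median = s$median, q3 = s$q3, max = s$max,
               stringsAsFactors = FALSE)
  }))
  write_csv_stable(sums, file.path(out, "group_summaries.csv"))
  paths <- c(summaries = file.path(out, "group_summaries.csv"))
  if (length(groups) == 2) {
    ht <- welch_t(groups[[1]], groups[[2]])
    tests <- data.frame(test = "welch_t", statistic = ht$statistic,
                        df1 = ht$df, df2 = NA, p_value = ht$p_value,
                        label = ht$label, stringsAsFactors = FALSE)
    write_csv_stable(tests, file.path(out, "tests.csv"))
    paths <- c(paths, tests = file.path(out, "tests.csv"))
  } else if (length(groups) >= 3) {
    res <- welch_anova_dunnett_t3(groups)
    omni <- data.frame(
      test = c("welch_anova", "brown_forsythe_anova"),
      statistic = c(res$welch$statistic, res$brown_forsythe$statistic),
      df1 = c(res$welch$df[1], res$brown_forsythe$df[1]),
      df2 = c(res$welch$df[2], res$brown_forsythe$df[2]),
      p_value = c(res$welch$p_value, res$brown_forsythe$p_value),
      label = c(res$welch$label, res$brown_forsythe$label),
      stringsAsFactors = FALSE)
    write_csv_stable(omni, file.path(out, "tests.csv"))
    write_csv_stable(res$pairwise, file.path(out, "pairwise_t3.csv"))
    paths <- c(paths, tests = file.path(out, "tests.csv"),
               pairwise = file.path(out, "pairwise_t3.csv"))
  }
  invisible(paths)
}
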