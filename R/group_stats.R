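# Group summaries and nonparametric comparisons, in the reporting style of
# the study: median\25-75% and Wilcoxon tests.

#' Summarize a sample the way the figures report it
#'
#' Median, quartiles (linear-interpolation percentiles), box-plot whiskers at
#' Q1 - 1.5 IQR and Q3 + 1.5 IQR, mean and SEM.
#'
#' @param values numeric vector (NAs dropped).
#' @return list of class `group_summary` with `n`, `median`, `q1`, `q3`,
#'   `whisker_lo`, `whisker_hi`, `mean`, `sem`.
#' @export
summarize_group <- function(values) {
  values <- values[is.finite(values)]
  stop_if(length(values) == 0, "empty input")
  q <- pctl(values, c(0.25, 0.5, 0.75))
  iqr <- q[3] - q[1]
  structure(list(n = length(values), median = q[2], q1 = q[1], q3 = q[3],
                 whisker_lo = q[1] - 1.5 * iqr, whisker_hi = q[3] + 1.5 * iqr,
                 mean = mean(values),
                 sem = stats::sd(values) / sqrt(length(values))),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(format_summary(x), "\n")
  invisible(x)
}

#' Format a summary as "median\\Q1-Q3"
#' @param s a [summarize_group()] result
#' @param digits significant digits
#' @return character scalar
#' @export
format_summary <- function(s, digits = 3) {
  sprintf("%s\\%s-%s (n=%d)",
          signif(s$median, digits), signif(s$q1, digits),
          signif(s$q3, digits), s$n)
}

#' Compare two groups with a Wilcoxon test
#'
#' Two-sided Wilcoxon rank-sum test (unpaired) or signed-rank test (paired).
#' The exact null distribution is used when both groups have at most 10
#' observations and no ties; otherwise the normal approximation with tie
#' correction.
#'
#' @param a,b numeric samples.
#' @param paired logical; paired samples must have equal length.
#' @return list with `statistic`, `p_value`, `stars` (`***` p<0.001, `**`
#'   p<0.01, `*` p<0.05, `ns` otherwise), `method`, `n`.
#' @export
compare_groups <- function(a, b, paired = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  stop_if(length(a) < 3 || length(b) < 3, "need n >= 3 per group")
  stop_if(paired && length(a) != length(b), "paired groups must match in size")
  exact <- length(a) <= 10 && length(b) <= 10
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, paired = paired, exact = exact, correct = TRUE))
  p <- wt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
  list(statistic = unname(wt$statistic), p_value = p, stars = stars,
       method = wt$method, n = c(length(a), length(b)))
}

#' Tabulate group summaries and pairwise tests
#'
#' Builds a report table in the "median\\Q1-Q3, p" style for a value split by
#' a grouping factor, testing each group against the first.
#'
#' @param values numeric vector.
#' @param group grouping vector (coerced to factor).
#' @return data.frame: `group`, `n`, `median`, `q1`, `q3`, `p_vs_first`,
#'   `stars`.
#' @export
report_groups <- function(values, group) {
  g <- factor(group)
  stop_if(nlevels(g) < 1, "no groups")
  sp <- split(values, g)
  ref <- sp[[1]]
  rows <- lapply(seq_along(sp), function(i) {
    s <- summarize_group(sp[[i]])
    if (i == 1 || s$n < 3 || sum(is.finite(ref)) < 3) {
      p <- NA_real_; st <- ""
    } else {
      cmp <- compare_groups(ref, sp[[i]])
      p <- cmp$p_value; st <- cmp$stars
    }
    data.frame(group = names(sp)[i], n = s$n, median = s$median,
               q1 = s$q1, q3 = s$q3, p_vs_first = p, stars = st,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
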