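#' Two-group summary statistics
#'
#' @param n1,n2 group sizes (>= 2).
#' @param mean1,mean2 group means.
#' @param sd1,sd2 group standard deviations (>= 0).
#' @return a list of class `group_summary`.
#' @export
group_summary <- function(n1, n2, mean1, mean2, sd1, sd2) {
  stop_if_not(n1 >= 2 && n2 >= 2, "group sizes must be >= 2")
  stop_if_not(sd1 >= 0 && sd2 >= 0, "standard deviations must be >= 0")
  structure(list(n1 = n1, n2 = n2, mean1 = mean1, mean2 = mean2,
                 sd1 = sd1, sd2 = sd2), class = "group_summary")
}

pooled_var <- function(s) {
  ((s$n1 - 1) * s$sd1^2 + (s$n2 - 1) * s$sd2^2) / (s$n1 + s$n2 - 2)
}

#' Pooled-variance two-sample t statistic from summaries
#'
#' Classic pooled t computed from group sizes, means and SDs alone; the
#' sign follows `mean1 - mean2`.
#'
#' @param summary a [group_summary()].
#' @return list with `t` and `df` (= n1 + n2 - 2).
#' @export
pooled_t <- function(summary) {
  sp2 <- pooled_var(summary)
  stop_if_not(sp2 > 0, "zero pooled variance")
  t <- (summary$mean1 - summary$mean2) /
    sqrt(sp2 * (1 / summary$n1 + 1 / summary$n2))
  list(t = t, df = summary$n1 + summary$n2 - 2)
}

#' Cohen's d from summaries
#'
#' Mean difference divided by the pooled standard deviation; the sign
#' follows `mean1 - mean2`.
#'
#' @param summary a [group_summary()].
#' @return the standardized mean difference.
#' @export
cohens_d <- function(summary) {
  sp <- sqrt(pooled_var(summary))
  stop_if_not(sp > 0, "zero pooled SD")
  (summary$mean1 - summary$mean2) / sp
}

#' Reconstruct a count from a printed percentage
#'
#' Round-half-up of `percent * n / 100`.
#'
#' @param percent value in \[0, 100\].
#' @param n group size.
#' @return integer count.
#' @export
percent_to_counts <- function(percent, n) {
  stop_if_not(all(percent >= 0 & percent <= 100),
              "percent must lie in [0, 100]")
  as.integer(round_half_up(percent * n / 100))
}

#' Reconstruct a full category column from printed percentages
#'
#' Round-half-up per category; printed percentages are themselves rounded,
#' so the rounded counts can miss the known group total — the residual is
#' assigned to the last (smallest) category so the column sums to `n`.
#'
#' @param percents percentages over categories of one group.
#' @param n the group total the counts must sum to.
#' @return integer counts summing to `n`.
#' @export
percents_to_counts <- function(percents, n) {
  counts <- percent_to_counts(percents, n)
  counts[length(counts)] <- counts[length(counts)] + (n - sum(counts))
  stop_if_not(all(counts >= 0), "percentages inconsistent with group total")
  counts
}

check_table <- function(counts, min_dim) {
  stop_if_not(is.matrix(counts) && all(counts >= 0),
              "counts must be a non-negative matrix")
  stop_if_not(nrow(counts) >= min_dim[1] && ncol(counts) >= min_dim[2],
              "table too small")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in contingency table", call. = FALSE)
}

#' Continuity-corrected chi-square for a 2x2 table
#'
#' Yates-corrected statistic `N (|ad - bc| - N/2)^2 / (r1 r2 c1 c2)`, with
#' the correction floored so perfectly proportional tables give 0.
#'
#' @param counts 2x2 matrix of non-negative counts.
#' @return the corrected statistic (df = 1).
#' @export
chi2_yates <- function(counts) {
  check_table(counts, c(2, 2))
  stop_if_not(nrow(counts) == 2 && ncol(counts) == 2,
              "Yates correction applies to 2x2 tables")
  unname(suppressWarnings(
    stats::chisq.test(counts, correct = TRUE)$statistic))
}

#' Pearson chi-square for an R x C table
#'
#' `sum (obs - exp)^2 / exp` with expected counts from the margins;
#' df = (R - 1)(C - 1).
#'
#' @param counts R x C matrix of non-negative counts.
#' @return list with `statistic` and `df`.
#' @export
chi2_pearson <- function(counts) {
  check_table(counts, c(2, 2))
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter))
}

#' Cohort comparison report from a summary CSV
#'
#' Reads a small CSV of printed group summaries and percentage rows and
#' recomputes the comparison statistic for each: pooled t (with Cohen's d)
#' for mean rows, Yates-corrected chi-square for two-category percentage
#' rows, plain Pearson chi-square for multi-category rows. Percentage rows
#' give the per-group category percentages as `;`-separated values in
#' `percents1` / `percents2`.
#'
#' Expected columns: `measure`, `type` (`t` or `chi2`), `n1`, `n2`, and
#' for `t` rows `mean1`, `mean2`, `sd1`, `sd2`, for `chi2` rows
#' `percents1`, `percents2`.
#'
#' @param path CSV path.
#' @return a `data.frame`: measure, type, statistic, df, cohens_d.
#' @export
cohort_stats_report <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(measure = tab$measure, type = tab$type,
                    statistic = NA_real_, df = NA_real_,
                    cohens_d = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    if (tab$type[i] == "t") {
      s <- group_summary(tab$n1[i], tab$n2[i], tab$mean1[i], tab$mean2[i],
                         tab$sd1[i], tab$sd2[i])
      pt <- pooled_t(s)
      out$statistic[i] <- pt$t; out$df[i] <- pt$df
      out$cohens_d[i] <- cohens_d(s)
    } else {
      p1 <- as.numeric(strsplit(tab$percents1[i], ";")[[1]])
      p2 <- as.numeric(strsplit(tab$percents2[i], ";")[[1]])
      counts <- cbind(percents_to_counts(p1, tab$n1[i]),
                      percents_to_counts(p2, tab$n2[i]))
      if (length(p1) == 2) {
        out$statistic[i] <- chi2_yates(counts); out$df[i] <- 1
      } else {
        cp <- chi2_pearson(counts)
        out$statistic[i] <- cp$statistic; out$df[i] <- cp$df
      }
    }
  }
  out
}
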