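# Cohort-comparison statistics computable from summary data alone: one-way
# ANOVA from (n, mean, SD) triples and chi-square homogeneity from counts.
# These reproduce the demographics-table tests without access to raw data.

#' One-way ANOVA from per-group summaries
#'
#' Grand mean weighted by n; between-group sum of squares
#' SSB = sum n_i (mean_i - grand)^2; within SSW = sum (n_i - 1) sd_i^2;
#' F = (SSB/(g-1)) / (SSW/(N-g)) referred to the F distribution. Identical
#' to full-data one-way ANOVA when the summaries come from raw data.
#'
#' @param n,means,sds equal-length vectors of group sizes (>= 2), means, SDs.
#' @return list: `F`, `df1`, `df2`, `p`, `degenerate` flag (SSW = 0 with
#'   SSB > 0 gives p = 0, flagged).
#' @export
anova_from_summary <- function(n, means, sds) {
  g <- length(n)
  stopifnot(g >= 2, length(means) == g, length(sds) == g, all(n >= 2),
            all(sds >= 0))
  N <- sum(n)
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum((n - 1) * sds^2)
  if (ssw == 0) {
    if (ssb > 0)
      return(list(F = Inf, df1 = g - 1L, df2 = N - g, p = 0, degenerate = TRUE))
    return(list(F = 0, df1 = g - 1L, df2 = N - g, p = 1, degenerate = TRUE))
  }
  Fv <- (ssb / (g - 1)) / (ssw / (N - g))
  list(F = Fv, df1 = g - 1L, df2 = N - g,
       p = stats::pf(Fv, g - 1, N - g, lower.tail = FALSE), degenerate = FALSE)
}

#' Chi-square homogeneity test from event counts
#'
#' Pearson chi-square on the 2 x g table of events/non-events without
#' continuity correction; df = g - 1.
#'
#' @param n per-group totals (> 0).
#' @param k per-group event counts (0 <= k <= n).
#' @return list: `statistic`, `df`, `p`.
#' @export
chisq_homogeneity <- function(n, k) {
  g <- length(n)
  stopifnot(g >= 2, length(k) == g, all(k >= 0), all(k <= n))
  if (any(n == 0)) stop("group with n = 0")
  tab <- cbind(k, n - k)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Demographics table with cross-cohort tests
#'
#' Per variable: per-cohort summaries plus the appropriate homogeneity test
#' — quantitative variables are routed to [anova_from_summary()] and binary
#' ones to [chisq_homogeneity()]. With a single cohort, summaries are
#' reported without tests.
#'
#' @param sheets named list of per-cohort sample sheets.
#' @param quantitative character vector of numeric sheet columns to
#'   summarise (default gestational_age, maternal_age).
#' @param binary character vector of 0/1 sheet columns (default smoking,
#'   plus `sex == "male"` reported as `sex_male`).
#' @return data.frame: variable, type, one `<cohort> (n)` summary column per
#'   cohort (mean (SD) or count (%)), p.
#' @export
build_table1 <- function(sheets,
                         quantitative = c("gestational_age", "maternal_age"),
                         binary = "smoking") {
  stopifnot(length(sheets) >= 1)
  sheets <- lapply(sheets, validate_sample_sheet)
  if (is.null(names(sheets)))
    names(sheets) <- vapply(sheets, function(s) s$cohort[1L], character(1))
  ns <- vapply(sheets, nrow, integer(1))
  rows <- list()
  fmt_q <- function(m, s) sprintf("%.2f (%.2f)", m, s)
  fmt_b <- function(k, n) sprintf("%d (%.1f%%)", k, 100 * k / n)
  for (v in quantitative) {
    ms <- vapply(sheets, function(s) mean(s[[v]]), numeric(1))
    sds <- vapply(sheets, function(s) stats::sd(s[[v]]), numeric(1))
    p <- if (length(sheets) >= 2) anova_from_summary(ns, ms, sds)$p else NA_real_
    rows[[v]] <- c(variable = v, type = "quantitative",
                   stats::setNames(fmt_q(ms, sds), names(sheets)),
                   p = p)
  }
  bin_cols <- c(stats::setNames("sex", "sex_male"),
                stats::setNames(binary, binary))
  for (bi in seq_along(bin_cols)) {
    v <- bin_cols[bi]
    lab <- names(bin_cols)[bi]
    ks <- vapply(sheets, function(s)
      if (v == "sex") sum(s$sex == "male") else sum(s[[v]] == 1), integer(1))
    p <- if (length(sheets) >= 2) chisq_homogeneity(ns, ks)$p else NA_real_
    rows[[lab]] <- c(variable = lab, type = "binary",
                     stats::setNames(fmt_b(ks, ns), names(sheets)),
                     p = p)
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  out$p <- as.numeric(out$p)
  rownames(out) <- NULL
  out
}
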