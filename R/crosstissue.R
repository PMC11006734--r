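# Benjamini-Hochberg FDR subsetting and cross-tissue / cross-model
# effect-size comparison.

#' Benjamini-Hochberg step-up FDR control
#'
#' Standard step-up on the sorted p-values; rejection flags at level `q` and
#' monotone adjusted values (capped at 1). Adjusted values delegate to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values.
#' @param q FDR level (default 0.05).
#' @return list: `reject` (logical, aligned to `p`), `adjusted`,
#'   `n_rejected`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  adjusted <- stats::p.adjust(p, method = "BH")
  reject <- adjusted <= q
  list(reject = reject, adjusted = adjusted, n_rejected = sum(reject))
}

#' Correlation of effect sizes between two EWAS scans
#'
#' Pearson correlation of the beta vectors over the shared CpGs (optionally
#' restricted to a subset), with the usual t-transform p-value.
#'
#' @param stats_a,stats_b stats data.frames with `cpg` and `beta`.
#' @param subset optional character vector of CpG ids to restrict to.
#' @return data.frame of class `CorrelationResult`: n, r, p, subset_desc.
#' @export
effect_correlation <- function(stats_a, stats_b, subset = NULL) {
  shared <- intersect(stats_a$cpg, stats_b$cpg)
  desc <- "all shared CpGs"
  if (!is.null(subset)) {
    shared <- intersect(shared, subset)
    desc <- sprintf("subset of %d CpGs", length(subset))
  }
  if (length(shared) < 3) stop("need at least 3 shared CpGs")
  ba <- stats_a$beta[match(shared, stats_a$cpg)]
  bb <- stats_b$beta[match(shared, stats_b$cpg)]
  if (stats::sd(ba) == 0 || stats::sd(bb) == 0)
    stop("zero variance in an effect vector")
  ct <- stats::cor.test(ba, bb)
  structure(data.frame(n = length(shared), r = unname(ct$estimate),
                       p = ct$p.value, subset_desc = desc,
                       stringsAsFactors = FALSE),
            class = c("CorrelationResult", "data.frame"))
}

#' Compare a base and an extended model fit
#'
#' Correlation of effect estimates plus the fraction of CpGs whose effect
#' direction agrees, optionally restricted to a DMP set — the standard
#' sensitivity-analysis summary for added covariates.
#'
#' @param stats_base,stats_extended stats data.frames with `cpg`, `beta`.
#' @param subset optional CpG id restriction.
#' @return list: `correlation` (`CorrelationResult`), `direction_concordance`
#'   (fraction in \[0,1\]).
#' @export
compare_models <- function(stats_base, stats_extended, subset = NULL) {
  corr <- effect_correlation(stats_base, stats_extended, subset)
  shared <- intersect(stats_base$cpg, stats_extended$cpg)
  if (!is.null(subset)) shared <- intersect(shared, subset)
  ba <- stats_base$beta[match(shared, stats_base$cpg)]
  bb <- stats_extended$beta[match(shared, stats_extended$cpg)]
  conc <- mean(sign(ba) == sign(bb))
  list(correlation = corr, direction_concordance = conc)
}
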