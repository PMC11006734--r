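# DerSimonian-Laird random-effects meta-analysis across cohorts.
#
# Fixed-effect weights w_i = 1/se_i^2 give the Cochran Q heterogeneity
# statistic; the moment estimator tau^2 = max(0, (Q - (k-1)) /
# (sum(w) - sum(w^2)/sum(w))) feeds the random-effects weights
# w*_i = 1/(se_i^2 + tau^2). CpGs present in at least `min_cohorts` cohorts
# are pooled; epigenome-wide significance is p < 9e-8.

EPIGENOME_WIDE_P <- 9e-8

#' DerSimonian-Laird pooling of one set of study estimates
#'
#' @param effects study effect estimates.
#' @param ses study standard errors (> 0), same length.
#' @return one-row data.frame: k, beta, se, z, p, Q, tau2.
#' @export
dl_meta <- function(effects, ses) {
  keep <- is.finite(effects) & is.finite(ses)
  effects <- effects[keep]; ses <- ses[keep]
  k <- length(effects)
  if (k == 0) return(NULL)
  if (any(ses <= 0)) stop("standard errors must be positive")
  w <- 1 / ses^2
  b_fe <- sum(w * effects) / sum(w)
  Q <- sum(w * (effects - b_fe)^2)
  tau2 <- if (k > 1) max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  ws <- 1 / (ses^2 + tau2)
  beta <- sum(ws * effects) / sum(ws)
  se <- sqrt(1 / sum(ws))
  z <- beta / se
  data.frame(k = k, beta = beta, se = se, z = z,
             p = 2 * stats::pnorm(-abs(z)), Q = Q, tau2 = tau2)
}

# vectorised DL over a CpG x cohort matrix pair (NA = absent)
dl_meta_matrix <- function(B, S) {
  ok <- is.finite(B) & is.finite(S)
  W <- ifelse(ok, 1 / S^2, 0)
  k <- rowSums(ok)
  sw <- rowSums(W)
  b_fe <- rowSums(W * ifelse(ok, B, 0)) / sw
  Q <- rowSums(W * ifelse(ok, (B - b_fe)^2, 0))
  denom <- sw - rowSums(W^2) / sw
  tau2 <- pmax(0, (Q - (k - 1)) / denom)
  tau2[k <= 1 | denom <= 0] <- 0
  WS <- ifelse(ok, 1 / (S^2 + tau2), 0)
  sws <- rowSums(WS)
  beta <- rowSums(WS * ifelse(ok, B, 0)) / sws
  se <- sqrt(1 / sws)
  z <- beta / se
  data.frame(k = k, beta = beta, se = se, z = z,
             p = 2 * stats::pnorm(-abs(z)), Q = Q, tau2 = tau2)
}

direction_string <- function(B) {
  apply(B, 1L, function(b) paste(
    ifelse(is.na(b), "?", ifelse(b > 0, "+", ifelse(b < 0, "-", "0"))),
    collapse = ""))
}

#' Meta-analyse corrected per-cohort EWAS statistics
#'
#' Pools the union of CpGs present in at least `min_cohorts` cohorts with
#' [dl_meta()], records a METAL-style direction string over the cohort order
#' ("+", "-", "0", "?" for absent), and flags DMPs at p < `sig`.
#'
#' @param cohort_stats named list of per-cohort stats data.frames
#'   (columns cpg, chrom, pos, beta, se at minimum).
#' @param min_cohorts minimum cohorts a CpG must appear in (default 1).
#' @param sig epigenome-wide significance threshold (default 9e-8).
#' @return data.frame of class `MetaStats`: cpg, chrom, pos, k, beta, se, z,
#'   p, Q, tau2, direction, dmp.
#' @export
run_meta <- function(cohort_stats, min_cohorts = 1L, sig = EPIGENOME_WIDE_P) {
  if (length(cohort_stats) == 0) stop("no cohorts supplied")
  all_cpg <- unique(unlist(lapply(cohort_stats, `[[`, "cpg")))
  nc <- length(cohort_stats)
  B <- S <- matrix(NA_real_, nrow = length(all_cpg), ncol = nc)
  chrom <- rep(NA_character_, length(all_cpg))
  pos <- rep(NA_integer_, length(all_cpg))
  for (i in seq_len(nc)) {
    st <- cohort_stats[[i]]
    idx <- match(st$cpg, all_cpg)
    B[idx, i] <- st$beta
    S[idx, i] <- st$se
    chrom[idx] <- st$chrom
    pos[idx] <- st$pos
  }
  pooled <- dl_meta_matrix(B, S)
  out <- cbind(data.frame(cpg = all_cpg, chrom = chrom, pos = pos,
                          stringsAsFactors = FALSE), pooled)
  out$direction <- direction_string(B)
  out <- out[out$k >= min_cohorts, , drop = FALSE]
  out$dmp <- out$p < sig
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("MetaStats", "data.frame")
  out
}
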