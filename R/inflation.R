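# Empirical-null estimation of bias and inflation of z-statistics.
#
# A three-component Gaussian mixture is fitted by EM; the largest-weight
# component is taken as the empirical null, whose mean is the bias and whose
# SD is the inflation of the test statistics. Statistics are corrected by
# rescaling (and optionally recentering) before meta-analysis. Genomic
# control lambda is reported alongside as the classical summary.

CHISQ1_MEDIAN <- stats::qchisq(0.5, df = 1)  # 0.4549364

#' Genomic-control lambda
#'
#' `median(z^2)` divided by the median of a chi-square with one degree of
#' freedom (0.4549). Note this is a variance-scale quantity: z drawn with
#' SD s gives lambda_GC ~ s^2.
#'
#' @param z vector of z-statistics.
#' @return lambda_GC (scalar).
#' @export
gc_lambda <- function(z) {
  z <- z[is.finite(z)]
  if (length(z) < 100)
    warning("fewer than 100 finite z values; lambda_GC is unstable")
  stats::median(z^2) / CHISQ1_MEDIAN
}

#' Fit a three-component Gaussian mixture to z-statistics
#'
#' EM on w0 N(m0, s0^2) + w1 N(m1, s1^2) + w2 N(m2, s2^2), initialised at
#' weights (0.9, 0.05, 0.05), means (0, -3, 3), SDs (1, 1, 1). The null
#' component is the one with the largest weight (ties broken by |mean|
#' closest to zero); its mean is the bias and its SD the inflation.
#'
#' @param z vector of z-statistics (>= 1000 recommended).
#' @param tol convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter maximum EM iterations (default 10000).
#' @return list of class `MixtureFit`: `weights`, `means`, `sds`, `bias`,
#'   `inflation`, `loglik` (trace), `converged`.
#' @export
fit_threecomp_mixture <- function(z, tol = 1e-6, max_iter = 10000L) {
  z <- z[is.finite(z)]
  n <- length(z)
  if (n < 10) stop("too few z values for a mixture fit")
  w <- c(0.9, 0.05, 0.05)
  mu <- c(0, -3, 3)
  sd_ <- c(1, 1, 1)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:3, function(k) w[k] * stats::dnorm(z, mu[k], sd_[k]),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    r <- dens / tot
    nk <- colSums(r)
    w <- nk / n
    mu <- colSums(r * z) / nk
    # identifiability constraint (the EM analogue of the informative priors
    # of the Gibbs formulation): the signal components stay outside the
    # null bulk, otherwise they absorb null mass on weak-signal data
    off <- 2 * sd_[1L]
    mu[2L] <- min(mu[2L], mu[1L] - off)
    mu[3L] <- max(mu[3L], mu[1L] + off)
    sd_ <- sqrt(colSums(r * (z - rep(mu, each = n))^2) / nk)
    sd_ <- pmax(sd_, 0.05)  # guard against component collapse
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  best <- which(w == max(w))
  if (length(best) > 1) best <- best[which.min(abs(mu[best]))]
  structure(list(weights = w, means = mu, sds = sd_,
                 bias = mu[best], inflation = sd_[best],
                 null_component = best, loglik = ll_trace,
                 converged = converged),
            class = "MixtureFit")
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat("MixtureFit: bias =", signif(x$bias, 4),
      " inflation =", signif(x$inflation, 4),
      if (!x$converged) " (not converged)" else "", "\n")
  invisible(x)
}

#' Correct per-cohort statistics for estimated bias and inflation
#'
#' corrected z = (z - bias)/inflation when `correct_bias`, else z/inflation;
#' corrected se = se * inflation (effect estimates are left untouched, so
#' corrected z ~ beta / corrected se when bias correction is off); p is
#' two-sided normal on the corrected z. Default is inflation-only
#' correction.
#'
#' @param stats `EwasStats` data.frame (cpg, beta, se, z, p, n ...).
#' @param fit a `MixtureFit`.
#' @param correct_bias also subtract the estimated bias (default FALSE).
#' @return data.frame of class `CorrectedStats` with columns of `stats` plus
#'   `z_raw`; attributes `bias`, `inflation`, `lambda_gc` (pre-correction).
#' @export
apply_correction <- function(stats, fit, correct_bias = FALSE) {
  if (fit$inflation <= 0) stop("inflation must be positive")
  out <- as.data.frame(stats)
  out$z_raw <- out$z
  b <- if (correct_bias) fit$bias else 0
  out$z <- (out$z_raw - b) / fit$inflation
  out$se <- out$se * fit$inflation
  out$p <- 2 * stats::pnorm(-abs(out$z))
  attr(out, "bias") <- fit$bias
  attr(out, "inflation") <- fit$inflation
  attr(out, "lambda_gc") <- suppressWarnings(gc_lambda(out$z_raw))
  class(out) <- c("CorrectedStats", "data.frame")
  out
}
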