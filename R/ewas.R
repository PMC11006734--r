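# Per-CpG robust regression of M-values on sex plus covariates.
#
# One Huber M-estimation fit per CpG (IRLS, c = 1.345, MAD scale) with
# heteroskedasticity-consistent (White/HC0) standard errors on the final
# weighted fit. p-values use the standard normal reference so that the
# z-statistics feed directly into the inflation and meta-analysis stages.

DEFAULT_COVARIATES <- c("gestational_age", "maternal_age", "smoking",
                        "cell_proportions")

#' Build the per-cohort design matrix
#'
#' Columns: intercept, female indicator (males are the reference), then the
#' requested covariates. The pseudo-covariate name `"cell_proportions"`
#' expands to five of the six cell-type columns: syncytiotrophoblast (the
#' largest mean share) is dropped as the reference since proportions sum
#' to one.
#'
#' @param sheet validated sample sheet (see [validate_sample_sheet()]).
#' @param covariates character vector of covariate names; default adds
#'   gestational age, maternal age, smoking and cell proportions.
#' @param include_sex keep the female column (dropped for sex-stratified
#'   meQTL fits).
#' @param drop_constant silently drop covariate columns that are constant
#'   in this sample subset (used for sex-stratified fits, where e.g. no
#'   smoker may remain in a stratum) instead of raising a rank error.
#' @return numeric matrix with rownames = sample ids; attribute
#'   `"female_col"` gives the female-indicator column index.
#' @export
build_design <- function(sheet, covariates = DEFAULT_COVARIATES,
                         include_sex = TRUE, drop_constant = FALSE) {
  sheet <- validate_sample_sheet(sheet)
  cols <- list(`(Intercept)` = rep(1, nrow(sheet)))
  if (include_sex) cols$female <- as.numeric(sheet$sex == "female")
  for (cv in covariates) {
    if (identical(cv, "cell_proportions")) {
      keep <- setdiff(CELL_TYPES, "syncytiotrophoblast")
      for (ct in keep) cols[[ct]] <- sheet[[ct]]
    } else {
      if (!cv %in% names(sheet)) stop("covariate not in sheet: ", cv)
      v <- sheet[[cv]]
      if (!is.numeric(v)) v <- as.numeric(as.factor(v)) - 1
      cols[[cv]] <- v
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- sheet$sample_id
  if (drop_constant && ncol(X) > 1L) {
    const <- c(FALSE, apply(X[, -1L, drop = FALSE], 2L, stats::var) == 0)
    if (any(const)) {
      message("dropping constant covariate(s): ",
              paste(colnames(X)[const], collapse = ", "))
      X <- X[, !const, drop = FALSE]
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(colnames(X)[drop_idx], collapse = ", "))
  }
  attr(X, "female_col") <- if (include_sex) 2L else NA_integer_
  X
}

#' Huber IRLS regression
#'
#' Iteratively reweighted least squares with the Huber psi function
#' (tuning constant `c`), residual scale estimated each iteration as the
#' MAD of residuals rescaled by 1.4826. Convergence when the largest
#' coefficient change is below `tol` or after `max_iter` iterations.
#' A perfect fit (zero residual scale) falls back to OLS and is flagged.
#'
#' @param y response vector.
#' @param X design matrix (rows > cols).
#' @param c Huber tuning constant (default 1.345, 95% Gaussian efficiency).
#' @param tol convergence tolerance on coefficients (default 1e-8).
#' @param max_iter maximum IRLS iterations (default 50).
#' @return list with `coefficients`, `scale`, `weights` (final IRLS
#'   weights), `residuals`, `iterations`, `degenerate` flag.
#' @export
huber_irls <- function(y, X, c = 1.345, tol = 1e-8, max_iter = 50L) {
  n <- length(y)
  if (n <= ncol(X)) stop("need more rows than columns")
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  res <- fit$residuals
  scale <- stats::mad(res, center = 0)
  if (scale <= .Machine$double.eps * max(abs(y), 1)) {
    return(list(coefficients = beta, scale = 0,
                weights = rep(1, n), psi_prime = rep(1, n), residuals = res,
                iterations = 0L, degenerate = TRUE))
  }
  w <- rep(1, n)
  for (it in seq_len(max_iter)) {
    u <- abs(res / scale)
    w <- ifelse(u <= c, 1, c / u)
    sw <- sqrt(w)
    fit <- stats::lm.fit(X * sw, y * sw)
    beta_new <- fit$coefficients
    res <- y - drop(X %*% beta_new)
    scale_new <- stats::mad(res, center = 0)
    if (scale_new <= .Machine$double.eps * max(abs(y), 1)) {
      # essentially perfect weighted fit; keep OLS on the raw data
      ols <- stats::lm.fit(X, y)
      return(list(coefficients = ols$coefficients, scale = 0,
                  weights = rep(1, n), psi_prime = rep(1, n),
                  residuals = ols$residuals,
                  iterations = it, degenerate = TRUE))
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    scale <- scale_new
    if (delta < tol) break
  }
  # psi-prime weights (Huber: indicator of the linear zone) for the
  # M-estimator bread; distinct from the IRLS weights c/|u| in the tails
  psi_prime <- as.numeric(abs(res / scale) <= c)
  list(coefficients = beta, scale = scale, weights = w,
       psi_prime = psi_prime, residuals = res,
       iterations = it, degenerate = FALSE)
}

#' White (HC0) sandwich standard errors for a (possibly robust) fit
#'
#' `(X'BX)^-1 X'W diag(r^2) WX (X'BX)^-1` where W holds the final IRLS
#' weights (so W r is the Huber psi-residual) and B the bread weights. With
#' unit weights this is the plain HC0 White estimator for OLS. For a Huber
#' fit the bread uses the psi-prime weights (indicator of the linear zone),
#' the asymptotically correct M-estimator sandwich; passing `bread_weights =
#' weights` reproduces the naive weighted form, which overstates z by
#' ~E[w]/E[psi'] on clean Gaussian data.
#'
#' @param X design matrix.
#' @param residuals residual vector of the converged fit.
#' @param weights final IRLS weights (unit weights give plain HC0 OLS).
#' @param bread_weights weights for the bread matrix; defaults to `weights`
#'   (use the fit's `psi_prime` for Huber fits). When these are the 0/1
#'   psi-prime indicators the bread uses the expectation form
#'   `mean(psi') X'X`, which stays nonsingular even when the excluded
#'   observations carry a sparse design column.
#' @return named vector of standard errors.
#' @export
white_sandwich_se <- function(X, residuals, weights = rep(1, nrow(X)),
                              bread_weights = weights) {
  Xw <- X * weights                       # W X (W diagonal)
  if (all(bread_weights %in% c(0, 1)) && any(bread_weights == 0)) {
    bread <- mean(bread_weights) * crossprod(X)
  } else {
    bread <- crossprod(X, X * bread_weights)  # X'BX
  }
  bi <- tryCatch(solve(bread), error = function(e)
    stop("singular bread matrix"))
  meat <- crossprod(Xw * abs(residuals))  # X'W diag(r^2) W X
  V <- bi %*% meat %*% bi
  se <- sqrt(diag(V))
  names(se) <- colnames(X)
  se
}

#' Epigenome-wide robust regression scan
#'
#' Fits one Huber regression per CpG of M-value on the design built from the
#' sheet, and reports the female-vs-male coefficient with its HC0 sandwich
#' standard error, z = beta/se, and a two-sided normal p-value. A CpG whose
#' M-values are constant yields an NA row (flagged in `degenerate`).
#'
#' @param meth `MethylationData`.
#' @param sheet sample sheet aligned by sample id (order may differ; matched
#'   by id).
#' @param covariates covariate names passed to [build_design()].
#' @return data.frame of class `EwasStats`: cpg, chrom, pos, beta, se, z, p,
#'   n, degenerate.
#' @export
run_ewas <- function(meth, sheet, covariates = DEFAULT_COVARIATES) {
  sheet <- validate_sample_sheet(sheet)
  idx <- match(meth$samples, sheet$sample_id)
  if (any(is.na(idx)))
    stop("sheet lacks sample: ", meth$samples[which(is.na(idx))[1L]])
  sheet <- sheet[idx, , drop = FALSE]
  X <- build_design(sheet, covariates)
  n <- nrow(X)
  ncpg <- nrow(meth$m)
  beta <- se <- rep(NA_real_, ncpg)
  degen <- logical(ncpg)
  for (j in seq_len(ncpg)) {
    y <- meth$m[j, ]
    if (stats::var(y) == 0) { degen[j] <- TRUE; next }
    fit <- huber_irls(y, X)
    s <- white_sandwich_se(X, fit$residuals, fit$weights, fit$psi_prime)
    beta[j] <- fit$coefficients[2L]
    se[j] <- s[2L]
    degen[j] <- fit$degenerate
  }
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(cpg = meth$cpg_ids, chrom = meth$annotation$chrom,
                    pos = meth$annotation$pos, beta = beta, se = se,
                    z = z, p = p, n = n, degenerate = degen,
                    stringsAsFactors = FALSE)
  if (any(degen))
    message(sum(degen), " degenerate CpG(s) (zero variance or perfect fit)")
  class(out) <- c("EwasStats", "data.frame")
  out
}

#' Write / read EWAS statistics TSV
#' @param stats `EwasStats` (or corrected/meta) data.frame.
#' @param path file path.
#' @export
write_stats_tsv <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stats_tsv
#' @export
read_stats_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
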