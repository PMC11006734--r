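# cis-meQTL mapping: genotype QC, cis pair enumeration, per-cohort OLS
# association overall and sex-stratified, DerSimonian-Laird meta-analysis
# per stratum, and sex-consistent vs sex-specific classification.

MEQTL_SIG_P <- 1e-8

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, the p-value is
#' the sum of probabilities of all heterozygote counts (of the same parity)
#' that are no more probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (nonnegative integers).
#' @return two-sided exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("counts must be nonnegative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all-zero genotype counts")
  n_a <- 2 * n_aa + n_Aa           # minor-ish allele count (either is fine)
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_a, n_A)
  # possible heterozygote counts share the parity of the rare allele count
  het <- seq.int(rare %% 2, rare, by = 2)
  # log P(n_Aa = h | allele counts) up to a constant:
  # 2^h * n! / (nAA! nAa! naa!) with nAA = (n_A - h)/2 etc.
  logp <- vapply(het, function(h) {
    haa <- (rare - h) / 2          # homozygotes of the rarer allele
    hAA <- n - h - haa             # homozygotes of the common allele
    h * log(2) - lfactorial(hAA) - lfactorial(h) - lfactorial(haa)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- match(n_Aa, het)
  if (is.na(obs)) stop("observed heterozygote count inconsistent with alleles")
  sum(prob[prob <= prob[obs] * (1 + 1e-12)])
}

#' Genotype quality control
#'
#' Applies, in order: call rate >= `call_rate`, minor allele frequency >=
#' `maf`, exact HWE p > `hwe_p`. Each SNP is removed by the first criterion
#' it fails; a report counts removals per criterion.
#'
#' @param geno `GenotypeData`.
#' @param call_rate minimum call rate (default 0.98).
#' @param maf minimum minor allele frequency (default 0.05).
#' @param hwe_p HWE exact-test p-value floor (default 1e-5).
#' @return list: `geno` (filtered `GenotypeData`), `report` (data.frame of
#'   per-criterion removal counts), `removed` (snp_id -> reason).
#' @export
qc_genotypes <- function(geno, call_rate = 0.98, maf = 0.05, hwe_p = 1e-5) {
  qc <- geno$qc
  reason <- rep(NA_character_, nrow(qc))
  reason[is.na(reason) & qc$call_rate < call_rate] <- "call_rate"
  reason[is.na(reason) & (is.na(qc$maf) | qc$maf < maf)] <- "maf"
  reason[is.na(reason) & qc$hwe_p <= hwe_p] <- "hwe"
  keep <- is.na(reason)
  report <- data.frame(criterion = c("call_rate", "maf", "hwe"),
                       removed = c(sum(reason == "call_rate", na.rm = TRUE),
                                   sum(reason == "maf", na.rm = TRUE),
                                   sum(reason == "hwe", na.rm = TRUE)))
  filtered <- genotype_data(geno$dosages[keep, , drop = FALSE],
                            geno$snps[keep, , drop = FALSE])
  removed <- data.frame(snp_id = qc$snp_id[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  list(geno = filtered, report = report, removed = removed)
}

#' Genotype principal components
#'
#' PCA of the mean-imputed, per-SNP standardized dosage matrix (constant
#' SNPs are excluded from standardization); used as population-structure
#' covariates in the meQTL models.
#'
#' @param geno `GenotypeData`.
#' @param k number of components (default 2).
#' @return samples x k matrix of scores (columns PC1..PCk).
#' @export
genotype_pcs <- function(geno, k = 2L) {
  D <- geno$dosages
  mu <- rowMeans(D, na.rm = TRUE)
  D[is.na(D)] <- mu[row(D)[is.na(D)]]
  sdv <- apply(D, 1L, stats::sd)
  keep <- sdv > 0
  Z <- (D[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  if (k > min(dim(Z)) - 1L) stop("k exceeds the rank of the dosage matrix")
  sv <- svd(crossprod(Z) / nrow(Z), nu = 0, nv = k)
  scores <- sv$v[, seq_len(k), drop = FALSE] * rep(sqrt(sv$d[seq_len(k)]),
                                                   each = ncol(Z))
  rownames(scores) <- colnames(D)
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Enumerate cis SNP-CpG pairs
#'
#' Same-chromosome pairs with |pos_SNP - pos_CpG| <= `window` (closed
#' boundary).
#'
#' @param snps SNP table (snp_id, chrom, pos).
#' @param cpgs CpG annotation (cpg_id, chrom, pos).
#' @param window cis half-width in bp (default 150000).
#' @return data.frame: snp_id, cpg_id, distance (signed, SNP - CpG).
#' @export
map_cis_pairs <- function(snps, cpgs, window = 150000L) {
  out <- list()
  for (ch in intersect(unique(snps$chrom), unique(cpgs$chrom))) {
    s <- snps[snps$chrom == ch, , drop = FALSE]
    g <- cpgs[cpgs$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    lo <- findInterval(g$pos - window - 1L, s$pos) + 1L
    hi <- findInterval(g$pos + window, s$pos)
    n_each <- pmax(hi - lo + 1L, 0L)
    if (sum(n_each) == 0) next
    ci <- rep.int(seq_len(nrow(g)), n_each)
    si <- unlist(lapply(seq_len(nrow(g)), function(i)
      if (n_each[i] > 0) lo[i]:hi[i] else integer(0)))
    out[[ch]] <- data.frame(snp_id = s$snp_id[si], cpg_id = g$cpg_id[ci],
                            distance = s$pos[si] - g$pos[ci],
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(snp_id = character(0), cpg_id = character(0),
                      distance = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-cohort cis-meQTL association scan
#'
#' Ordinary least squares of each CpG's M-values on additive dosage plus
#' covariates (smoking, gestational age, cell proportions, the first two
#' genotype PCs, and sex — dropped in sex-stratified strata), fitted by
#' residualizing both M and dosage on the covariates. p-values are
#' two-sided normal, matching the matrix-factorized screens used for this
#' task. SNPs monomorphic within the stratum are skipped.
#'
#' @param meth `MethylationData`.
#' @param geno `GenotypeData` (QC'd; missing dosages are mean-imputed).
#' @param sheet sample sheet covering the methylation samples.
#' @param pairs cis pair table from [map_cis_pairs()]; computed at `window`
#'   if NULL.
#' @param stratum `"all"`, `"male"` or `"female"`.
#' @param window cis half-width when `pairs` is NULL.
#' @return data.frame: snp_id, cpg_id, distance, beta, se, p, n.
#' @export
fit_meqtl_cohort <- function(meth, geno, sheet, pairs = NULL,
                             stratum = c("all", "male", "female"),
                             window = 150000L) {
  stratum <- match.arg(stratum)
  sheet <- validate_sample_sheet(sheet)
  common <- intersect(intersect(meth$samples, sheet$sample_id), geno$samples)
  if (stratum != "all")
    common <- intersect(common, sheet$sample_id[sheet$sex == stratum])
  if (length(common) < 10) stop("too few samples in stratum ", stratum)
  sheet <- sheet[match(common, sheet$sample_id), , drop = FALSE]
  M <- meth$m[, common, drop = FALSE]
  D <- geno$dosages[, common, drop = FALSE]
  mu <- rowMeans(D, na.rm = TRUE)
  D[is.na(D)] <- mu[row(D)[is.na(D)]]
  pcs <- genotype_pcs(geno, 2L)[common, , drop = FALSE]
  X <- build_design(sheet, include_sex = (stratum == "all"),
                    drop_constant = TRUE)
  X <- cbind(X, pcs)
  if (is.null(pairs)) pairs <- map_cis_pairs(geno$snps, meth$annotation, window)
  empty <- data.frame(snp_id = character(0), cpg_id = character(0),
                      distance = integer(0), beta = numeric(0),
                      se = numeric(0), p = numeric(0), n = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) return(empty)
  # residualize M and dosage on covariates; per-pair simple regression
  Q <- qr.Q(qr(X))
  RM <- t(M) - Q %*% crossprod(Q, t(M))       # n x cpg residuals
  RD <- t(D) - Q %*% crossprod(Q, t(D))       # n x snp residuals
  n <- length(common)
  dfree <- n - ncol(X) - 1L
  si <- match(pairs$snp_id, colnames(RD))
  ci <- match(pairs$cpg_id, colnames(RM))
  ok <- !is.na(si) & !is.na(ci)
  mono <- apply(D, 1L, function(r) stats::var(r) == 0)
  poly_ok <- !mono[si]
  keep <- ok & poly_ok
  if (any(ok & !poly_ok))
    message(sum(ok & !poly_ok), " pair(s) skipped: monomorphic SNP in stratum ",
            stratum)
  si <- si[keep]; ci <- ci[keep]
  if (length(si) == 0) return(empty)
  sxx_all <- colSums(RD^2)
  syy_all <- colSums(RM^2)
  np <- length(si)
  sxy <- numeric(np)
  for (chunk in split(seq_len(np), ceiling(seq_len(np) / 5000))) {
    sxy[chunk] <- colSums(RD[, si[chunk], drop = FALSE] *
                          RM[, ci[chunk], drop = FALSE])
  }
  sxx <- sxx_all[si]
  syy <- syy_all[ci]
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / dfree / sxx)
  z <- beta / se
  data.frame(snp_id = pairs$snp_id[keep], cpg_id = pairs$cpg_id[keep],
             distance = pairs$distance[keep], beta = beta, se = se,
             p = 2 * stats::pnorm(-abs(z)), n = rep(n, length(beta)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Meta-analyse per-cohort meQTL statistics for one stratum
#'
#' DerSimonian-Laird pooling per SNP-CpG pair over the cohorts where the
#' pair was measured; only pairs present in at least `min_cohorts` cohorts
#' are kept, and significance is flagged at `sig`.
#'
#' @param cohort_stats list of per-cohort [fit_meqtl_cohort()] outputs.
#' @param min_cohorts minimum cohorts per pair (default 2).
#' @param sig cis significance threshold (default 1e-8).
#' @return data.frame: snp_id, cpg_id, distance, k, beta, se, z, p, Q, tau2,
#'   significant.
#' @export
meta_meqtl <- function(cohort_stats, min_cohorts = 2L, sig = MEQTL_SIG_P) {
  if (length(cohort_stats) == 0) stop("no cohorts supplied")
  key <- function(st) paste(st$snp_id, st$cpg_id, sep = "\r")
  all_keys <- unique(unlist(lapply(cohort_stats, key)))
  nc <- length(cohort_stats)
  B <- S <- matrix(NA_real_, nrow = length(all_keys), ncol = nc)
  dist <- rep(NA_integer_, length(all_keys))
  for (i in seq_len(nc)) {
    st <- cohort_stats[[i]]
    idx <- match(key(st), all_keys)
    B[idx, i] <- st$beta
    S[idx, i] <- st$se
    dist[idx] <- st$distance
  }
  pooled <- dl_meta_matrix(B, S)
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  out <- cbind(data.frame(snp_id = vapply(parts, `[[`, character(1), 1L),
                          cpg_id = vapply(parts, `[[`, character(1), 2L),
                          distance = dist, stringsAsFactors = FALSE), pooled)
  out <- out[out$k >= min_cohorts, , drop = FALSE]
  out$significant <- out$p < sig
  rownames(out) <- NULL
  out
}

#' Classify meQTLs as sex-consistent or sex-specific
#'
#' Pair level: a pair is *sex-consistent* when it is significant in the
#' overall sample and its male and female meta effects share a direction;
#' *sex-specific* when it is significant in the male-only or female-only
#' stratum and the other sex's effect has the opposite direction. CpGs
#' appearing in both pair-level groups are assigned to the group whose
#' qualifying pair has the lowest meta p (ties to sex-consistent), so the
#' CpG-level classes are disjoint by construction.
#'
#' @param all_meta,male_meta,female_meta [meta_meqtl()] outputs for the
#'   three strata (same pair universe).
#' @param sig significance threshold (default 1e-8).
#' @return list: `pairs` (pair-level labels), `cpg` (disjoint CpG-level
#'   classes with the supporting best pair), `consistent_cpgs`,
#'   `specific_cpgs` (character vectors).
#' @export
classify_sex_meqtls <- function(all_meta, male_meta, female_meta,
                                sig = MEQTL_SIG_P) {
  key <- function(st) paste(st$snp_id, st$cpg_id, sep = "\r")
  ka <- key(all_meta); km <- key(male_meta); kf <- key(female_meta)
  # align male/female onto the overall universe
  bm <- male_meta$beta[match(ka, km)]
  bf <- female_meta$beta[match(ka, kf)]
  pm <- male_meta$p[match(ka, km)]
  pf <- female_meta$p[match(ka, kf)]
  consistent <- !is.na(bm) & !is.na(bf) & all_meta$p < sig &
    sign(bm) == sign(bf) & sign(bm) != 0
  spec_m <- !is.na(pm) & !is.na(bf) & pm < sig & sign(bm) != sign(bf)
  spec_f <- !is.na(pf) & !is.na(bm) & pf < sig & sign(bf) != sign(bm)
  specific <- (spec_m | spec_f) & !is.na(bm) & !is.na(bf)
  n_missing <- sum(is.na(bm) | is.na(bf))
  if (n_missing)
    message(n_missing, " pair(s) lack a stratum and are ineligible for ",
            "classification rules requiring it")
  pair_p_spec <- pmin(ifelse(spec_m, pm, Inf), ifelse(spec_f, pf, Inf))
  pairs <- data.frame(snp_id = all_meta$snp_id, cpg_id = all_meta$cpg_id,
                      consistent = consistent, specific = specific,
                      p_consistent = ifelse(consistent, all_meta$p, Inf),
                      p_specific = pair_p_spec,
                      stringsAsFactors = FALSE)
  best_by_cpg <- function(flag, pcol) {
    sub <- pairs[flag, , drop = FALSE]
    if (nrow(sub) == 0)
      return(data.frame(cpg_id = character(0), p = numeric(0), snp_id = character(0),
                        stringsAsFactors = FALSE))
    o <- order(sub$cpg_id, sub[[pcol]])
    sub <- sub[o, , drop = FALSE]
    sub <- sub[!duplicated(sub$cpg_id), , drop = FALSE]
    data.frame(cpg_id = sub$cpg_id, p = sub[[pcol]], snp_id = sub$snp_id,
               stringsAsFactors = FALSE)
  }
  bc <- best_by_cpg(pairs$consistent, "p_consistent")
  bs <- best_by_cpg(pairs$specific, "p_specific")
  both <- intersect(bc$cpg_id, bs$cpg_id)
  # disjointness rule: lowest qualifying p wins; ties go to sex-consistent
  to_spec <- both[bs$p[match(both, bs$cpg_id)] < bc$p[match(both, bc$cpg_id)]]
  bc_keep <- bc[!bc$cpg_id %in% to_spec, , drop = FALSE]
  bs_keep <- bs[!bs$cpg_id %in% setdiff(both, to_spec), , drop = FALSE]
  cpg <- rbind(
    if (nrow(bc_keep)) cbind(bc_keep, class = "sex_consistent") else NULL,
    if (nrow(bs_keep)) cbind(bs_keep, class = "sex_specific") else NULL)
  if (is.null(cpg))
    cpg <- data.frame(cpg_id = character(0), p = numeric(0),
                      snp_id = character(0), class = character(0),
                      stringsAsFactors = FALSE)
  stopifnot(!any(duplicated(cpg$cpg_id)))  # disjoint by construction
  rownames(cpg) <- NULL
  list(pairs = pairs, cpg = cpg,
       consistent_cpgs = cpg$cpg_id[cpg$class == "sex_consistent"],
       specific_cpgs = cpg$cpg_id[cpg$class == "sex_specific"])
}
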