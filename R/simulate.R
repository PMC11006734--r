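# Synthetic multi-cohort generator with planted ground truth.
#
# Emulates the statistical structure the analysis assumes: three cohorts with
# realistic phenotype distributions, M-value matrices with planted sex
# effects biased toward female hypomethylation, per-cohort test-statistic
# inflation, spatially correlated CpG neighborhoods for region calling, and
# biallelic genotypes in HWE with planted cis-meQTLs of sex-consistent and
# sex-specific kinds.
#
# Inflation is planted as a sex-aligned polygenic background: every null CpG
# receives a small cohort-specific effect b ~ N(bias * s, (lambda^2 - 1) s^2)
# where s = sigma_j * ||w_c|| is the sampling SD of the female coefficient
# under the realized cohort design. Null z-statistics then genuinely have
# mean ~ bias and SD ~ lambda, so the empirical-null correction stage is
# exercised on data rather than on rescaled numbers. (Independent
# heteroskedastic noise cannot inflate sandwich-based z-statistics, which is
# why the background construction is used.)

#' Simulation configuration
#'
#' @param cohort_sizes integer vector of per-cohort sample counts
#'   (default 137, 470, 139).
#' @param n_cpgs number of CpGs per cohort matrix.
#' @param n_snps number of SNPs in the shared genotype panel.
#' @param frac_dmp fraction of CpGs with a true sex effect.
#' @param hypo_female_frac fraction of true effects that are negative in
#'   females (default 0.85, female hypomethylation).
#' @param effect_size mean |true effect| in M-value units (default 0.5).
#' @param effect_size_sd SD of |true effect| around `effect_size`.
#' @param residual_sd typical per-CpG residual SD of M-values (per-CpG SDs
#'   are lognormal around this value).
#' @param cohort_inflation per-cohort target SD of null z-statistics
#'   (default 1.14, 1.37, 1.17).
#' @param cohort_bias per-cohort target mean of null z-statistics (default 0).
#' @param region_spec list of planted regions, each
#'   `list(n_probes=, spacing=, effect=)` (spacing in bp, effect in M-units
#'   shared in sign across member probes).
#' @param meqtl_spec `list(n_consistent=, n_sex_specific=, beta=, window=)`:
#'   planted cis-meQTL counts, per-allele effect (M-units) and cis window (bp).
#' @param tissue_effect_corr named vector of target correlations of true sex
#'   effects between tissue pairs (`cvs_placenta`, `cvs_cordblood`,
#'   `placenta_cordblood`).
#' @param tissue_effect_sd SD of true per-tissue sex effects in the tissue
#'   set (all CpGs; models a continuum of small effects).
#' @param n_tissue_samples samples in the triple-tissue subset (default 65).
#' @param acf_rho residual correlation of CpG neighbors closer than 200 bp.
#' @param cpg_spacing_bp mean inter-CpG gap; with `regular_spacing` the gap
#'   is exact rather than exponential.
#' @param regular_spacing logical; lay CpGs on an exact grid.
#' @param covariate_effect_sd SD of per-CpG covariate coefficients.
#' @param seed master seed; one RNG stream per cohort is derived from it.
#' @return list of class `SimulationConfig`.
#' @export
sim_config <- function(cohort_sizes = c(137L, 470L, 139L),
                       n_cpgs = 2000L,
                       n_snps = 500L,
                       frac_dmp = 0.02,
                       hypo_female_frac = 0.85,
                       effect_size = 0.5,
                       effect_size_sd = 0.1,
                       residual_sd = 0.5,
                       cohort_inflation = c(1.14, 1.37, 1.17),
                       cohort_bias = rep(0, length(cohort_sizes)),
                       region_spec = list(),
                       meqtl_spec = list(n_consistent = 0L, n_sex_specific = 0L,
                                         beta = 0.8, window = 150000L),
                       tissue_effect_corr = c(cvs_placenta = 0.55,
                                              cvs_cordblood = 0,
                                              placenta_cordblood = 0),
                       tissue_effect_sd = 0.3,
                       n_tissue_samples = 65L,
                       acf_rho = 0.5,
                       cpg_spacing_bp = 10000,
                       regular_spacing = FALSE,
                       covariate_effect_sd = 0.02,
                       seed = 1L) {
  stopifnot(frac_dmp >= 0, frac_dmp <= 1,
            hypo_female_frac >= 0, hypo_female_frac <= 1,
            cpg_spacing_bp > 0, residual_sd > 0)
  cohort_inflation <- rep_len(cohort_inflation, length(cohort_sizes))
  cohort_bias <- rep_len(cohort_bias, length(cohort_sizes))
  for (r in region_spec) stopifnot(r$spacing > 0, r$n_probes >= 1)
  cfg <- as.list(environment())
  class(cfg) <- "SimulationConfig"
  cfg
}

# deterministic per-cohort RNG stream derived from the master seed
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483629) + 1L
}

# cohort-level phenotype distributions (birth cohort demographics scale:
# gestational age in weeks, maternal age in years, smoking prevalence and
# sex ratio per cohort)
COHORT_PHENO <- list(
  ga_mean = c(38.2, 40.0, 39.9), ga_sd = c(1.95, 1.55, 1.43),
  mat_age_mean = c(29.2, 34.5, 32.0), mat_age_sd = c(5.8, 4.9, 5.2),
  smoking = c(0.23, 0.02, 0.10), male_frac = c(0.51, 0.51, 0.48))

# Dirichlet draw via gamma variates
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), ncol = length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

CELL_ALPHA <- 50 * c(nRBC = 0.05, trophoblast = 0.15, syncytiotrophoblast = 0.50,
                     stromal = 0.15, Hofbauer = 0.05, endothelial = 0.10)

simulate_sheet <- function(n, cohort_name, ci, tissue = "placenta") {
  ph <- COHORT_PHENO
  i <- ((ci - 1L) %% 3L) + 1L  # recycle the three phenotype profiles
  sex <- ifelse(stats::runif(n) < ph$male_frac[i], "male", "female")
  props <- rdirichlet(n, CELL_ALPHA)
  colnames(props) <- CELL_TYPES
  ga <- stats::rnorm(n, ph$ga_mean[i], ph$ga_sd[i])
  if (tissue == "cvs") ga <- stats::rnorm(n, 12.5, 1.2)  # first-trimester sampling
  smoking <- as.integer(stats::runif(n) < ph$smoking[i])
  # keep the design estimable at small n: smoking must vary within a cohort
  if (length(unique(smoking)) == 1L)
    smoking[sample.int(n, 1L)] <- 1L - smoking[1L]
  if (length(unique(sex)) == 1L)
    sex[sample.int(n, 1L)] <- setdiff(c("male", "female"), sex[1L])
  sheet <- data.frame(
    sample_id = sprintf("%s_S%03d", cohort_name, seq_len(n)),
    cohort = cohort_name, tissue = tissue, sex = sex,
    gestational_age = ga,
    maternal_age = stats::rnorm(n, ph$mat_age_mean[i], ph$mat_age_sd[i]),
    smoking = smoking,
    stringsAsFactors = FALSE)
  cbind(sheet, as.data.frame(props))
}

# genome layout: CpGs across 6 chromosomes; planted regions are runs of
# consecutive CpGs whose gaps are overwritten with the region spacing
layout_cpgs <- function(cfg) {
  n <- cfg$n_cpgs
  n_chr <- min(6L, max(1L, n %/% 50L + 1L))
  chrom <- sort(rep_len(paste0("chr", seq_len(n_chr)), n))
  gaps <- if (cfg$regular_spacing) rep(cfg$cpg_spacing_bp, n)
          else pmax(201, round(stats::rexp(n, 1 / cfg$cpg_spacing_bp)))
  region_id <- integer(n)
  used <- logical(n)
  for (ri in seq_along(cfg$region_spec)) {
    r <- cfg$region_spec[[ri]]
    # pick a run inside one chromosome, away from already-used runs
    repeat {
      start <- sample.int(n - r$n_probes, 1L)
      run <- start:(start + r$n_probes - 1L)
      if (length(unique(chrom[run])) == 1L && !any(used[run])) break
    }
    gaps[run[-1L]] <- r$spacing
    region_id[run] <- ri
    used[run] <- TRUE
  }
  pos <- integer(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- 1e6 + cumsum(c(0, gaps[idx[-1L]]))
  }
  data.frame(cpg_id = sprintf("cg%07d", seq_len(n)), chrom = chrom,
             pos = as.integer(pos), region_id = region_id,
             stringsAsFactors = FALSE)
}

# residual noise with AR-style correlation between neighbors within 200 bp;
# unit marginal variance. Returns n_cpg x n_sample matrix.
correlated_noise <- function(ann, n_samples, rho) {
  n <- nrow(ann)
  e <- matrix(stats::rnorm(n * n_samples), nrow = n)
  if (rho == 0) return(e)
  for (ch in unique(ann$chrom)) {
    idx <- which(ann$chrom == ch)
    if (length(idx) < 2) next
    gap <- diff(ann$pos[idx])
    r <- ifelse(gap <= 200, rho, 0)
    for (k in seq_along(gap)) {
      if (r[k] > 0)
        e[idx[k + 1L], ] <- r[k] * e[idx[k], ] +
          sqrt(1 - r[k]^2) * e[idx[k + 1L], ]
    }
  }
  e
}

#' Simulate a multi-cohort methylation study with planted truth
#'
#' @param cfg a [sim_config()].
#' @return list with `cohorts` (per cohort: `meth`, `sheet`, `geno`) and
#'   `truth` (per-CpG effects and flags, per-region intervals, per-pair
#'   meQTL classes).
#' @export
simulate_multi_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(derive_seed(cfg$seed, 0L))
  ann <- layout_cpgs(cfg)
  n_cpgs <- cfg$n_cpgs

  # per-CpG baseline: bimodal M-value means, lognormal residual SDs
  comp <- sample.int(3L, n_cpgs, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  mu <- c(-2.5, 2.5, 0)[comp] + stats::rnorm(n_cpgs, 0, 0.8)
  sigma <- cfg$residual_sd * exp(stats::rnorm(n_cpgs, 0, 0.3))

  # planted single-CpG sex effects (excluding region probes, which get the
  # region effect) with sign biased toward female hypomethylation
  n_dmp <- floor(cfg$frac_dmp * n_cpgs)
  if (cfg$frac_dmp > 0 && n_dmp < 1)
    warning("frac_dmp * n_cpgs < 1: zero planted effects")
  free <- which(ann$region_id == 0L)
  dmp_idx <- if (n_dmp > 0) sample(free, n_dmp) else integer(0)
  effect <- numeric(n_cpgs)
  if (n_dmp > 0) {
    mag <- pmax(0.05, cfg$effect_size + stats::rnorm(n_dmp, 0, cfg$effect_size_sd))
    sgn <- ifelse(stats::runif(n_dmp) < cfg$hypo_female_frac, -1, 1)
    effect[dmp_idx] <- sgn * mag
  }
  for (ri in seq_along(cfg$region_spec)) {
    r <- cfg$region_spec[[ri]]
    run <- which(ann$region_id == ri)
    sgn <- if (stats::runif(1) < cfg$hypo_female_frac) -1 else 1
    effect[run] <- sgn * r$effect
  }
  is_dmp <- effect != 0

  # shared SNP panel: planted meQTL SNPs near their target CpGs, the rest
  # scattered in CpG neighborhoods
  mq <- cfg$meqtl_spec
  n_planted <- mq$n_consistent + mq$n_sex_specific
  if (cfg$n_snps < n_planted) stop("n_snps < planted meQTL count")
  mq_cpg <- if (n_planted > 0)
    sample(which(!is_dmp & ann$region_id == 0L), n_planted) else integer(0)
  snp_pos <- integer(cfg$n_snps)
  snp_chrom <- character(cfg$n_snps)
  if (n_planted > 0) {
    snp_chrom[1:n_planted] <- ann$chrom[mq_cpg]
    snp_pos[1:n_planted] <- ann$pos[mq_cpg] +
      round(stats::runif(n_planted, -0.8, 0.8) * mq$window)
  }
  if (cfg$n_snps > n_planted) {
    rest <- (n_planted + 1L):cfg$n_snps
    anchor <- sample.int(n_cpgs, length(rest), replace = TRUE)
    snp_chrom[rest] <- ann$chrom[anchor]
    snp_pos[rest] <- ann$pos[anchor] +
      round(stats::runif(length(rest), -2, 2) * mq$window)
  }
  snp_pos <- pmax(1L, snp_pos)
  snps <- data.frame(snp_id = sprintf("rs%06d", seq_len(cfg$n_snps)),
                     chrom = snp_chrom, pos = as.integer(snp_pos),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  snp_maf <- stats::runif(cfg$n_snps, 0.05, 0.5)
  if (n_planted > 0) snp_maf[1:n_planted] <- stats::runif(n_planted, 0.15, 0.5)

  # planted meQTL truth: per-stratum genotype effects
  meqtl_truth <- NULL
  delta_m <- delta_f <- numeric(cfg$n_snps)
  if (n_planted > 0) {
    cls <- rep(c("sex_consistent", "sex_specific"),
               c(mq$n_consistent, mq$n_sex_specific))
    sgn <- sample(c(-1, 1), n_planted, replace = TRUE)
    dm <- df <- sgn * mq$beta
    spec <- which(cls == "sex_specific")
    # half male-driven, half female-driven; the other sex gets a weaker
    # opposite-direction effect so stratified direction checks can fire
    male_driven <- spec[seq_along(spec) %% 2L == 1L]
    female_driven <- setdiff(spec, male_driven)
    df[male_driven] <- -dm[male_driven] / 4
    dm[female_driven] <- -df[female_driven] / 4
    delta_m[1:n_planted] <- dm
    delta_f[1:n_planted] <- df
    meqtl_truth <- data.frame(
      snp_id = snps$snp_id[1:n_planted], cpg_id = ann$cpg_id[mq_cpg],
      class = cls, beta_male = dm, beta_female = df,
      stringsAsFactors = FALSE)
  }

  cohort_names <- paste0("cohort", seq_along(cfg$cohort_sizes))
  cohorts <- vector("list", length(cfg$cohort_sizes))
  names(cohorts) <- cohort_names
  for (ci in seq_along(cfg$cohort_sizes)) {
    set.seed(derive_seed(cfg$seed, ci))
    n <- cfg$cohort_sizes[ci]
    sheet <- simulate_sheet(n, cohort_names[ci], ci)
    female <- as.numeric(sheet$sex == "female")

    # genotypes: binomial(2, p) in HWE from the shared panel frequencies
    dos <- matrix(stats::rbinom(cfg$n_snps * n, 2L,
                                rep(snp_maf, times = n)), nrow = cfg$n_snps)
    dimnames(dos) <- list(snps$snp_id, sheet$sample_id)
    geno <- genotype_data(dos, snps)

    # design-based scale of the female coefficient for this cohort
    X <- build_design(sheet)
    w2 <- solve(crossprod(X))[2L, 2L]   # Var(beta_hat) = sigma^2 * w2
    wnorm <- sqrt(w2)

    # sex-aligned polygenic background on null CpGs -> null z SD ~ lambda
    lam <- cfg$cohort_inflation[ci]
    extra_var <- lam^2 - 1
    if (extra_var < 0) {
      warning("cohort_inflation < 1 cannot be planted; using 1")
      extra_var <- 0
    }
    bg <- stats::rnorm(n_cpgs, mean = cfg$cohort_bias[ci] * sigma * wnorm,
                       sd = sqrt(extra_var) * sigma * wnorm)
    bg[is_dmp] <- 0
    beta_c <- effect + bg

    # covariate structure (modeled downstream, so it adds realism not bias)
    covs <- cbind(ga = sheet$gestational_age - mean(sheet$gestational_age),
                  ma = sheet$maternal_age - mean(sheet$maternal_age),
                  sm = sheet$smoking - mean(sheet$smoking),
                  scale(as.matrix(sheet[, CELL_TYPES]), scale = FALSE))
    G <- matrix(stats::rnorm(n_cpgs * ncol(covs), 0, cfg$covariate_effect_sd),
                nrow = n_cpgs)
    G[, 4:9] <- G[, 4:9] * 15  # cell-type shifts are the dominant covariate

    eps <- correlated_noise(ann, n, cfg$acf_rho) * sigma
    M <- mu + outer(beta_c, female) + tcrossprod(G, covs) + eps
    if (n_planted > 0) {
      male <- 1 - female
      pl <- 1:n_planted
      # dosage is centered at its expectation so that sex-dependent
      # genotype effects do not leak a marginal sex effect into the
      # methylation truth (within-stratum meQTL slopes are unaffected)
      dosc <- dos[pl, , drop = FALSE] - 2 * snp_maf[pl]
      M[mq_cpg, ] <- M[mq_cpg, ] +
        dosc * (outer(delta_m[pl], male) + outer(delta_f[pl], female))
    }
    dimnames(M) <- list(ann$cpg_id, sheet$sample_id)
    meth <- methylation_data(M, ann[, c("cpg_id", "chrom", "pos")])
    cohorts[[ci]] <- list(meth = meth, sheet = sheet, geno = geno)
  }

  regions <- NULL
  if (length(cfg$region_spec)) {
    regions <- do.call(rbind, lapply(seq_along(cfg$region_spec), function(ri) {
      run <- which(ann$region_id == ri)
      data.frame(region_id = ri, chrom = ann$chrom[run[1L]],
                 start = min(ann$pos[run]), end = max(ann$pos[run]),
                 n_probes = length(run),
                 cpgs = paste(ann$cpg_id[run], collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }
  truth <- list(
    cpg = data.frame(cpg_id = ann$cpg_id, chrom = ann$chrom, pos = ann$pos,
                     is_dmp = is_dmp, true_effect = effect,
                     region_id = ann$region_id, stringsAsFactors = FALSE),
    regions = regions,
    meqtl = meqtl_truth)
  list(cohorts = cohorts, truth = truth, config = cfg)
}

#' Simulate a triple-tissue dataset on shared samples
#'
#' True per-tissue sex-effect vectors are drawn from a multivariate normal
#' whose correlation matrix matches `tissue_effect_corr`; all CpGs carry a
#' (mostly small) effect, modeling the continuum the cross-tissue
#' correlation analysis operates on.
#'
#' @param cfg a [sim_config()].
#' @return list with `tissues` (named list of `MethylationData`), `sheets`
#'   (per tissue), and `truth` (`effects` matrix plus realized correlations).
#' @export
simulate_tissue_set <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(derive_seed(cfg$seed, 100L))
  tc <- cfg$tissue_effect_corr
  R <- diag(3)
  dimnames(R) <- list(TISSUES, TISSUES)
  R["cvs", "placenta"] <- R["placenta", "cvs"] <- tc[["cvs_placenta"]]
  R["cvs", "cordblood"] <- R["cordblood", "cvs"] <- tc[["cvs_cordblood"]]
  R["placenta", "cordblood"] <- R["cordblood", "placenta"] <-
    tc[["placenta_cordblood"]]
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("tissue correlation matrix is not positive semi-definite")
  # PSD square root handles degenerate (perfectly correlated) targets
  L <- diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  ann <- layout_cpgs(cfg)
  n_cpgs <- cfg$n_cpgs
  effects <- (matrix(stats::rnorm(n_cpgs * 3), ncol = 3) %*% L) *
    cfg$tissue_effect_sd
  colnames(effects) <- TISSUES
  n <- cfg$n_tissue_samples
  base_sheet <- simulate_sheet(n, "tissueset", 2L)
  mu <- stats::rnorm(n_cpgs, 0, 2)
  sigma <- cfg$residual_sd * exp(stats::rnorm(n_cpgs, 0, 0.3))
  female <- as.numeric(base_sheet$sex == "female")
  tissues <- sheets <- vector("list", 3)
  names(tissues) <- names(sheets) <- TISSUES
  for (t in TISSUES) {
    sheet <- base_sheet
    sheet$tissue <- t
    if (t == "cvs") sheet$gestational_age <- stats::rnorm(n, 12.5, 1.2)
    props <- rdirichlet(n, CELL_ALPHA)
    colnames(props) <- CELL_TYPES
    sheet[, CELL_TYPES] <- props
    M <- mu + outer(effects[, t], female) +
      matrix(stats::rnorm(n_cpgs * n), nrow = n_cpgs) * sigma
    dimnames(M) <- list(ann$cpg_id, sheet$sample_id)
    tissues[[t]] <- methylation_data(M, ann[, c("cpg_id", "chrom", "pos")])
    sheets[[t]] <- sheet
  }
  list(tissues = tissues, sheets = sheets,
       truth = list(effects = effects, realized_corr = stats::cor(effects)))
}
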