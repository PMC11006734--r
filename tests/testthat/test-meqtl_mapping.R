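# Genotype QC, cis pair enumeration, association fits, pooling, and the
# sex-consistent / sex-specific classification.

# full-enumeration oracle for the HWE exact test, written independently of
# the implementation (explicit normalized probabilities over all tables)
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  na <- 2 * naa + nAa
  rare <- min(na, 2 * n - na)
  het <- seq(rare %% 2, rare, by = 2)
  pr <- sapply(het, function(h) {
    a2 <- (rare - h) / 2
    A2 <- n - h - a2
    exp(lfactorial(n) - lfactorial(A2) - lfactorial(h) - lfactorial(a2) +
          h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
          lfactorial(2 * n))
  })
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[het == nAa] * (1 + 1e-12)])
}

test_that("HWE exact test matches enumeration and closed cases", {
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  # large HWE-proportioned sample is unremarkable
  expect_gt(hwe_exact_test(360, 480, 160), 0.5)
  # random tables against the oracle
  set.seed(1)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    counts <- as.vector(rmultinom(1, n, prob = c(0.4, 0.4, 0.2)))
    expect_equal(hwe_exact_test(counts[1], counts[2], counts[3]),
                 hwe_oracle(counts[1], counts[2], counts[3]),
                 tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(0, 0, 0), "all-zero")
})

test_that("QC removes SNPs by the stated criteria in order", {
  # hand-built panel (n = 40): fail call rate, fail MAF, fail HWE, two clean
  dos <- rbind(
    cr   = c(NA, NA, rep(c(0, 1, 2, 1), length.out = 38)),  # 95% call rate
    lowm = c(rep(0, 39), 1),                  # 1 alt allele of 80 = 0.0125
    hwe  = rep(c(0, 2), each = 20),           # no hets: exact p << 1e-5
    ok1  = rep(c(0, 1, 2, 1), 10),
    ok2  = rep(c(2, 1, 0, 1), 10))
  colnames(dos) <- sprintf("S%02d", 1:40)
  snps <- data.frame(snp_id = rownames(dos), chrom = "chr1",
                     pos = c(100, 200, 300, 400, 500), ref = "A", alt = "G")
  g <- genotype_data(dos, snps)
  res <- qc_genotypes(g)
  expect_setequal(res$geno$snps$snp_id, c("ok1", "ok2"))
  expect_equal(res$removed$reason[res$removed$snp_id == "cr"], "call_rate")
  expect_equal(res$removed$reason[res$removed$snp_id == "lowm"], "maf")
  expect_equal(res$removed$reason[res$removed$snp_id == "hwe"], "hwe")
  expect_equal(sum(res$report$removed), 3L)
})

test_that("QC thresholds sit exactly at the stated boundaries", {
  # maf 0.04 removed, 3% missing removed at the 98% call-rate rule
  dos <- rbind(m04 = c(rep(0, 46), rep(1, 4)),
               mis = c(rep(NA, 2), rep(c(0, 1, 2, 1), 12)))
  colnames(dos) <- sprintf("S%02d", 1:50)
  snps <- data.frame(snp_id = rownames(dos), chrom = "1", pos = c(1, 2),
                     ref = "A", alt = "G")
  res <- qc_genotypes(genotype_data(dos, snps))
  expect_equal(res$removed$reason[res$removed$snp_id == "m04"], "maf")
  expect_equal(res$removed$reason[res$removed$snp_id == "mis"], "call_rate")
})

test_that("genotype PCs separate planted subpopulations", {
  set.seed(3)
  n1 <- 60; n2 <- 60; n_snp <- 150
  p1 <- runif(n_snp, 0.1, 0.9)
  # divergent allele frequencies in the second subpopulation
  p2 <- plogis(qlogis(p1) + rnorm(n_snp, 0, 1.5))
  dos <- cbind(matrix(rbinom(n_snp * n1, 2, rep(p1, n1)), nrow = n_snp),
               matrix(rbinom(n_snp * n2, 2, rep(p2, n2)), nrow = n_snp))
  dos <- rbind(dos, 1)  # one constant SNP must be excluded, not break PCA
  rownames(dos) <- sprintf("rs%03d", seq_len(n_snp + 1))
  colnames(dos) <- sprintf("S%03d", seq_len(n1 + n2))
  snps <- data.frame(snp_id = rownames(dos), chrom = "chr1",
                     pos = seq_len(n_snp + 1), ref = "A", alt = "G")
  g <- genotype_data(dos, snps)
  pcs <- genotype_pcs(g, 2)
  pop <- rep(c(0, 1), c(n1, n2))
  expect_gt(abs(cor(pcs[, 1], pop)), 0.9)
  # permutation equivariance (up to component sign)
  set.seed(4)
  perm <- sample(ncol(dos))
  g2 <- genotype_data(dos[, perm], snps)
  pcs2 <- genotype_pcs(g2, 2)
  expect_gt(abs(cor(pcs2[, 1], pcs[perm, 1])), 1 - 1e-8)
  expect_error(genotype_pcs(g, k = 500), "rank")
})

test_that("cis pair enumeration uses a closed 150-kb boundary", {
  cpgs <- data.frame(cpg_id = "cg1", chrom = "chr1", pos = 500000L)
  snps <- data.frame(snp_id = c("in_edge", "out_edge", "other_chr"),
                     chrom = c("chr1", "chr1", "chr2"),
                     pos = c(650000L, 650001L, 500000L))
  pairs <- map_cis_pairs(snps, cpgs)
  expect_equal(pairs$snp_id, "in_edge")
  expect_equal(pairs$distance, 150000L)
})

test_that("cis pairs match the brute-force double loop on a toy map", {
  set.seed(5)
  snps <- data.frame(snp_id = sprintf("rs%d", 1:30),
                     chrom = sample(c("chr1", "chr2"), 30, TRUE),
                     pos = sample.int(1e6, 30))
  cpgs <- data.frame(cpg_id = sprintf("cg%d", 1:20),
                     chrom = sample(c("chr1", "chr2"), 20, TRUE),
                     pos = sample.int(1e6, 20))
  w <- 120000L
  pairs <- map_cis_pairs(snps, cpgs, window = w)
  brute <- list()
  for (i in seq_len(nrow(snps))) for (j in seq_len(nrow(cpgs))) {
    if (snps$chrom[i] == cpgs$chrom[j] &&
        abs(snps$pos[i] - cpgs$pos[j]) <= w)
      brute[[length(brute) + 1]] <- paste(snps$snp_id[i], cpgs$cpg_id[j])
  }
  expect_setequal(paste(pairs$snp_id, pairs$cpg_id), unlist(brute))
})

meqtl_sim <- function() cached("meqtl_sim", {
  simulate_multi_cohort(sim_config(
    cohort_sizes = c(137L, 470L, 139L), n_cpgs = 400L, n_snps = 80L,
    frac_dmp = 0, cohort_inflation = c(1, 1, 1), acf_rho = 0,
    meqtl_spec = list(n_consistent = 25L, n_sex_specific = 10L, beta = 0.8,
                      window = 150000L),
    seed = 17L))
})

test_that("per-cohort fits recover planted meQTL effects and calibrate nulls", {
  sim <- meqtl_sim()
  co <- sim$cohorts[[2]]  # the large cohort
  st <- fit_meqtl_cohort(co$meth, co$geno, co$sheet, stratum = "all")
  truth <- sim$truth$meqtl
  key <- paste(st$snp_id, st$cpg_id)
  con <- truth[truth$class == "sex_consistent", ]
  idx <- match(paste(con$snp_id, con$cpg_id), key)
  expect_false(any(is.na(idx)))
  err <- st$beta[idx] - con$beta_male
  expect_lt(mean(abs(err)), 0.1)
  # null pairs: planted SNP-CpG combinations aside, type-I error ~ alpha
  null_idx <- setdiff(seq_along(key),
                      match(paste(truth$snp_id, truth$cpg_id), key))
  t1 <- mean(st$p[null_idx] < 0.05)
  expect_gt(t1, 0.02)
  expect_lt(t1, 0.09)
})

test_that("recoding the counted allele flips the effect sign exactly", {
  sim <- meqtl_sim()
  co <- sim$cohorts[[1]]
  st1 <- fit_meqtl_cohort(co$meth, co$geno, co$sheet, stratum = "all")
  flipped <- genotype_data(2 - co$geno$dosages, co$geno$snps)
  st2 <- fit_meqtl_cohort(co$meth, flipped, co$sheet, stratum = "all")
  key1 <- paste(st1$snp_id, st1$cpg_id)
  key2 <- paste(st2$snp_id, st2$cpg_id)
  idx <- match(key1, key2)
  expect_equal(st2$beta[idx], -st1$beta, tolerance = 1e-10)
  expect_equal(st2$p[idx], st1$p, tolerance = 1e-10)
})

test_that("pair-level meta respects the two-cohort rule and pools exactly", {
  a <- data.frame(snp_id = c("s1", "s2"), cpg_id = c("c1", "c2"),
                  distance = c(10L, 20L), beta = c(0.5, 0.3),
                  se = c(0.1, 0.1), p = 0.001, n = 100L)
  b <- data.frame(snp_id = "s1", cpg_id = "c1", distance = 10L, beta = 0.5,
                  se = 0.1, p = 0.001, n = 120L)
  m <- meta_meqtl(list(a, b), min_cohorts = 2)
  expect_equal(nrow(m), 1L)  # the pair present in one cohort only is excluded
  expect_equal(m$snp_id, "s1")
  expect_equal(m$beta, 0.5)
  expect_equal(m$se, 0.1 / sqrt(2))
})

test_that("classification follows the definitions and the lowest-p rule", {
  mk <- function(snp, cpg, beta, p) data.frame(
    snp_id = snp, cpg_id = cpg, distance = 0L, k = 2L, beta = beta,
    se = 0.1, z = beta / 0.1, p = p, Q = 0, tau2 = 0, significant = p < 1e-8,
    stringsAsFactors = FALSE)
  # case 1: overall significant, same directions -> sex-consistent
  # case 2: male-only significant, opposite female direction -> sex-specific
  # case 3: one CpG qualifying both ways -> lowest p wins (consistent here)
  all_m <- rbind(mk("s1", "c1", 0.45, 1e-10),
                 mk("s2", "c2", 0.10, 0.2),
                 mk("s3", "c3", 0.50, 1e-12),
                 mk("s4", "c3", 0.20, 1e-4))
  male_m <- rbind(mk("s1", "c1", 0.5, 1e-8),
                  mk("s2", "c2", 0.5, 1e-9),
                  mk("s3", "c3", 0.45, 1e-10),
                  mk("s4", "c3", 0.6, 1e-9))
  female_m <- rbind(mk("s1", "c1", 0.4, 1e-6),
                    mk("s2", "c2", -0.1, 0.3),
                    mk("s3", "c3", 0.5, 1e-10),
                    mk("s4", "c3", -0.2, 0.1))
  cls <- classify_sex_meqtls(all_m, male_m, female_m)
  expect_equal(cls$cpg$class[cls$cpg$cpg_id == "c1"], "sex_consistent")
  expect_equal(cls$cpg$class[cls$cpg$cpg_id == "c2"], "sex_specific")
  # c3: consistent via s3 at 1e-12 beats specific via s4 at 1e-9
  expect_equal(cls$cpg$class[cls$cpg$cpg_id == "c3"], "sex_consistent")
  expect_length(intersect(cls$consistent_cpgs, cls$specific_cpgs), 0L)
})

test_that("planted meQTL classes are recovered end to end", {
  sim <- meqtl_sim()
  strata <- c("all", "male", "female")
  metas <- lapply(strata, function(s) {
    per <- lapply(sim$cohorts, function(co)
      fit_meqtl_cohort(co$meth, co$geno, co$sheet, stratum = s))
    meta_meqtl(per)
  })
  names(metas) <- strata
  cls <- classify_sex_meqtls(metas$all, metas$male, metas$female)
  truth <- sim$truth$meqtl
  found <- cls$cpg
  hit <- merge(found, truth[, c("cpg_id", "class")], by = "cpg_id",
               suffixes = c("_called", "_true"))
  expect_gt(nrow(hit) / nrow(truth), 0.9)
  expect_gt(mean(hit$class_called == hit$class_true), 0.9)
  # classes disjoint on every run
  expect_length(intersect(cls$consistent_cpgs, cls$specific_cpgs), 0L)
  # without planted sex-specific truth, overall-significant pairs agree in
  # direction between the sexes nearly always
  sig <- metas$all$significant
  is_planted_spec <- paste(metas$all$snp_id, metas$all$cpg_id) %in%
    paste(truth$snp_id[truth$class == "sex_specific"],
          truth$cpg_id[truth$class == "sex_specific"])
  bm <- metas$male$beta[match(paste(metas$all$snp_id, metas$all$cpg_id),
                              paste(metas$male$snp_id, metas$male$cpg_id))]
  bf <- metas$female$beta[match(paste(metas$all$snp_id, metas$all$cpg_id),
                                paste(metas$female$snp_id, metas$female$cpg_id))]
  conc <- sign(bm) == sign(bf)
  expect_gt(mean(conc[sig & !is_planted_spec], na.rm = TRUE), 0.99)
})
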