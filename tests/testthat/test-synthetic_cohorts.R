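# Generator properties: determinism, planted-truth bookkeeping, HWE of
# simulated genotypes, and the tissue-set correlation structure.

test_that("generation is deterministic given the master seed", {
  cfg <- sim_config(cohort_sizes = c(30L, 40L), n_cpgs = 100L, n_snps = 20L,
                    frac_dmp = 0.1, seed = 5L)
  s1 <- simulate_multi_cohort(cfg)
  s2 <- simulate_multi_cohort(cfg)
  expect_identical(s1$cohorts[[1]]$meth$m, s2$cohorts[[1]]$meth$m)
  expect_identical(s1$cohorts[[2]]$geno$dosages, s2$cohorts[[2]]$geno$dosages)
  expect_identical(s1$truth$cpg, s2$truth$cpg)
  # a different seed changes the data
  cfg2 <- sim_config(cohort_sizes = c(30L, 40L), n_cpgs = 100L, n_snps = 20L,
                     frac_dmp = 0.1, seed = 6L)
  expect_false(identical(simulate_multi_cohort(cfg2)$cohorts[[1]]$meth$m,
                         s1$cohorts[[1]]$meth$m))
})

test_that("frac_dmp = 0 plants nothing and tiny fractions warn", {
  sim <- small_null_sim()
  expect_false(any(sim$truth$cpg$is_dmp))
  expect_true(all(sim$truth$cpg$true_effect == 0))
  cfg <- sim_config(cohort_sizes = 30L, n_cpgs = 100L, n_snps = 10L,
                    frac_dmp = 0.001, seed = 2L)
  expect_warning(simulate_multi_cohort(cfg), "zero planted effects")
})

test_that("planted effect signs follow the female-hypomethylation fraction", {
  cfg <- sim_config(cohort_sizes = 30L, n_cpgs = 1250L, n_snps = 10L,
                    frac_dmp = 0.8, hypo_female_frac = 0.85, seed = 3L)
  sim <- simulate_multi_cohort(cfg)
  eff <- sim$truth$cpg$true_effect[sim$truth$cpg$is_dmp]
  expect_length(eff, 1000L)
  # binomial(1000, 0.85): 850 +- 25 covers ~2.2 sigma
  expect_gt(sum(eff < 0), 825)
  expect_lt(sum(eff < 0), 875)
})

test_that("simulated genotypes sit in Hardy-Weinberg equilibrium", {
  cfg <- sim_config(cohort_sizes = 200L, n_cpgs = 50L, n_snps = 300L,
                    frac_dmp = 0, seed = 8L)
  sim <- simulate_multi_cohort(cfg)
  qc <- sim$cohorts[[1]]$geno$qc
  expect_gte(mean(qc$hwe_p > 1e-5), 0.99)
  expect_true(all(qc$maf <= 0.5 & qc$maf >= 0))
})

test_that("sheets validate and regions/meQTL truth are bookkept", {
  cfg <- sim_config(cohort_sizes = c(50L, 60L), n_cpgs = 400L, n_snps = 60L,
                    frac_dmp = 0.05,
                    region_spec = list(list(n_probes = 5, spacing = 50,
                                            effect = 0.6)),
                    meqtl_spec = list(n_consistent = 10, n_sex_specific = 4,
                                      beta = 0.8, window = 150000),
                    seed = 4L)
  sim <- simulate_multi_cohort(cfg)
  for (co in sim$cohorts) expect_silent(validate_sample_sheet(co$sheet))
  # every planted region probe is flagged with a shared-sign effect
  tr <- sim$truth$cpg
  run <- tr[tr$region_id == 1L, ]
  expect_equal(nrow(run), 5L)
  expect_true(all(run$is_dmp))
  expect_equal(length(unique(sign(run$true_effect))), 1L)
  expect_true(all(diff(run$pos) == 50))
  # sex-specific truth has opposite-sign effects between the sexes
  mq <- sim$truth$meqtl
  expect_equal(sum(mq$class == "sex_consistent"), 10L)
  sp <- mq[mq$class == "sex_specific", ]
  expect_true(all(sign(sp$beta_male) != sign(sp$beta_female)))
  con <- mq[mq$class == "sex_consistent", ]
  expect_true(all(con$beta_male == con$beta_female))
  # planted SNPs lie within the cis window of their CpG
  snps <- sim$cohorts[[1]]$geno$snps
  idx <- match(mq$snp_id, snps$snp_id)
  cidx <- match(mq$cpg_id, tr$cpg_id)
  expect_true(all(abs(snps$pos[idx] - tr$pos[cidx]) <= 150000))
  expect_true(all(snps$chrom[idx] == tr$chrom[cidx]))
})

test_that("tissue set reproduces the target effect correlations", {
  cfg <- sim_config(cohort_sizes = 65L, n_cpgs = 5000L, n_snps = 10L,
                    tissue_effect_corr = c(cvs_placenta = 0.55,
                                           cvs_cordblood = 0,
                                           placenta_cordblood = 0),
                    seed = 11L)
  ts <- simulate_tissue_set(cfg)
  expect_equal(cfg$n_tissue_samples, 65L)
  expect_equal(ncol(ts$tissues$placenta$m), 65L)
  r <- cor(ts$truth$effects[, "cvs"], ts$truth$effects[, "placenta"])
  # Fisher-z 95% band around 0.55 at n = 5000
  band <- tanh(atanh(0.55) + c(-1, 1) * 1.96 / sqrt(5000 - 3))
  expect_gt(r, band[1])
  expect_lt(r, band[2])
  expect_lt(abs(cor(ts$truth$effects[, "placenta"],
                    ts$truth$effects[, "cordblood"])), 0.05)

  # degenerate correlation 1 duplicates the effect vector
  cfg2 <- sim_config(cohort_sizes = 65L, n_cpgs = 500L, n_snps = 10L,
                     tissue_effect_corr = c(cvs_placenta = 1,
                                            cvs_cordblood = 0,
                                            placenta_cordblood = 0),
                     seed = 12L)
  ts2 <- simulate_tissue_set(cfg2)
  expect_equal(ts2$truth$effects[, "cvs"], ts2$truth$effects[, "placenta"],
               tolerance = 1e-6)

  # invalid correlation matrix is rejected
  cfg3 <- sim_config(cohort_sizes = 65L, n_cpgs = 100L, n_snps = 10L,
                     tissue_effect_corr = c(cvs_placenta = 0.9,
                                            cvs_cordblood = -0.9,
                                            placenta_cordblood = 0.9),
                     seed = 13L)
  expect_error(simulate_tissue_set(cfg3), "positive semi-definite")
})

test_that("null-generator z-statistics are calibrated through the EWAS", {
  sim <- small_null_sim()
  st <- run_ewas(sim$cohorts[[3]]$meth, sim$cohorts[[3]]$sheet)
  expect_gt(sd(st$z), 0.85)
  expect_lt(sd(st$z), 1.15)
})
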