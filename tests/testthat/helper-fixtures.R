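# Shared fixtures built in code. Simulations are cached per test file so
# parameterised blocks can reuse them without re-generating.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small three-cohort null simulation used by several files
small_null_sim <- function() cached("small_null", {
  simulate_multi_cohort(sim_config(
    cohort_sizes = c(150L, 160L, 140L), n_cpgs = 300L, n_snps = 40L,
    frac_dmp = 0, cohort_inflation = c(1, 1, 1), acf_rho = 0, seed = 42L))
})

# full-size null study at the published cohort sizes and inflation targets
calibration_sim <- function() cached("calibration", {
  cfg <- sim_config(n_cpgs = 5000L, n_snps = 20L, frac_dmp = 0, seed = 2024L)
  sim <- simulate_multi_cohort(cfg)
  corrected <- lapply(sim$cohorts, function(co) {
    st <- run_ewas(co$meth, co$sheet)
    fit <- fit_threecomp_mixture(st$z)
    list(stats = apply_correction(st, fit), fit = fit)
  })
  list(sim = sim, corrected = corrected, config = cfg)
})

# full-size recovery study: planted DMPs, one tight region, planted meQTLs
recovery_sim <- function() cached("recovery", {
  cfg <- sim_config(
    n_cpgs = 5000L, n_snps = 300L, frac_dmp = 0.04,
    effect_size = 0.6, effect_size_sd = 0,
    region_spec = list(list(n_probes = 5L, spacing = 50L, effect = 0.6)),
    meqtl_spec = list(n_consistent = 100L, n_sex_specific = 20L,
                      beta = 0.8, window = 150000L),
    seed = 2025L)
  sim <- simulate_multi_cohort(cfg)
  corrected <- lapply(sim$cohorts, function(co) {
    st <- run_ewas(co$meth, co$sheet)
    apply_correction(st, fit_threecomp_mixture(st$z))
  })
  meta <- run_meta(corrected)
  list(sim = sim, corrected = corrected, meta = meta, config = cfg)
})

# minimal valid sample sheet for design-matrix tests
toy_sheet <- function(n = 8L, seed = 1L) {
  set.seed(seed)
  props <- matrix(rgamma(n * 6, shape = c(2, 6, 20, 6, 2, 4)), ncol = 6,
                  byrow = TRUE)
  props <- props / rowSums(props)
  colnames(props) <- c("nRBC", "trophoblast", "syncytiotrophoblast",
                       "stromal", "Hofbauer", "endothelial")
  cbind(data.frame(
    sample_id = sprintf("S%02d", seq_len(n)), cohort = "toy",
    tissue = "placenta",
    sex = rep(c("male", "female"), length.out = n),
    gestational_age = rnorm(n, 39, 1.5), maternal_age = rnorm(n, 32, 5),
    smoking = rep(c(0L, 1L), length.out = n), stringsAsFactors = FALSE),
    as.data.frame(props))
}

# write a small single-sample-block VCF in code
write_toy_vcf <- function(path, rows, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  path
}
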