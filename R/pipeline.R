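# End-to-end orchestration: simulate (or load) -> per-cohort robust EWAS ->
# inflation correction -> random-effects meta-analysis -> DMR calling ->
# cis-meQTL mapping and classification -> enrichment -> demographics table.
# Every intermediate is written in the documented delimited formats and a
# JSON manifest records seeds, thresholds and per-stage row counts.

#' Run the full analysis pipeline on synthetic or pre-loaded cohorts
#'
#' @param config a [sim_config()] describing the synthetic study (ignored
#'   when `cohorts` is supplied).
#' @param out_dir output directory (created); intermediates and
#'   `manifest.json` are written here.
#' @param cohorts optional pre-built list as returned by
#'   [simulate_multi_cohort()], or a list whose elements are path lists
#'   `list(meth=, sheet=, geno=)` to load with the package readers; when
#'   NULL the generator runs with `config`.
#' @param covariates covariate names for the EWAS design.
#' @param sig_dmp epigenome-wide threshold (default 9e-8).
#' @param sig_meqtl cis-meQTL threshold (default 1e-8).
#' @param dmr_seed_p,dmr_extend DMR seeding threshold and extension cutoff.
#' @param cis_window cis window half-width in bp.
#' @param min_cohorts_meqtl pair availability rule for meQTL meta-analysis.
#' @param verbose print per-stage counts.
#' @return invisible list: `manifest` plus the in-memory stage results
#'   (`meta`, `dmr`, `meqtl_classes`, `enrichment`, `table1`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("pipeline"),
                         cohorts = NULL,
                         covariates = DEFAULT_COVARIATES,
                         sig_dmp = EPIGENOME_WIDE_P,
                         sig_meqtl = MEQTL_SIG_P,
                         dmr_seed_p = 0.05, dmr_extend = 200L,
                         cis_window = 150000L, min_cohorts_meqtl = 2L,
                         verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(package_version = as.character(utils::packageVersion("sexdiffmeth")),
                   thresholds = list(dmp = sig_dmp, meqtl = sig_meqtl,
                                     dmr_seed_p = dmr_seed_p,
                                     dmr_extend = dmr_extend,
                                     cis_window = cis_window),
                   counts = list())

  load_cohort <- function(paths) {
    for (p in unlist(paths)) {
      if (is.character(p) && !file.exists(p))
        stop("cohort file not found: ", p, call. = FALSE)
    }
    ann <- if (!is.null(paths$annotation))
      read_cpg_annotation(paths$annotation)
    list(meth = read_methylation_matrix(paths$meth, annotation = ann),
         sheet = read_sample_sheet(paths$sheet),
         geno = if (!is.null(paths$geno)) read_genotypes(paths$geno))
  }
  sim <- stage("simulate", {
    if (is.null(cohorts)) simulate_multi_cohort(config)
    else if (!is.null(cohorts$cohorts)) cohorts
    else list(cohorts = lapply(cohorts, function(co)
      if (is.character(co$meth)) load_cohort(co) else co), truth = NULL)
  })
  if (is.null(cohorts)) manifest$seed <- config$seed
  if (is.null(names(sim$cohorts)))
    names(sim$cohorts) <- paste0("cohort", seq_along(sim$cohorts))
  truth <- sim$truth
  if (!is.null(truth)) {
    utils::write.table(truth$cpg, file.path(out_dir, "truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  ncoh <- length(sim$cohorts)
  say("cohorts: ", ncoh)

  corrected <- list()
  fits <- list()
  for (nm in names(sim$cohorts)) {
    co <- sim$cohorts[[nm]]
    write_sample_sheet(co$sheet, file.path(out_dir, paste0(nm, "_sheet.csv")))
    st <- stage(paste0("ewas:", nm), run_ewas(co$meth, co$sheet, covariates))
    fit <- stage(paste0("correct:", nm),
                 fit_threecomp_mixture(st$z[is.finite(st$z)]))
    cs <- apply_correction(st, fit)
    write_stats_tsv(cs, file.path(out_dir, paste0(nm, "_ewas.tsv")))
    jsonlite::write_json(
      list(bias = fit$bias, inflation = fit$inflation,
           lambda_gc = attr(cs, "lambda_gc")),
      file.path(out_dir, paste0(nm, "_inflation.json")), auto_unbox = TRUE,
      digits = NA)
    say(nm, ": ", nrow(st), " CpGs tested, lambda_GC = ",
        signif(attr(cs, "lambda_gc"), 4), ", inflation = ",
        signif(fit$inflation, 4))
    corrected[[nm]] <- cs
    fits[[nm]] <- fit
    manifest$counts[[paste0("cpgs_", nm)]] <- nrow(st)
  }

  meta <- stage("meta", run_meta(corrected, sig = sig_dmp))
  write_stats_tsv(meta, file.path(out_dir, "meta.tsv"))
  manifest$counts$cpgs_meta <- nrow(meta)
  manifest$counts$dmps <- sum(meta$dmp)
  say("meta: ", nrow(meta), " CpGs, ", sum(meta$dmp), " DMPs")

  dmr <- stage("dmr", run_dmr(meta, seed_p = dmr_seed_p, extend = dmr_extend,
                              threshold = sig_dmp))
  write_regions_bed(dmr$regions, file.path(out_dir, "dmrs.bed"))
  manifest$counts$dmrs <- nrow(dmr$regions)
  say("dmr: ", nrow(dmr$candidates), " candidates, ", nrow(dmr$regions),
      " significant regions")

  meqtl_classes <- NULL
  meqtl_meta <- list()
  if (!is.null(sim$cohorts[[1L]]$geno)) {
    strata <- c("all", "male", "female")
    per_stratum <- lapply(strata, function(s) {
      lapply(sim$cohorts, function(co) {
        qc <- qc_genotypes(co$geno)
        stage(paste0("meqtl:", s),
              fit_meqtl_cohort(co$meth, qc$geno, co$sheet, stratum = s,
                               window = cis_window))
      })
    })
    names(per_stratum) <- strata
    meqtl_meta <- lapply(per_stratum, meta_meqtl,
                         min_cohorts = min_cohorts_meqtl, sig = sig_meqtl)
    utils::write.table(meqtl_meta$all, file.path(out_dir, "meqtl_all.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    meqtl_classes <- stage("classify",
                           classify_sex_meqtls(meqtl_meta$all, meqtl_meta$male,
                                               meqtl_meta$female, sig = sig_meqtl))
    utils::write.table(meqtl_classes$cpg,
                       file.path(out_dir, "meqtl_classes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$counts$meqtl_pairs_tested <- nrow(meqtl_meta$all)
    manifest$counts$meqtl_significant <- sum(meqtl_meta$all$significant)
    manifest$counts$meqtl_consistent_cpgs <-
      length(meqtl_classes$consistent_cpgs)
    manifest$counts$meqtl_specific_cpgs <- length(meqtl_classes$specific_cpgs)
    say("meqtl: ", nrow(meqtl_meta$all), " pairs, ",
        sum(meqtl_meta$all$significant), " significant; classes: ",
        length(meqtl_classes$consistent_cpgs), " consistent / ",
        length(meqtl_classes$specific_cpgs), " specific CpGs")
  }

  enr <- NULL
  if (!is.null(meqtl_classes) && sum(meta$dmp) > 0) {
    enr <- stage("enrich", meqtl_overlap_enrichment(
      meta$cpg[meta$dmp],
      unique(meqtl_classes$cpg$cpg_id[meqtl_classes$cpg$class == "sex_consistent"]),
      meta$cpg))
    manifest$counts$dmp_meqtl_overlap <- enr$a
    say("enrichment: OR = ", signif(enr$odds_ratio, 4))
  }

  tab1 <- stage("table1", build_table1(lapply(sim$cohorts, `[[`, "sheet")))
  utils::write.table(tab1, file.path(out_dir, "table1.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, corrected = corrected, fits = fits,
                 meta = meta, dmr = dmr, meqtl_meta = meqtl_meta,
                 meqtl_classes = meqtl_classes, enrichment = enr,
                 table1 = tab1, truth = truth, out_dir = out_dir))
}
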