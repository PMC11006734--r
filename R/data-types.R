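# Controlled vocabularies used across the pipeline
ISLAND_LEVELS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")
CONTEXT_LEVELS <- c("Promoter", "5UTR", "Exon", "Intron", "3UTR", "Downstream",
                    "DistalIntergenic")
CELL_TYPES <- c("nRBC", "trophoblast", "syncytiotrophoblast", "stromal",
                "Hofbauer", "endothelial")
TISSUES <- c("cvs", "placenta", "cordblood")

#' Construct a MethylationData object
#'
#' Container for an M-value matrix (CpGs in rows, samples in columns — the
#' layout of the on-disk matrix) together with per-CpG annotation.
#'
#' @param m numeric matrix, CpGs x samples, finite M-values.
#' @param annotation data.frame with columns `cpg_id`, `chrom`, `pos` and
#'   optionally `island_relation`, `nearest_gene`, `genic_context`. Row order
#'   must match the rows of `m`.
#' @return An object of class `MethylationData`: a list with elements
#'   `m` (matrix), `annotation` (data.frame), `samples`, `cpg_ids`.
#' @export
methylation_data <- function(m, annotation) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("M-value matrix must be numeric")
  if (any(!is.finite(m))) stop("M-value matrix contains non-finite values")
  annotation <- validate_cpg_annotation(annotation)
  if (nrow(annotation) != nrow(m))
    stop("annotation rows (", nrow(annotation), ") != matrix rows (", nrow(m), ")")
  if (is.null(rownames(m))) rownames(m) <- annotation$cpg_id
  if (!identical(rownames(m), annotation$cpg_id))
    stop("matrix rownames disagree with annotation cpg ids")
  if (is.null(colnames(m)))
    stop("M-value matrix must carry sample ids as column names")
  structure(
    list(m = m, annotation = annotation,
         samples = colnames(m), cpg_ids = annotation$cpg_id),
    class = "MethylationData")
}

#' @export
print.MethylationData <- function(x, ...) {
  cat("MethylationData:", nrow(x$m), "CpGs x", ncol(x$m), "samples\n")
  cat("  chromosomes:", paste(unique(x$annotation$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.MethylationData <- function(x) dim(x$m)

validate_cpg_annotation <- function(ann) {
  ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  need <- c("cpg_id", "chrom", "pos")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  dup <- ann$cpg_id[duplicated(ann$cpg_id)]
  if (length(dup)) stop("duplicated cpg id: ", dup[1L])
  if (any(ann$pos < 1)) stop("CpG positions must be >= 1 (1-based)")
  if ("island_relation" %in% names(ann)) {
    bad <- setdiff(unique(ann$island_relation), c(ISLAND_LEVELS, NA, ""))
    if (length(bad)) stop("unknown island_relation level: ", bad[1L])
  } else {
    ann$island_relation <- NA_character_
  }
  if (!"nearest_gene" %in% names(ann)) ann$nearest_gene <- NA_character_
  if ("genic_context" %in% names(ann)) {
    bad <- setdiff(unique(ann$genic_context), c(CONTEXT_LEVELS, NA, ""))
    if (length(bad)) stop("unknown genic_context level: ", bad[1L])
  } else {
    ann$genic_context <- NA_character_
  }
  ann$pos <- as.integer(ann$pos)
  rownames(ann) <- NULL
  ann
}

#' Validate a sample sheet
#'
#' A sample sheet is a plain data.frame with one row per sample and columns
#' `sample_id`, `cohort`, `tissue` (cvs/placenta/cordblood), `sex`
#' (male/female), `gestational_age` (weeks), `maternal_age` (years),
#' `smoking` (0/1 or logical) and one column per placental cell type
#' (nRBC, trophoblast, syncytiotrophoblast, stromal, Hofbauer, endothelial),
#' nonnegative and summing to 1 per sample.
#'
#' @param sheet data.frame to validate.
#' @param tol tolerance on the cell-proportion sum (default 1e-6).
#' @return The validated (type-normalised) data.frame, invisibly classed.
#' @export
validate_sample_sheet <- function(sheet, tol = 1e-6) {
  sheet <- as.data.frame(sheet, stringsAsFactors = FALSE)
  need <- c("sample_id", "cohort", "tissue", "sex", "gestational_age",
            "maternal_age", "smoking", CELL_TYPES)
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicated sample ids in sheet")
  if (!all(sheet$sex %in% c("male", "female")))
    stop("sex must be coded male/female")
  if (!all(sheet$tissue %in% TISSUES))
    stop("tissue must be one of ", paste(TISSUES, collapse = "/"))
  sheet$smoking <- as.integer(as.logical(sheet$smoking))
  props <- as.matrix(sheet[, CELL_TYPES])
  if (any(props < 0)) stop("cell proportions must be nonnegative")
  s <- rowSums(props)
  if (any(abs(s - 1) > tol))
    stop("cell proportions must sum to 1 (max deviation ",
         format(max(abs(s - 1))), ")")
  sheet
}

#' Construct a GenotypeData object
#'
#' @param dosages integer/numeric matrix, SNPs x samples, entries 0/1/2 or NA.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`.
#' @return Object of class `GenotypeData` with per-SNP QC metrics
#'   (`call_rate`, `maf`, `hwe_p`) computed on construction.
#' @export
genotype_data <- function(dosages, snps) {
  dosages <- as.matrix(dosages)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(snps))
  if (length(miss)) stop("snp table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(snps) != nrow(dosages)) stop("snp table / dosage matrix row mismatch")
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or missing")
  if (anyDuplicated(snps$snp_id)) stop("duplicated snp ids")
  if (is.null(rownames(dosages))) rownames(dosages) <- snps$snp_id
  if (is.null(colnames(dosages))) stop("dosage matrix must carry sample ids")
  qc <- compute_genotype_qc(dosages)
  structure(
    list(dosages = dosages, snps = snps, samples = colnames(dosages), qc = qc),
    class = "GenotypeData")
}

#' @export
print.GenotypeData <- function(x, ...) {
  cat("GenotypeData:", nrow(x$dosages), "SNPs x", ncol(x$dosages), "samples\n")
  invisible(x)
}

# call rate, MAF (from non-missing dosages) and HWE exact p per SNP
compute_genotype_qc <- function(dosages) {
  n <- ncol(dosages)
  nm <- rowSums(!is.na(dosages))
  call_rate <- nm / n
  alt <- rowSums(dosages, na.rm = TRUE)
  af <- ifelse(nm > 0, alt / (2 * nm), NA_real_)
  maf <- pmin(af, 1 - af)
  n_het <- rowSums(dosages == 1, na.rm = TRUE)
  n_hom_alt <- rowSums(dosages == 2, na.rm = TRUE)
  n_hom_ref <- nm - n_het - n_hom_alt
  hwe_p <- vapply(seq_len(nrow(dosages)), function(i) {
    if (nm[i] == 0) return(NA_real_)
    hwe_exact_test(n_hom_ref[i], n_het[i], n_hom_alt[i])
  }, numeric(1))
  data.frame(snp_id = rownames(dosages), call_rate = call_rate, maf = maf,
             hwe_p = hwe_p, stringsAsFactors = FALSE, row.names = NULL)
}

#' Convert M-values to beta-values and back
#'
#' The standard array identities: beta = 2^M / (2^M + 1) (methylated
#' proportion, strictly inside (0,1)) and M = log2(beta / (1 - beta)).
#'
#' @param m numeric vector of M-values.
#' @return `m_to_beta`: beta-values in (0,1).
#' @export
m_to_beta <- function(m) {
  if (any(!is.finite(m))) stop("M-values must be finite")
  # computed via plogis for numerical stability at large |M|
  stats::plogis(m * log(2))
}

#' @rdname m_to_beta
#' @param beta numeric vector of beta-values, strictly in (0,1).
#' @return `beta_to_m`: M-values.
#' @export
beta_to_m <- function(beta) {
  if (any(!is.finite(beta)) || any(beta <= 0) || any(beta >= 1))
    stop("beta-values must lie strictly in (0,1)")
  log2(beta / (1 - beta))
}
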