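# Readers and writers for the delimited formats the pipeline consumes:
# methylation matrix TSV (row = CpG, header = sample ids), sample sheet CSV,
# genotype dosage TSV or VCF, CpG annotation TSV, gene models BED.

#' Read a methylation M-value matrix
#'
#' Tab-delimited, one row per CpG: first column the CpG id, remaining columns
#' numeric M-values under a header of sample ids. Non-numeric cells, NA cells,
#' duplicated CpG ids and ragged rows are rejected.
#'
#' @param path file path.
#' @param annotation optional CpG annotation data.frame (cpg_id/chrom/pos...);
#'   if omitted, placeholder coordinates are attached (chrom "chrUn", pos by
#'   file order) so that purely per-site operations still run.
#' @return A [methylation_data()] object.
#' @export
read_methylation_matrix <- function(path, annotation = NULL) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) stop("methylation matrix needs >= 1 sample column")
  samples <- header[-1L]
  lines <- readLines(path)[-1L]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(header))
  if (length(bad))
    stop("ragged row at line ", bad[1L] + 1L, ": expected ", length(header),
         " fields, found ", nf[bad[1L]])
  ids <- vapply(fields, `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicated cpg id: ", dup[1L])
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(samples),
              dimnames = list(ids, samples))
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]][-1L]))
    if (any(is.na(v)))
      stop("non-numeric or missing M-value at line ", i + 1L, " (cpg ", ids[i], ")")
    m[i, ] <- v
  }
  if (is.null(annotation)) {
    annotation <- data.frame(cpg_id = ids, chrom = "chrUn",
                             pos = seq_along(ids), stringsAsFactors = FALSE)
  } else {
    annotation <- validate_cpg_annotation(annotation)
    idx <- match(ids, annotation$cpg_id)
    if (any(is.na(idx)))
      stop("annotation lacks cpg id: ", ids[which(is.na(idx))[1L]])
    annotation <- annotation[idx, , drop = FALSE]
    rownames(annotation) <- NULL
  }
  methylation_data(m, annotation)
}

#' Write a methylation matrix
#'
#' Inverse of [read_methylation_matrix()]; values are written at full
#' precision (17 significant digits) so round-trips are lossless.
#'
#' @param meth a `MethylationData` object.
#' @param path output path.
#' @export
write_methylation_matrix <- function(meth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("cpg_id", meth$samples), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(meth$m)), function(i) {
    paste(c(meth$cpg_ids[i], format(meth$m[i, ], digits = 17, trim = TRUE,
                                    scientific = FALSE)), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' CSV with the exact column names documented in [validate_sample_sheet()].
#' @param path file path.
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_sample_sheet
#' @param sheet sample sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read CpG annotation from TSV
#'
#' Columns: cpg_id, chrom, pos, and optionally island_relation, nearest_gene,
#' genic_context (the six-level island vocabulary is enforced).
#' @param path file path.
#' @export
read_cpg_annotation <- function(path) {
  validate_cpg_annotation(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_cpg_annotation
#' @param ann annotation data.frame.
#' @export
write_cpg_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genotypes from VCF or dosage TSV
#'
#' For VCF input, GT fields "0/0", "0/1", "1/1" (or phased "|") map to
#' dosages 0/1/2 and "./." to missing; multi-allelic records are skipped with
#' a message giving the count; any other GT is an error. For TSV input the
#' documented dialect is tab-delimited with columns snp_id, chrom, pos, ref,
#' alt, then one numeric column per sample (0/1/2/NA).
#'
#' QC metrics (call rate, MAF from non-missing dosages, exact HWE p) are
#' computed on load.
#'
#' @param path file path, `.vcf` (optionally gzipped) or `.tsv`.
#' @return A [genotype_data()] object.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) read_genotypes_vcf(path)
  else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    message("skipping ", sum(multi), " multi-allelic record(s)")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  code <- function(g) {
    g[is.na(g)] <- "./."
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_real_, length(g))
    out[g == "0/0"] <- 0
    out[g == "0/1" | g == "1/0"] <- 1
    out[g == "1/1"] <- 2
    bad <- !(g %in% c("0/0", "0/1", "1/0", "1/1", "./."))
    if (any(bad)) stop("malformed GT field: ", g[which(bad)[1L]])
    out
  }
  dos <- apply(gt, 2, code)
  dim(dos) <- dim(gt)
  dimnames(dos) <- dimnames(gt)
  ids <- fix$ID
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix$CHROM[noid], ":", fix$POS[noid])
  snps <- data.frame(snp_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  rownames(dos) <- ids
  genotype_data(dos, snps)
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("snp_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(meta_cols, names(tab))
  if (length(miss)) stop("dosage file lacks columns: ", paste(miss, collapse = ", "))
  dos <- as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE])
  rownames(dos) <- tab$snp_id
  genotype_data(dos, tab[, meta_cols])
}

#' @rdname read_genotypes
#' @param geno a `GenotypeData` object.
#' @export
write_genotypes_tsv <- function(geno, path) {
  out <- cbind(geno$snps, as.data.frame(geno$dosages, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene models from BED
#'
#' BED6 gives gene intervals (for nearest-gene mapping); BED12 additionally
#' carries exon blocks and the CDS (thick) interval used to derive UTRs for
#' genic-context annotation. Import is delegated to rtracklayer; BED's
#' 0-based half-open coordinates become 1-based closed on load.
#'
#' @param path BED file path.
#' @return A `GRanges` with `name` metadata (and `blocks`/`thick` for BED12).
#' @export
read_gene_models <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write DMR regions as BED
#'
#' 0-based half-open output with name, score (-log10 sidak p) and the two
#' region-level p-values as extra columns.
#' @param regions data.frame of DMR calls (see [call_regions()]).
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,  # to 0-based half-open
                    end = regions$end,
                    name = sprintf("DMR_%d", seq_len(nrow(regions))),
                    n_probes = regions$n_probes,
                    slk_p = signif(regions$slk_p, 8),
                    sidak_p = signif(regions$sidak_p, 8))
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
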