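# Nearest-gene mapping, genic-context annotation, and two-sided Fisher
# enrichment of DMP sets against the tested-but-not-significant background.

#' Map CpGs to their nearest gene
#'
#' Distance 0 if the CpG lies inside a gene interval, else the minimal gap
#' to the nearest interval on the same chromosome. Ties are broken to the
#' gene with the smaller start, then lexicographically by name.
#'
#' @param cpg_ann CpG annotation data.frame (cpg_id, chrom, pos).
#' @param genes `GRanges` of gene intervals with `name` metadata (BED6 via
#'   [read_gene_models()]), or a data.frame with chrom/start/end/name
#'   (1-based closed).
#' @return data.frame: cpg_id, nearest_gene, distance (NA if no gene on any
#'   chromosome).
#' @export
nearest_gene <- function(cpg_ann, genes) {
  gtab <- as_gene_table(genes)
  out <- data.frame(cpg_id = cpg_ann$cpg_id, nearest_gene = NA_character_,
                    distance = NA_integer_, stringsAsFactors = FALSE)
  if (nrow(gtab) == 0) return(out)
  # deterministic tie-break order: distance, then start, then name
  for (i in seq_len(nrow(cpg_ann))) {
    g <- gtab[gtab$chrom == cpg_ann$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    p <- cpg_ann$pos[i]
    d <- ifelse(p >= g$start & p <= g$end, 0L,
                pmin(abs(p - g$start), abs(p - g$end)))
    o <- order(d, g$start, g$name)[1L]
    out$nearest_gene[i] <- g$name[o]
    out$distance[i] <- d[o]
  }
  out
}

as_gene_table <- function(genes) {
  if (inherits(genes, "GRanges")) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(genes)),
               start = GenomicRanges::start(genes),
               end = GenomicRanges::end(genes),
               name = if (!is.null(genes$name)) genes$name
                      else paste0("gene", seq_along(genes)),
               strand = as.character(GenomicRanges::strand(genes)),
               stringsAsFactors = FALSE)
  } else {
    g <- as.data.frame(genes, stringsAsFactors = FALSE)
    if (!"strand" %in% names(g)) g$strand <- "+"
    g
  }
}

#' Annotate CpGs with genic context
#'
#' Priority annotation in the ChIPseeker style: Promoter (TSS -3000..+3000,
#' strand-aware) > 5UTR > Exon > Intron > 3UTR > Downstream (within 3000 bp
#' past the gene end) > DistalIntergenic. UTR and exon/intron resolution
#' needs BED12 input (exon blocks + CDS thick interval); with plain BED6
#' genes the genic levels collapse to Exon.
#'
#' @param cpg_ann CpG annotation data.frame (cpg_id, chrom, pos).
#' @param genes `GRanges` from [read_gene_models()] (BED6 or BED12).
#' @param promoter_bp promoter radius around the TSS (default 3000).
#' @param downstream_bp downstream extent past the gene end (default 3000).
#' @return character vector of genic_context labels aligned to `cpg_ann`.
#' @export
annotate_context <- function(cpg_ann, genes, promoter_bp = 3000L,
                             downstream_bp = 3000L) {
  gtab <- as_gene_table(genes)
  has_blocks <- inherits(genes, "GRanges") && !is.null(genes$blocks)
  has_thick <- inherits(genes, "GRanges") && !is.null(genes$thick)
  blocks <- if (has_blocks) genes$blocks else NULL
  thick <- if (has_thick) as.data.frame(genes$thick) else NULL
  labels <- rep("DistalIntergenic", nrow(cpg_ann))
  prio <- match(labels, CONTEXT_LEVELS)
  assign_if_better <- function(i, label) {
    p <- match(label, CONTEXT_LEVELS)
    if (p < prio[i]) { labels[i] <<- label; prio[i] <<- p }
  }
  for (i in seq_len(nrow(cpg_ann))) {
    p <- cpg_ann$pos[i]
    gs <- which(gtab$chrom == cpg_ann$chrom[i])
    for (gi in gs) {
      st <- gtab$start[gi]; en <- gtab$end[gi]
      minus <- identical(gtab$strand[gi], "-")
      tss <- if (minus) en else st
      tend <- if (minus) st else en
      if (abs(p - tss) <= promoter_bp) assign_if_better(i, "Promoter")
      if (p >= st && p <= en) {
        # inside the gene: exon vs intron vs UTRs
        in_exon <- TRUE
        if (has_blocks) {
          bl <- as.data.frame(blocks[[gi]])
          ex_start <- st + bl$start - 1L
          ex_end <- st + bl$end - 1L
          in_exon <- any(p >= ex_start & p <= ex_end)
        }
        lab <- if (!in_exon) "Intron" else "Exon"
        if (in_exon && has_thick && thick$width[gi] > 0) {
          cs <- thick$start[gi]; ce <- thick$end[gi]
          if (p < cs) lab <- if (minus) "3UTR" else "5UTR"
          else if (p > ce) lab <- if (minus) "5UTR" else "3UTR"
        }
        assign_if_better(i, lab)
      } else {
        past_end <- if (minus) (tend - p) else (p - tend)
        if (past_end > 0 && past_end <= downstream_bp)
          assign_if_better(i, "Downstream")
      }
    }
  }
  labels
}

#' Two-sided Fisher test on a 2x2 table
#'
#' Counts: `a` foreground with the feature, `b` foreground without, `c`
#' background with, `d` background without. The odds ratio is the sample
#' odds ratio ad/bc (so printed enrichment tables reproduce exactly); the
#' two-sided p is the conditional hypergeometric sum of all tables with the
#' observed margins whose point probability does not exceed the observed
#' one, computed in log space.
#'
#' @param a,b,c,d nonnegative integer counts.
#' @return list of class `Fisher2x2`: `a`,`b`,`c`,`d`, `odds_ratio`
#'   (Inf-flagged when b*c = 0), `p`.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  or <- if (b * c == 0) Inf else (a * d) / (b * c)
  m <- a + b          # foreground size
  k <- a + c          # feature-positive margin
  n_tot <- a + b + c + d
  if (m == 0 || k == 0 || m == n_tot || k == n_tot) {
    p <- 1
  } else {
    lo <- max(0L, k - (n_tot - m))
    hi <- min(k, m)
    x <- lo:hi
    logp <- stats::dhyper(x, m, n_tot - m, k, log = TRUE)
    obs <- logp[x == a]
    p <- sum(exp(logp[logp <= obs + 1e-7]))
    p <- min(p, 1)
  }
  structure(list(a = a, b = b, c = c, d = d, odds_ratio = or, p = p),
            class = "Fisher2x2")
}

#' @export
print.Fisher2x2 <- function(x, ...) {
  cat("Fisher 2x2: OR =", signif(x$odds_ratio, 4), " p =", signif(x$p, 4), "\n")
  invisible(x)
}

#' Fisher enrichment of a CpG set for a feature
#'
#' Builds the 2x2 of foreground/background against a logical feature and
#' delegates to [fisher_2x2()]. Foreground and background must be disjoint.
#'
#' @param foreground,background character vectors of CpG ids (disjoint).
#' @param feature named logical vector (or character vector of
#'   feature-positive CpG ids).
#' @return `Fisher2x2`.
#' @export
fisher_enrichment <- function(foreground, background, feature) {
  if (length(intersect(foreground, background)))
    stop("foreground and background must be disjoint")
  has <- function(ids) {
    if (is.logical(feature)) {
      v <- feature[ids]
      v[is.na(v)] <- FALSE
      v
    } else ids %in% feature
  }
  fg <- has(foreground)
  bg <- has(background)
  fisher_2x2(sum(fg), sum(!fg), sum(bg), sum(!bg))
}

#' Enrichment of DMPs for meQTL-involved CpGs
#'
#' Background is the tested CpGs minus the DMPs (the
#' tested-but-not-significant set); the feature is membership in the meQTL
#' CpG set.
#'
#' @param dmps character vector of significant CpG ids.
#' @param meqtl_cpgs CpG ids involved in (sex-consistent) meQTLs.
#' @param tested_cpgs all CpG ids tested in the meta-analysis.
#' @return `Fisher2x2`.
#' @export
meqtl_overlap_enrichment <- function(dmps, meqtl_cpgs, tested_cpgs) {
  background <- setdiff(tested_cpgs, dmps)
  fisher_enrichment(dmps, background, meqtl_cpgs)
}

#' Enrichment table over annotation categories
#'
#' Runs [fisher_enrichment()] for every level of an annotation column
#' (island relation or genic context) of the tested CpGs.
#'
#' @param meta `MetaStats` with a `dmp` column.
#' @param ann CpG annotation with the `column` filled in.
#' @param column `"island_relation"` or `"genic_context"`.
#' @return data.frame: feature, a, b, c, d, odds_ratio, p.
#' @export
enrichment_by_category <- function(meta, ann,
                                   column = c("island_relation",
                                              "genic_context")) {
  column <- match.arg(column)
  lab <- ann[[column]][match(meta$cpg, ann$cpg_id)]
  fg <- meta$cpg[meta$dmp]
  bg <- meta$cpg[!meta$dmp]
  lv <- if (column == "island_relation") ISLAND_LEVELS else CONTEXT_LEVELS
  lv <- intersect(lv, unique(lab))
  rows <- lapply(lv, function(l) {
    feat <- meta$cpg[which(lab == l)]
    f <- fisher_enrichment(fg, bg, feat)
    data.frame(feature = l, a = f$a, b = f$b, c = f$c, d = f$d,
               odds_ratio = f$odds_ratio, p = f$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
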