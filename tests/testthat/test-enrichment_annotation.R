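# Nearest-gene mapping, genic-context priority annotation, and the Fisher
# enrichment machinery.

test_that("nearest gene honors distance-0 overlap and tie-breaks", {
  genes <- data.frame(chrom = "chr1", start = c(1000L, 5000L),
                      end = c(2000L, 6000L), name = c("GENE_A", "GENE_B"),
                      strand = "+")
  cpgs <- data.frame(cpg_id = c("inside", "tie"), chrom = "chr1",
                     pos = c(1500L, 3500L))
  ng <- nearest_gene(cpgs, genes)
  expect_equal(ng$nearest_gene[1], "GENE_A")
  expect_equal(ng$distance[1], 0L)
  # equidistant (1500 bp to each end): smaller start wins
  expect_equal(ng$nearest_gene[2], "GENE_A")
  expect_equal(ng$distance[2], 1500L)
})

test_that("nearest gene equals the brute-force all-pairs minimum", {
  set.seed(2)
  genes <- data.frame(chrom = sample(c("chr1", "chr2"), 20, TRUE),
                      start = sample.int(1e6, 20))
  genes$end <- genes$start + sample(500:5000, 20)
  genes$name <- sprintf("G%02d", 1:20)
  genes$strand <- sample(c("+", "-"), 20, TRUE)
  cpgs <- data.frame(cpg_id = sprintf("cg%02d", 1:30),
                     chrom = sample(c("chr1", "chr2"), 30, TRUE),
                     pos = sample.int(1e6, 30))
  ng <- nearest_gene(cpgs, genes)
  for (i in seq_len(nrow(cpgs))) {
    g <- genes[genes$chrom == cpgs$chrom[i], ]
    d <- pmax(g$start - cpgs$pos[i], cpgs$pos[i] - g$end, 0)
    expect_equal(ng$distance[i], min(d))
  }
})

test_that("genic context follows the priority ordering", {
  # BED12 written in code: gene on +, two exons, CDS inside; gene on -
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    paste(c("chr1", 10000, 30000, "PLUS", 0, "+", 14000, 29000, 0, 2,
            "8000,2000", "0,18000"), collapse = "\t"),
    paste(c("chr1", 50000, 60000, "MINUS", 0, "-", 52000, 58000, 0, 1,
            "10000", "0"), collapse = "\t")), bed)
  genes <- read_gene_models(bed)
  cpgs <- data.frame(
    cpg_id = c("prom_up", "utr5", "exon_cds", "intron", "utr3",
               "downstream", "distal", "prom_minus", "genic_prom"),
    chrom = "chr1",
    pos = c(9500L,    # 500 bp upstream of + TSS -> Promoter
            13600L,   # first exon, before CDS start, > 3 kb past TSS -> 5UTR
            16000L,   # inside CDS within the first exon -> Exon
            20000L,   # between exons -> Intron
            29500L,   # last exon past the CDS end -> 3UTR
            31000L,   # 1 kb past + gene end -> Downstream
            40000L,   # nowhere near -> DistalIntergenic
            60500L,   # 500 bp beyond - gene end = upstream of - TSS
            12500L))  # genic but within 3 kb of the + TSS -> Promoter
  ctx <- annotate_context(cpgs, genes)
  names(ctx) <- cpgs$cpg_id
  expect_equal(unname(ctx["prom_up"]), "Promoter")
  expect_equal(unname(ctx["utr5"]), "5UTR")
  expect_equal(unname(ctx["exon_cds"]), "Exon")
  expect_equal(unname(ctx["intron"]), "Intron")
  expect_equal(unname(ctx["utr3"]), "3UTR")
  expect_equal(unname(ctx["downstream"]), "Downstream")
  expect_equal(unname(ctx["distal"]), "DistalIntergenic")
  expect_equal(unname(ctx["prom_minus"]), "Promoter")
  expect_equal(unname(ctx["genic_prom"]), "Promoter")  # priority rule
})

test_that("context labels match an independent rule-by-rule oracle", {
  set.seed(3)
  genes_df <- data.frame(chrom = "chr1",
                         start = seq(10000, by = 30000, length.out = 8))
  genes_df$end <- genes_df$start + 12000
  genes_df$name <- sprintf("G%d", 1:8)
  genes_df$strand <- rep(c("+", "-"), 4)
  cpgs <- data.frame(cpg_id = sprintf("cg%03d", 1:100), chrom = "chr1",
                     pos = sample.int(260000, 100) + 1L)
  ctx <- annotate_context(cpgs, genes_df)  # BED6-style: genic = Exon
  oracle <- vapply(seq_len(nrow(cpgs)), function(i) {
    p <- cpgs$pos[i]
    lab <- "DistalIntergenic"
    best <- 8L
    for (j in seq_len(nrow(genes_df))) {
      tss <- if (genes_df$strand[j] == "-") genes_df$end[j] else genes_df$start[j]
      tend <- if (genes_df$strand[j] == "-") genes_df$start[j] else genes_df$end[j]
      cand <- character(0)
      if (abs(p - tss) <= 3000) cand <- c(cand, "Promoter")
      if (p >= genes_df$start[j] && p <= genes_df$end[j]) cand <- c(cand, "Exon")
      dpast <- if (genes_df$strand[j] == "-") tend - p else p - tend
      if (dpast > 0 && dpast <= 3000) cand <- c(cand, "Downstream")
      for (cc in cand) {
        r <- match(cc, c("Promoter", "5UTR", "Exon", "Intron", "3UTR",
                         "Downstream", "DistalIntergenic"))
        if (r < best) { best <- r; lab <- cc }
      }
    }
    lab
  }, character(1))
  expect_equal(ctx, oracle)
})

test_that("Fisher 2x2 reproduces printed, trivial and enumerated cases", {
  # reconstructed enrichment table: 2162 of 10320 DMPs in 70848 meQTL CpGs
  # against a 747781-CpG background
  f <- fisher_2x2(2162, 10320 - 2162, 70848 - 2162, 747781 - (70848 - 2162))
  expect_equal(round(f$odds_ratio, 2), 2.62)
  expect_lt(f$p, 1e-200)

  f2 <- fisher_2x2(10, 10, 10, 10)
  expect_equal(f2$odds_ratio, 1)
  expect_equal(f2$p, 1)

  f3 <- fisher_2x2(3, 1, 1, 3)
  expect_equal(f3$odds_ratio, 9)
  expect_equal(f3$p, 34 / 70, tolerance = 1e-12)

  f4 <- fisher_2x2(0, 10, 0, 10)  # zero margin
  expect_equal(f4$p, 1)
  expect_true(is.infinite(fisher_2x2(2, 0, 3, 5)$odds_ratio))
})

test_that("two-sided p equals the reference exact test on small tables", {
  set.seed(4)
  for (i in 1:200) {
    n <- sample(8:200, 1)
    a <- sample(0:min(n, 40), 1)
    rest <- n - a
    b <- sample(0:rest, 1); rest <- rest - b
    cc <- sample(0:rest, 1); d <- rest - cc
    if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) next
    mine <- fisher_2x2(a, b, cc, d)$p
    ref <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("enrichment wrappers build the right tables", {
  expect_error(fisher_enrichment(c("a", "b"), c("b", "c"), "a"), "disjoint")
  res <- meqtl_overlap_enrichment(dmps = c("a", "b"),
                                  meqtl_cpgs = c("x", "y"),
                                  tested_cpgs = c("a", "b", "x", "y", "z"))
  expect_equal(res$a, 0)
  expect_equal(res$odds_ratio, 0)

  # simulated 3x enrichment: feature prevalence 0.1 in background with
  # odds scaled by 3 in the foreground
  set.seed(5)
  bg <- sprintf("b%05d", 1:40000)
  fg <- sprintf("f%04d", 1:4000)
  feat <- c(bg[runif(40000) < 0.10], fg[runif(4000) < 0.25])
  f <- fisher_enrichment(fg, bg, feat)
  # expected OR = (0.25/0.75)/(0.1/0.9) = 3
  expect_gt(f$odds_ratio, 2.5)
  expect_lt(f$odds_ratio, 3.5)
})

test_that("random foregrounds give uniform enrichment p-values", {
  set.seed(6)
  universe <- sprintf("u%04d", 1:500)
  feat <- universe[1:100]
  ps <- replicate(400, {
    fg <- sample(universe, 60)
    bg <- setdiff(universe, fg)
    fisher_enrichment(fg, bg, feat)$p
  })
  # the exact-test p is discrete and conservative; check rejection rates
  # at two levels rather than a continuous-uniform KS
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.08)
  expect_gt(mean(ps < 0.25), 0.12)
  expect_lt(mean(ps < 0.25), 0.30)
})

test_that("category enrichment table covers observed levels", {
  set.seed(7)
  n <- 2000
  ann <- data.frame(cpg_id = sprintf("c%04d", 1:n), chrom = "chr1",
                    pos = 1:n,
                    island_relation = sample(c("Island", "OpenSea", "N_Shore"),
                                             n, TRUE, prob = c(0.3, 0.5, 0.2)))
  meta <- data.frame(cpg = ann$cpg_id, dmp = FALSE)
  # plant OpenSea enrichment among DMPs
  opensea <- which(ann$island_relation == "OpenSea")
  meta$dmp[sample(opensea, 150)] <- TRUE
  meta$dmp[sample(which(!meta$dmp), 50)] <- TRUE
  tab <- enrichment_by_category(meta, ann, "island_relation")
  expect_setequal(tab$feature, c("Island", "N_Shore", "OpenSea"))
  os <- tab[tab$feature == "OpenSea", ]
  expect_gt(os$odds_ratio, 1.5)
  expect_lt(os$p, 0.01)
})
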