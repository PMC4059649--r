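make_genes <- function(contig, start, end, strand = "+", id = NULL) {
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end),
                               strand = rep_len(strand, length(start)))
  gr$feature_id <- id %||% sprintf("g%02d", seq_along(gr))
  gr$role <- "gene_model"
  gr
}
make_lincs <- function(contig, start, end, id = NULL) {
  gr <- GenomicRanges::GRanges(rep_len(contig, length(start)),
                               IRanges::IRanges(start, end))
  gr$tu_id <- id %||% sprintf("linc%02d", seq_along(gr))
  gr
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("nearest flanking genes and edge-to-edge gaps are assigned", {
  genes <- make_genes("c1", c(1000, 5000), c(2000, 6000),
                      strand = c("+", "-"), id = c("g1", "g2"))
  linc <- make_lincs("c1", 3000, 3500)
  a <- assignApcGenes(linc, genes)
  expect_equal(a$upstream_gene, "g1")
  expect_equal(a$upstream_distance, 999L)
  expect_equal(a$downstream_gene, "g2")
  expect_equal(a$downstream_distance, 1499L)
})

test_that("a lincRNA at a contig end has no flanking gene on that side", {
  genes <- make_genes("c1", 5000, 6000, id = "g1")
  a <- assignApcGenes(make_lincs("c1", 100, 400), genes)
  expect_true(is.na(a$upstream_gene))
  expect_equal(a$downstream_gene, "g1")
})

test_that("bookended gene and lincRNA have distance zero", {
  genes <- make_genes("c1", 1000, 2000, id = "g1")
  a <- assignApcGenes(make_lincs("c1", 2001, 2400), genes)
  expect_true(is.na(a$downstream_gene))
  expect_equal(a$upstream_gene, "g1")
  expect_equal(a$upstream_distance, 0L)
})

test_that("a gene overlapping a lincRNA violates the intergenic precondition", {
  genes <- make_genes("c1", 1000, 2000)
  expect_error(assignApcGenes(make_lincs("c1", 1500, 2500), genes),
               "intergenic")
})

test_that("distance ties break toward the smaller start coordinate and are flagged", {
  genes <- make_genes("c1", c(100, 300), c(500, 500), id = c("gA", "gB"))
  a <- assignApcGenes(make_lincs("c1", 1000, 1200), genes)
  expect_equal(a$upstream_gene, "gA")
  expect_true(a$tie)
})

test_that("two lincRNAs flanking one gene give a 2:1 relationship", {
  genes <- make_genes("c1", c(1000, 5000, 9000),
                      c(2000, 6000, 10000), id = c("gL", "gM", "gR"))
  lincs <- make_lincs("c1", c(3000, 7000), c(3500, 7500))
  a <- assignApcGenes(lincs, genes)
  expect_true(all(c("gM") %in% a$upstream_gene | "gM" %in% a$downstream_gene))
  cen <- relationshipCensus(a)
  expect_equal(cen$one_to_two, 2L)
  expect_equal(cen$two_to_one, 1L)
  expect_equal(cen$n_to_one[["gM"]], 2L)
  expect_equal(cen$total_apcgenes, 3L)
})

test_that("n consecutive lincRNAs sharing one gene form an n:1 relationship", {
  genes <- make_genes("c1", 9000, 10000, id = "gX")
  lincs <- make_lincs("c1", c(1000, 3000, 5000), c(1500, 3500, 5500))
  cen <- relationshipCensus(assignApcGenes(lincs, genes))
  expect_equal(cen$n_to_one[["gX"]], 3L)
  expect_equal(cen$two_to_one, 0L)
  expect_equal(cen$one_to_two, 0L)
})

test_that("an empty assignment set gives an empty census", {
  cen <- relationshipCensus(assignApcGenes(make_lincs("c1", integer(0),
                                                      integer(0)),
                                           make_genes("c1", 100, 500)))
  expect_equal(cen$total_apcgenes, 0L)
  expect_equal(cen$one_to_two, 0L)
})

test_that("assignment agrees with a linear-scan oracle on random instances", {
  set.seed(19)
  for (i in 1:60) {
    n_genes <- sample(1:100, 1)
    starts <- sort(sample(seq(1, 500000, by = 50), n_genes))
    ends <- starts + sample(20:40, n_genes, replace = TRUE)
    genes <- make_genes("cZ", starts, ends)
    linc_start <- sample(1:500000, 1)
    linc_end <- linc_start + 10L
    ok <- all(ends < linc_start | starts > linc_end)
    if (!ok) next
    a <- assignApcGenes(make_lincs("cZ", linc_start, linc_end), genes)
    o <- apc_oracle(linc_start, linc_end, starts, ends, genes$feature_id)
    expect_equal(a$upstream_gene, o$upstream$gene, info = paste("up", i))
    expect_equal(a$upstream_distance, o$upstream$dist, info = paste("ud", i))
    expect_equal(a$downstream_gene, o$downstream$gene, info = paste("dn", i))
    expect_equal(a$downstream_distance, o$downstream$dist,
                 info = paste("dd", i))
  }
})

test_that("configuration classification is total over its 12 geometric cases", {
  # every (geometry, gene strand, orientation) combination, mapped by hand
  cases <- expand.grid(geometry = c("left", "right"),
                       gene_strand = c("+", "-"),
                       orientation = c("F", "R", "FR"),
                       stringsAsFactors = FALSE)
  expected <- apply(cases, 1, function(r) {
    side <- if ((r[["geometry"]] == "left") == (r[["gene_strand"]] == "+"))
      "5P" else "3P"
    dir <- if (r[["orientation"]] == "FR") "bidirectional"
    else if ((r[["orientation"]] == "F") == (r[["gene_strand"]] == "+"))
      "same" else "opposite"
    key <- configurationClasses()
    key$label[key$side == side & key$direction == dir]
  })
  linc_start <- ifelse(cases$geometry == "left", 1000L, 8000L)
  lincs <- GenomicRanges::GRanges(sprintf("k%02d", seq_len(nrow(cases))),
                                  IRanges::IRanges(linc_start,
                                                   linc_start + 400L))
  genes <- GenomicRanges::GRanges(sprintf("k%02d", seq_len(nrow(cases))),
                                  IRanges::IRanges(5000L, 6000L),
                                  strand = cases$gene_strand)
  got <- classifyConfiguration(lincs, genes, cases$orientation)
  expect_equal(got$label, unname(expected))
  expect_setequal(unique(got$label), configurationClasses()$label)
})

test_that("a specific mixed case: lincRNA left of a minus gene, called forward", {
  l <- GenomicRanges::GRanges("c1", IRanges::IRanges(500, 900))
  g <- GenomicRanges::GRanges("c1", IRanges::IRanges(2000, 3000),
                              strand = "-")
  got <- classifyConfiguration(l, g, "F")
  expect_equal(got$side, "3P")
  expect_equal(got$direction, "opposite")
  expect_equal(got$label, "C5_3P_OPP")
})

test_that("classification rejects unknown strands and overlapping pairs", {
  l <- GenomicRanges::GRanges("c1", IRanges::IRanges(500, 900))
  g_star <- GenomicRanges::GRanges("c1", IRanges::IRanges(2000, 3000))
  expect_error(classifyConfiguration(l, g_star, "F"), "strand")
  g_ovl <- GenomicRanges::GRanges("c1", IRanges::IRanges(800, 3000),
                                  strand = "+")
  expect_error(classifyConfiguration(l, g_ovl, "F"), "overlap")
})
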