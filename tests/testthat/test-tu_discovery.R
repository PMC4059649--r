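make_features <- function(contig, start, end, role = "transcript",
                          id = NULL) {
  gr <- GenomicRanges::GRanges(rep_len(contig, length(start)),
                               IRanges::IRanges(start, end))
  gr$feature_id <- id %||% sprintf("f%02d", seq_along(gr))
  gr$role <- rep_len(role, length(gr))
  gr
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("disjoint intervals form separate TUs; overlap chains merge into one", {
  f <- make_features("c1", c(100, 300), c(200, 400))
  expect_length(mergeTranscriptUnits(f), 2L)

  chain <- make_features("c1", c(100, 150, 250), c(200, 300, 400))
  tu <- mergeTranscriptUnits(chain)
  expect_length(tu, 1L)
  expect_equal(start(tu), 100L)
  expect_equal(end(tu), 400L)
  expect_setequal(tu$members[[1]], chain$feature_id)
})

test_that("merging requires a shared base: bookended features stay separate", {
  f <- make_features("c1", c(100, 201), c(200, 300))
  expect_length(mergeTranscriptUnits(f), 2L)
  g <- make_features("c1", c(100, 200), c(200, 300))
  expect_length(mergeTranscriptUnits(g), 1L)
})

test_that("merging ignores annotated strand and respects contig boundaries", {
  gr <- GenomicRanges::GRanges(c("c1", "c1", "c2"),
                               IRanges::IRanges(c(100, 150, 100),
                                                c(200, 250, 200)),
                               strand = c("+", "-", "+"))
  gr$feature_id <- c("a", "b", "c")
  gr$role <- "transcript"
  tu <- mergeTranscriptUnits(gr)
  expect_length(tu, 2L)
  expect_setequal(tu$members[[which(as.character(seqnames(tu)) == "c1")]],
                  c("a", "b"))
})

test_that("merging is idempotent: re-merging TUs as features is a fixed point", {
  set.seed(7)
  f <- random_feature_set(40L)
  tu <- mergeTranscriptUnits(f)
  as_features <- granges(tu)
  as_features$feature_id <- tu$tu_id
  as_features$role <- "transcript"
  tu2 <- mergeTranscriptUnits(as_features)
  expect_equal(granges(tu2), granges(tu))
})

test_that("TU partition matches the brute-force transitive-closure oracle", {
  set.seed(11)
  for (i in 1:60) {
    f <- random_feature_set(50L)
    tu <- mergeTranscriptUnits(f)
    expect_equal(
      signature_of_tus(tu),
      merge_oracle_signature(as.character(seqnames(f)), start(f), end(f),
                             f$feature_id),
      info = paste("instance", i))
    # span covers every member
    ov <- GenomicRanges::findOverlaps(f, tu, type = "within",
                                      ignore.strand = TRUE)
    expect_equal(length(unique(S4Vectors::queryHits(ov))), length(f))
  }
})

test_that("TUs containing gene models are discarded, transcript-only TUs kept", {
  f <- make_features("c1", c(100, 150, 500), c(200, 300, 700),
                     role = c("transcript", "gene_model", "transcript"))
  tu <- mergeTranscriptUnits(f)
  sp <- dropGeneContaining(tu)
  expect_equal(length(sp$retained), 1L)
  expect_equal(length(sp$discarded), 1L)
  expect_true(sp$discarded$contains_gene_model)
  empty <- mergeTranscriptUnits(make_features("c1", integer(0), integer(0)))
  sp0 <- dropGeneContaining(empty)
  expect_length(sp0$retained, 0L)
  expect_length(sp0$discarded, 0L)
})

test_that("hit filter discards on e-value strictly below the cutoff only", {
  tu <- mergeTranscriptUnits(make_features("c1", c(100, 500, 900),
                                           c(300, 700, 1100)))
  hit_row <- function(id, e) {
    data.frame(qseqid = id, sseqid = "s", pident = 99, length = 100,
               mismatch = 0, gapopen = 0, qstart = 1, qend = 100,
               sstart = 1, send = 100, evalue = e, bitscore = 200)
  }
  hits <- rbind(hit_row(tu$tu_id[1], 1e-6), hit_row(tu$tu_id[2], 1e-5))
  sp <- applyHitFilter(tu, hits)
  expect_equal(sp$discarded$tu_id, tu$tu_id[1])      # 1e-6 < 1e-5
  expect_setequal(sp$retained$tu_id, tu$tu_id[2:3])  # boundary + no hits kept
  expect_warning(applyHitFilter(tu, hit_row("TU_nowhere_1_2", 1e-9)),
                 "unknown TU")
})

test_that("ORF filter discards strictly above 100 aa; length filter below 200 bp", {
  tu <- mergeTranscriptUnits(make_features("c1", c(1, 400), c(310, 720)))
  seqs <- Biostrings::DNAStringSet(c("ATGTAA", "ATGAAA"))
  names(seqs) <- tu$tu_id
  sp <- dropCodingByOrf(tu, seqs)
  expect_length(sp$retained, 2L)   # 1 aa and 2 aa are both <= 100
  expect_equal(sp$retained$longest_orf_aa, c(1L, 2L))

  lens <- mergeTranscriptUnits(make_features("c1", c(1, 500, 2000),
                                             c(199, 699, 3965)))
  spl <- dropShort(lens)
  expect_equal(width(spl$discarded), 199L)
  expect_setequal(width(spl$retained), c(200L, 1966L))
})

test_that("coding-potential filter requires both strand scores strictly below zero", {
  tu <- mergeTranscriptUnits(make_features("c1", c(1, 500, 1000),
                                           c(300, 800, 1300)))
  scores <- data.frame(query_id = tu$tu_id,
                       plus_score = c(-1.2, -1.2, 0.0),
                       minus_score = c(-0.3, 0.3, -1.0))
  sp <- applyCodingPotentialFilter(tu, scores)
  expect_equal(sp$retained$tu_id, tu$tu_id[1])
  expect_setequal(sp$discarded$tu_id, tu$tu_id[2:3])
  expect_error(applyCodingPotentialFilter(tu, scores[1:2, ]),
               tu$tu_id[3])
})

test_that("a cascade over empty input yields an empty result and all-zero report", {
  genome <- Biostrings::DNAStringSet(c(c1 = paste(rep("A", 100), collapse = "")))
  res <- runCascade(make_features("c1", integer(0), integer(0)), genome)
  expect_length(candidates(res), 0L)
  expect_true(all(cascadeReport(res)$n_input == 0L))
  expect_true(all(cascadeReport(res)$n_retained == 0L))
})

test_that("cascade bookkeeping sums and chains; survivors satisfy every predicate", {
  ds <- simulateLincDataset(
    config = list(n_genes = 12L, n_lincs = 8L,
                  decoys = c(short = 2L, long_orf = 2L, blast_hit = 2L,
                             coding_score = 2L),
                  contig_length = 60000L),
    seed = 21L)
  res <- runCascade(ds$features, ds$genome, hits = ds$hits,
                    scores = ds$scores, mirnaHits = ds$mirna_hits)
  rep <- cascadeReport(res)
  expect_equal(rep$n_input, rep$n_discarded + rep$n_retained)
  expect_equal(rep$n_retained[-nrow(rep)], rep$n_input[-1])
  expect_true(all(diff(rep$n_retained) <= 0))
  cand <- candidates(res)
  expect_true(all(width(cand) >= 200))
  expect_true(all(cand$longest_orf_aa <= 100))
  expect_true(all(cand$plus_score < 0 & cand$minus_score < 0))
  expect_true(all(!cand$contains_gene_model))
  hit_ids <- unique(ds$hits$qseqid[ds$hits$evalue < 1e-5])
  expect_true(all(!cand$tu_id %in% hit_ids))
})

test_that("each decoy is discarded at exactly its designed stage", {
  ds <- simulateLincDataset(
    config = list(n_genes = 12L, n_lincs = 8L,
                  decoys = c(short = 2L, long_orf = 2L, blast_hit = 2L,
                             coding_score = 2L),
                  contig_length = 60000L),
    seed = 21L)
  res <- runCascade(ds$features, ds$genome, hits = ds$hits,
                    scores = ds$scores, mirnaHits = ds$mirna_hits)
  rep <- cascadeReport(res)
  by_stage <- setNames(rep$n_discarded, rep$stage)
  expect_equal(by_stage[["similarity_hits"]], 2L)
  expect_equal(by_stage[["long_orf"]], 2L)
  expect_equal(by_stage[["short_length"]], 2L)
  expect_equal(by_stage[["coding_potential"]], 2L)
  expect_setequal(candidates(res)$tu_id, ds$manifest$lincs$tu_id)
})

test_that("the survivor set does not depend on the filter order", {
  ds <- simulateLincDataset(seed = 33L)
  tus <- mergeTranscriptUnits(ds$features)
  seqs <- extractTuSequences(tus, ds$genome)
  scores <- ds$scores
  extra <- setdiff(tus$tu_id, scores$query_id)
  scores <- rbind(scores, data.frame(query_id = extra, plus_score = -1,
                                     minus_score = -1))
  filters <- list(
    gene = function(x) dropGeneContaining(x)$retained,
    hits = function(x) applyHitFilter(x, ds$hits)$retained,
    orf = function(x) dropCodingByOrf(x, seqs)$retained,
    short = function(x) dropShort(x)$retained,
    cpc = function(x) applyCodingPotentialFilter(x, scores)$retained)
  set.seed(5)
  reference <- NULL
  for (perm in 1:6) {
    x <- tus
    for (f in sample(filters)) x <- f(x)
    ids <- sort(x$tu_id)
    if (is.null(reference)) reference <- ids
    expect_equal(ids, reference, info = paste("permutation", perm))
  }
})
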