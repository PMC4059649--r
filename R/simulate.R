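## Synthetic-data generators. Each generator is seeded and records its seed
## and configuration in the truth manifest; with a fixed seed the outputs
## are byte-identical across runs. The generated data emulate the study
## design the pipeline targets: a compact multi-contig fungal genome with
## planted protein-coding genes (ORF > 100 aa), planted intergenic
## non-coding loci (>= 200 bp, no ORF > 100 aa on either strand), decoy
## transcripts each violating exactly one cascade filter, three-stage qPCR
## expression with planted correlation classes, and RACE-style band
## patterns consistent with planted orientations.

NON_STOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste0, collapse = ""),
  STOP_CODONS)

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## ATG + (aa - 1) non-stop codons + one stop
.orf_sequence <- function(aa) {
  paste0("ATG",
         paste(sample(NON_STOP_CODONS, aa - 1L, replace = TRUE),
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

## rejection-sample a sequence with no ORF > max_orf_aa on either strand
.noncoding_dna <- function(n, max_orf_aa = 100L) {
  repeat {
    s <- .random_dna(n)
    if (longestOrfAa(s) <= max_orf_aa) return(s)
  }
}

.revcomp_chr <- function(s) {
  as.character(reverseComplement(DNAStringSet(s))[[1L]])
}

.tu_id_for <- function(contig, start, end) {
  sprintf("TU_%s_%d_%d", contig, start, end)
}

#' Default configuration for the synthetic genome
#'
#' @return named list: \code{n_contigs} (2), \code{contig_length} (50000
#'   bp), \code{n_genes} (10), \code{n_lincs} (6), \code{decoys} (named
#'   integer vector over types \code{short}, \code{long_orf},
#'   \code{blast_hit}, \code{coding_score}; one of each), \code{gene_orf_aa}
#'   (ORF length range of planted genes, 120-200 aa), \code{linc_length}
#'   (250-1200 bp), \code{gap} (intergenic spacing range, 300-800 bp),
#'   \code{orientation_probs} (probabilities of planting F, R, FR
#'   orientations on lincRNA loci).
#' @export
defaultSimConfig <- function() {
  list(n_contigs = 2L, contig_length = 50000L, n_genes = 10L, n_lincs = 6L,
       decoys = c(short = 1L, long_orf = 1L, blast_hit = 1L,
                  coding_score = 1L),
       gene_orf_aa = c(120L, 200L), linc_length = c(250L, 1200L),
       gap = c(300L, 800L),
       orientation_probs = c(F = 0.4, R = 0.4, FR = 0.2))
}

#' Generate a synthetic genome with planted genes and lincRNA loci
#'
#' Lays out, per contig, an alternating sequence of planted protein-coding
#' genes and non-coding elements (lincRNA loci and decoy loci) separated by
#' random intergenic gaps, so that most lincRNA loci are flanked by genes
#' on both sides. Planted genes carry an ATG-initiated ORF longer than 100
#' aa on their annotated strand; lincRNA loci are rejection-sampled to
#' contain no ORF longer than 100 aa on either strand. Decoy loci are
#' constructed to violate exactly one cascade filter each: \code{short}
#' (150 bp), \code{long_orf} (an unannotated 120-aa ORF), \code{blast_hit}
#' (slated for a synthetic similarity hit) and \code{coding_score} (slated
#' for a positive coding-potential score).
#'
#' @param config list as from \code{\link{defaultSimConfig}}.
#' @param seed integer seed; recorded in the manifest.
#' @return list: \code{genome} (named \code{DNAStringSet}), \code{genes}
#'   (\code{GRanges} of gene models), \code{manifest} (truth manifest:
#'   \code{genes}, \code{lincs}, \code{decoys} data.frames with planted
#'   coordinates, orientations and predicted TU ids, plus \code{seed} and
#'   the config echo).
#' @export
simulateGenome <- function(config = defaultSimConfig(), seed = 1L) {
  config <- modifyList(defaultSimConfig(), config)
  set.seed(seed)
  decoy_types <- rep(names(config$decoys), config$decoys)
  n_nc <- config$n_lincs + length(decoy_types)

  ## element descriptors in planting order, interleaved gene / non-gene
  nc_kind <- sample(c(rep("linc", config$n_lincs),
                      if (length(decoy_types))
                        paste0("decoy:", decoy_types)
                      else character(0)))
  elements <- list()
  gi <- 0L; ni <- 0L
  n_total <- config$n_genes + n_nc
  want_gene <- TRUE
  for (k in seq_len(n_total)) {
    if ((want_gene && gi < config$n_genes) || ni >= n_nc) {
      gi <- gi + 1L
      elements[[k]] <- list(kind = "gene", id = sprintf("G%03d", gi))
      want_gene <- FALSE
    } else {
      ni <- ni + 1L
      elements[[k]] <- list(kind = nc_kind[ni],
                            id = if (nc_kind[ni] == "linc")
                              sprintf("L%03d", sum(startsWith(
                                vapply(elements[seq_len(k - 1L)],
                                       `[[`, "", "kind"), "linc")) + 1L)
                            else sprintf("D%03d", sum(startsWith(
                              vapply(elements[seq_len(k - 1L)],
                                     `[[`, "", "kind"), "decoy")) + 1L))
      want_gene <- TRUE
    }
  }

  contig_of <- sort(rep(seq_len(config$n_contigs),
                        length.out = n_total))
  contig_names <- sprintf("ctg%02d", seq_len(config$n_contigs))
  genes <- lincs <- decoys <- list()
  contig_seq <- character(config$n_contigs)

  for (ci in seq_len(config$n_contigs)) {
    parts <- character(0)
    pos <- 0L
    for (k in which(contig_of == ci)) {
      el <- elements[[k]]
      gap <- sample(config$gap[1]:config$gap[2], 1L)
      parts <- c(parts, .random_dna(gap))
      pos <- pos + gap
      if (el$kind == "gene") {
        aa <- sample(config$gene_orf_aa[1]:config$gene_orf_aa[2], 1L)
        s <- .orf_sequence(aa)
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") s <- .revcomp_chr(s)
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = el$id, contig = contig_names[ci],
          start = pos + 1L, end = pos + nchar(s), strand = strand,
          orf_aa = aa, stringsAsFactors = FALSE)
      } else if (el$kind == "linc") {
        len <- sample(config$linc_length[1]:config$linc_length[2], 1L)
        s <- .noncoding_dna(len)
        ori <- sample(names(config$orientation_probs), 1L,
                      prob = config$orientation_probs)
        lincs[[length(lincs) + 1L]] <- data.frame(
          linc_id = el$id, contig = contig_names[ci],
          start = pos + 1L, end = pos + len, length = len,
          orientation = ori,
          tu_id = .tu_id_for(contig_names[ci], pos + 1L, pos + len),
          stringsAsFactors = FALSE)
      } else {
        type <- sub("^decoy:", "", el$kind)
        s <- switch(type,
          short = .noncoding_dna(150L),
          long_orf = {
            body <- .orf_sequence(120L)
            paste0(.noncoding_dna(60L), body, .noncoding_dna(60L))
          },
          blast_hit = .noncoding_dna(400L),
          coding_score = .noncoding_dna(400L))
        decoys[[length(decoys) + 1L]] <- data.frame(
          decoy_id = el$id, type = type, contig = contig_names[ci],
          start = pos + 1L, end = pos + nchar(s),
          tu_id = .tu_id_for(contig_names[ci], pos + 1L, pos + nchar(s)),
          stringsAsFactors = FALSE)
      }
      parts <- c(parts, s)
      pos <- pos + nchar(s)
    }
    if (pos > config$contig_length)
      stop(sprintf("config infeasible: contig %s needs %d bp but contig_length is %d",
                   contig_names[ci], pos, config$contig_length))
    parts <- c(parts, .random_dna(config$contig_length - pos))
    contig_seq[ci] <- paste(parts, collapse = "")
  }

  genome <- DNAStringSet(contig_seq)
  names(genome) <- contig_names
  genes_df <- do.call(rbind, genes)
  gene_gr <- GRanges(genes_df$contig,
                     IRanges(genes_df$start, genes_df$end),
                     strand = genes_df$strand)
  gene_gr$feature_id <- genes_df$gene_id
  gene_gr$role <- "gene_model"
  gene_gr$stage <- NA_character_
  manifest <- list(seed = seed, config = config, genes = genes_df,
                   lincs = do.call(rbind, lincs),
                   decoys = if (length(decoys)) do.call(rbind, decoys)
                            else data.frame())
  list(genome = genome, genes = gene_gr, manifest = manifest)
}

#' Generate per-stage assembled-transcript sets from a truth manifest
#'
#' Emits, per developmental stage, transcripts covering the planted loci:
#' every gene and decoy is transcribed in stage M (the first two genes as
#' two overlapping fragments whose union equals the gene span, to exercise
#' TU merging); each lincRNA locus is transcribed in the stages where it is
#' flagged present (all three by default).
#'
#' @param manifest truth manifest from \code{\link{simulateGenome}}.
#' @param stage_presence optional logical matrix (lincRNA x stage, columns
#'   \code{M}, \code{P}, \code{FB}); default all \code{TRUE}.
#' @param n_fragmented_genes how many genes are emitted as two overlapping
#'   fragments (default 2).
#' @return named list of \code{GRanges} (one per stage) in
#'   \code{\link{readAnnotation}} feature layout.
#' @export
simulateTranscripts <- function(manifest, stage_presence = NULL,
                                n_fragmented_genes = 2L) {
  lincs <- manifest$lincs
  if (is.null(stage_presence)) {
    stage_presence <- matrix(TRUE, nrow = nrow(lincs), ncol = 3L,
                             dimnames = list(lincs$linc_id, STAGES))
  }
  out <- list()
  for (st in STAGES) {
    rows <- list()
    if (st == "M") {
      g <- manifest$genes
      for (i in seq_len(nrow(g))) {
        w <- g$end[i] - g$start[i] + 1L
        if (i <= n_fragmented_genes && w >= 30L) {
          cut1 <- g$start[i] + as.integer(0.6 * w)
          cut2 <- g$start[i] + as.integer(0.3 * w)
          rows[[length(rows) + 1L]] <- data.frame(
            contig = g$contig[i],
            start = c(g$start[i], cut2), end = c(cut1, g$end[i]),
            feature_id = paste0("t_", g$gene_id[i], c("_a", "_b")),
            stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            contig = g$contig[i], start = g$start[i], end = g$end[i],
            feature_id = paste0("t_", g$gene_id[i]),
            stringsAsFactors = FALSE)
        }
      }
      d <- manifest$decoys
      for (i in seq_len(nrow(d))) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig = d$contig[i], start = d$start[i], end = d$end[i],
          feature_id = paste0("t_", d$decoy_id[i]),
          stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(nrow(lincs))) {
      if (stage_presence[lincs$linc_id[i], st]) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig = lincs$contig[i], start = lincs$start[i],
          end = lincs$end[i],
          feature_id = paste0("t_", lincs$linc_id[i], "_", st),
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    gr <- if (is.null(df)) .empty_features() else {
      g <- GRanges(df$contig, IRanges(df$start, df$end), strand = "*")
      g$feature_id <- df$feature_id
      g$role <- "transcript"
      g$stage <- st
      g
    }
    out[[st]] <- gr
  }
  out
}

#' Generate similarity-hit and coding-score side tables
#'
#' Decoys of type \code{blast_hit} receive one Nt-style hit row with
#' e-value 1e-20 (well below the 1e-5 cutoff); every non-coding locus
#' receives coding-potential scores drawn below zero on both strands,
#' except \code{coding_score} decoys whose plus-strand score is drawn at or
#' above zero. The miRNA-precursor table is empty by default, matching a
#' screen that finds no hits.
#'
#' @param manifest truth manifest from \code{\link{simulateGenome}}.
#' @param seed integer seed.
#' @return list: \code{hits}, \code{scores}, \code{mirna_hits} data.frames
#'   in the \code{\link{readHits}} / \code{\link{readCodingScores}} layouts.
#' @export
simulateSideTables <- function(manifest, seed = 1L) {
  set.seed(seed)
  d <- manifest$decoys
  loci <- rbind(
    data.frame(tu_id = manifest$lincs$tu_id,
               type = "linc", stringsAsFactors = FALSE),
    if (nrow(d)) data.frame(tu_id = d$tu_id, type = d$type,
                            stringsAsFactors = FALSE))
  hit_ids <- loci$tu_id[loci$type == "blast_hit"]
  hits <- data.frame(
    qseqid = hit_ids, sseqid = sprintf("nt|%06d", seq_along(hit_ids)),
    pident = 98.0, length = 200L, mismatch = 2L, gapopen = 0L,
    qstart = 1L, qend = 200L, sstart = 1L, send = 200L,
    evalue = 1e-20, bitscore = 380.0, stringsAsFactors = FALSE)
  scores <- data.frame(
    query_id = loci$tu_id,
    plus_score = runif(nrow(loci), -2, -0.1),
    minus_score = runif(nrow(loci), -2, -0.1),
    stringsAsFactors = FALSE)
  scores$plus_score[loci$type == "coding_score"] <-
    runif(sum(loci$type == "coding_score"), 0, 2)
  mirna <- hits[0, , drop = FALSE]
  list(hits = hits, scores = scores, mirna_hits = mirna)
}

## one three-stage log2 expression profile with clear stage structure:
## a baseline plus two stage offsets of magnitude 1.5-4 log2 units
.base_log2_profile <- function() {
  a <- runif(1, -5, 1)
  a + c(0, sample(c(-1, 1), 2L, replace = TRUE) * runif(2, 1.5, 4))
}

#' Generate a qPCR Ct table with planted correlation classes
#'
#' For each pair a three-stage lincRNA expression profile is drawn with
#' clear stage-to-stage structure; the apcGene profile is then a positive
#' scaling of it (planted class \code{positive}, r = 1 at zero noise), a
#' reflected profile (\code{negative}, r = -1 at zero noise), or an
#' independently drawn profile rejection-sampled to |r| <= 0.5
#' (\code{none}; with only three stages, genuinely independent profiles
#' frequently exceed |r| = 0.8 by chance, so the planted "uncorrelated"
#' class is defined as demonstrably weak correlation). Profiles are
#' converted to Ct around a reference baseline via the inverse of the
#' delta-Ct transform, and Gaussian replicate noise on the cycle scale is
#' added. Replicate Ct values beyond cycle 40 are recorded as undetected
#' (sentinel 40).
#'
#' @param classes character vector of planted classes per pair
#'   (\code{positive}, \code{negative}, \code{none}).
#' @param noise_sd replicate noise SD in cycles (>= 0).
#' @param seed integer seed.
#' @param ref_ct reference-gene baseline Ct (default 20).
#' @param n_reps replicates per gene/stage (default 3).
#' @return list: \code{ct} (data.frame in \code{\link{readCtTable}} layout,
#'   numeric Ct with the sentinel already applied, including the
#'   \code{GAPDH} rows), \code{truth} (\code{data.frame(lincrna_id,
#'   apcgene_id, class)}), \code{pairs} (ids only, for
#'   \code{\link{analyzeExpressionPairs}}).
#' @export
simulateCtTable <- function(classes, noise_sd = 0, seed = 1L, ref_ct = 20,
                            n_reps = 3L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  bad <- setdiff(classes, c("positive", "negative", "none"))
  if (length(bad))
    stop(sprintf("unknown correlation class(es): %s",
                 paste(bad, collapse = ", ")))
  set.seed(seed)
  rows <- list()
  emit <- function(gene_id, log2_rel) {
    ct_mean <- ref_ct - log2_rel
    for (s in seq_along(STAGES)) {
      ct <- ct_mean[s] + rnorm(n_reps, 0, noise_sd)
      ct <- pmin(pmax(ct, 0), 40)
      rows[[length(rows) + 1L]] <<- data.frame(
        gene_id = gene_id, stage = STAGES[s], replicate = seq_len(n_reps),
        ct = ct, stringsAsFactors = FALSE)
    }
  }
  truth <- list()
  for (i in seq_along(classes)) {
    linc_l2 <- .base_log2_profile()
    linc_lin <- 2^linc_l2
    apc_lin <- switch(classes[i],
      positive = 2^runif(1, -2, 2) * linc_lin,
      negative = 2^runif(1, -2, 0) *
        ((max(linc_lin) + min(linc_lin)) - linc_lin),
      none = {
        repeat {
          cand <- 2^.base_log2_profile()
          if (abs(cor(cand, linc_lin)) <= 0.5) break
        }
        cand
      })
    lid <- sprintf("linc_%03d", i)
    aid <- sprintf("apc_%03d", i)
    emit(lid, linc_l2)
    emit(aid, log2(apc_lin))
    truth[[i]] <- data.frame(lincrna_id = lid, apcgene_id = aid,
                             class = classes[i], stringsAsFactors = FALSE)
  }
  for (s in STAGES) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = "GAPDH", stage = s, replicate = seq_len(n_reps),
      ct = pmin(pmax(ref_ct + rnorm(n_reps, 0, noise_sd), 0), 40),
      stringsAsFactors = FALSE)
  }
  ct <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(ct, "reference_gene_id") <- "GAPDH"
  truth <- do.call(rbind, truth)
  list(ct = ct, truth = truth,
       pairs = truth[c("lincrna_id", "apcgene_id")])
}

#' Generate an MRA band table from planted orientations
#'
#' Emits, for each planted orientation, the band rows its pattern implies:
#' lane P4a carries a band at the expected size iff forward transcription
#' is planted, lane P4b iff reverse transcription is planted, and the
#' control lane Pc always carries its band. With \code{nonspecific = TRUE}
#' an extra band at 2.2x the expected size is added to lane P4a (outside
#' any sane tolerance, so calls are unchanged but the nonspecific flag is
#' raised).
#'
#' @param orientations \code{data.frame(lincrna_id, stage, orientation)}
#'   with orientation in \code{F}, \code{R}, \code{FR}; stage may be
#'   \code{"pooled"}.
#' @param expected_sizes named numeric vector of expected product sizes
#'   (bp) per lincRNA id; defaults to 500 for every locus.
#' @param nonspecific add out-of-tolerance extra bands (default FALSE).
#' @return data.frame in the \code{\link{readBandTable}} file layout
#'   (\code{observed_sizes} as semicolon-separated strings).
#' @export
simulateMraBands <- function(orientations, expected_sizes = NULL,
                             nonspecific = FALSE) {
  if (is.null(expected_sizes))
    expected_sizes <- setNames(rep(500, length(unique(orientations$lincrna_id))),
                               unique(orientations$lincrna_id))
  rows <- list()
  for (i in seq_len(nrow(orientations))) {
    id <- orientations$lincrna_id[i]
    st <- orientations$stage[i]
    ori <- orientations$orientation[i]
    exp_size <- expected_sizes[[id]]
    obs_a <- if (ori %in% c("F", "FR")) as.character(exp_size) else ""
    if (nonspecific) {
      extra <- as.character(round(2.2 * exp_size))
      obs_a <- if (nzchar(obs_a)) paste(obs_a, extra, sep = ";") else extra
    }
    obs_b <- if (ori %in% c("R", "FR")) as.character(exp_size) else ""
    rows[[length(rows) + 1L]] <- data.frame(
      lincrna_id = id, stage = st, lane = c("P4a", "P4b", "Pc"),
      expected_size = exp_size,
      observed_sizes = c(obs_a, obs_b, as.character(exp_size)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$observed_sizes <- as.character(out$observed_sizes)
  obs <- strsplit(out$observed_sizes, ";", fixed = TRUE)
  out$observed_sizes_parsed <- lapply(obs, function(x) as.numeric(x[nzchar(x)]))
  out
}

#' Generate a complete synthetic input bundle with its truth manifest
#'
#' Orchestrates \code{\link{simulateGenome}},
#' \code{\link{simulateTranscripts}}, \code{\link{simulateSideTables}},
#' \code{\link{simulateCtTable}} and \code{\link{simulateMraBands}} into
#' one internally consistent dataset. If \code{out_dir} is given, the
#' bundle is also written to disk (genome FASTA, gene GFF3, one GTF per
#' stage, hit/score/Ct/band TSVs, manifest JSON).
#'
#' @param config genome configuration (see \code{\link{defaultSimConfig}}).
#' @param seed integer master seed (sub-generators derive from it).
#' @param noise_sd qPCR replicate noise SD in cycles (default 0).
#' @param out_dir optional output directory.
#' @return list: \code{genome}, \code{genes} (\code{GRanges}),
#'   \code{transcripts} (per-stage \code{GRanges} list), \code{features}
#'   (genes + pooled transcripts, ready for \code{\link{runCascade}}),
#'   \code{hits}, \code{scores}, \code{mirna_hits}, \code{ct},
#'   \code{ct_truth}, \code{bands}, \code{orientations},
#'   \code{manifest}.
#' @export
simulateLincDataset <- function(config = defaultSimConfig(), seed = 1L,
                                noise_sd = 0, out_dir = NULL) {
  gen <- simulateGenome(config, seed = seed)
  manifest <- gen$manifest
  tx <- simulateTranscripts(manifest)
  side <- simulateSideTables(manifest, seed = seed + 1L)
  n_lincs <- nrow(manifest$lincs)
  classes <- rep(c("positive", "negative", "none"),
                 length.out = n_lincs)
  ctd <- simulateCtTable(classes, noise_sd = noise_sd, seed = seed + 2L)
  orientations <- data.frame(lincrna_id = manifest$lincs$linc_id,
                             stage = "pooled",
                             orientation = manifest$lincs$orientation,
                             stringsAsFactors = FALSE)
  bands <- simulateMraBands(
    orientations,
    expected_sizes = setNames(pmax(150, round(0.8 * manifest$lincs$length)),
                              manifest$lincs$linc_id))
  features <- c(gen$genes, do.call(c, unname(tx)))
  manifest$expression_classes <- ctd$truth
  out <- list(genome = gen$genome, genes = gen$genes, transcripts = tx,
              features = features, hits = side$hits, scores = side$scores,
              mirna_hits = side$mirna_hits, ct = ctd$ct,
              ct_truth = ctd$truth, bands = bands,
              orientations = orientations, manifest = manifest)
  if (!is.null(out_dir)) .write_dataset(out, out_dir)
  out
}

.write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeXStringSet(ds$genome, file.path(out_dir, "genome.fa"))
  writeAnnotation(ds$genes, file.path(out_dir, "genes.gff3"), "GFF3")
  for (st in names(ds$transcripts)) {
    if (length(ds$transcripts[[st]]))
      writeAnnotation(ds$transcripts[[st]],
                      file.path(out_dir, sprintf("transcripts_%s.gtf", st)),
                      "GTF")
  }
  write.table(ds$hits, file.path(out_dir, "hits_nt_nr_sp.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(ds$mirna_hits, file.path(out_dir, "hits_mirna.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(ds$scores, file.path(out_dir, "coding_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ct_out <- ds$ct
  ct_out$ct <- ifelse(ct_out$ct >= 40, "ND", format(ct_out$ct, digits = 10))
  write.table(ct_out, file.path(out_dir, "ct_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  bands_out <- ds$bands[c("lincrna_id", "stage", "lane", "expected_size",
                          "observed_sizes")]
  write.table(bands_out, file.path(out_dir, "mra_bands.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- ds$manifest
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
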