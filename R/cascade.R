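## Transcript-unit construction and the lincRNA filter cascade.
##
## Filter order: gene-overlap -> similarity hits -> long ORF -> short
## length -> coding potential -> miRNA-precursor screen. All filters are
## independent predicates, so the surviving set does not depend on the
## order; only the per-stage bookkeeping does.

#' Default filter thresholds for the lincRNA cascade
#'
#' @return named list: \code{evalue_cutoff} (similarity hits with e-value
#'   strictly below this discard a TU; default \code{1e-5}),
#'   \code{max_orf_aa} (TUs with an ORF strictly longer than this are
#'   discarded; default 100), \code{min_length_bp} (TUs shorter than this
#'   are discarded, length exactly at the threshold is retained; default
#'   200), \code{coding_score_cutoff} (both strand scores must be strictly
#'   below this for a TU to count as non-coding; default 0).
#' @export
defaultFilterThresholds <- function() {
  list(evalue_cutoff = 1e-5, max_orf_aa = 100L, min_length_bp = 200L,
       coding_score_cutoff = 0)
}

#' Merge overlapping features into transcript units
#'
#' Partitions genomic features (assembled transcripts and gene models,
#' pooled across stages) into transcript units: two features belong to the
#' same TU iff they are connected by a chain of pairwise interval overlaps
#' on the same contig. Overlap is strand-agnostic (the assays producing the
#' transcripts are not strand-specific) and requires at least 1 shared bp:
#' bookended features (end + 1 == start) are kept separate. The TU span is
#' the union hull of its members.
#'
#' @param features \code{GRanges} with metadata columns \code{feature_id}
#'   and \code{role} (\code{"gene_model"} or \code{"transcript"}), as
#'   returned by \code{\link{readAnnotation}}.
#' @return \code{GRanges} of TUs (strand \code{*}), sorted by position, with
#'   metadata columns \code{tu_id} (deterministic,
#'   \code{TU_<contig>_<start>_<end>}), \code{members} (\code{CharacterList}
#'   of member feature ids) and \code{contains_gene_model}.
#' @examples
#' f <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(100, 150, 500),
#'                                                    c(200, 300, 600)))
#' f$feature_id <- c("t1", "t2", "t3"); f$role <- "transcript"
#' mergeTranscriptUnits(f)  # two TUs: [100,300] and [500,600]
#' @export
mergeTranscriptUnits <- function(features) {
  .validate_features(features)
  if (length(features) == 0L) {
    tus <- GRanges()
    mcols(tus) <- DataFrame(tu_id = character(0),
                            members = CharacterList(),
                            contains_gene_model = logical(0))
    return(tus)
  }
  tus <- reduce(granges(features), ignore.strand = TRUE, min.gapwidth = 0L)
  strand(tus) <- "*"
  tus <- sort(tus, ignore.strand = TRUE)
  ov <- findOverlaps(features, tus, ignore.strand = TRUE)
  members <- unname(splitAsList(features$feature_id[queryHits(ov)],
                                factor(subjectHits(ov),
                                       levels = seq_along(tus))))
  has_gene <- unname(vapply(
    splitAsList(features$role[queryHits(ov)] == "gene_model",
                factor(subjectHits(ov), levels = seq_along(tus))),
    any, logical(1)))
  mcols(tus) <- DataFrame(
    tu_id = sprintf("TU_%s_%d_%d", as.character(seqnames(tus)),
                    start(tus), end(tus)),
    members = members,
    contains_gene_model = has_gene)
  tus
}

.split_tus <- function(tus, keep) {
  list(retained = tus[keep], discarded = tus[!keep])
}

#' Filter stage: discard TUs containing predicted gene models
#'
#' @param tus \code{GRanges} of TUs from \code{\link{mergeTranscriptUnits}}.
#' @return list with elements \code{retained} (TUs with no gene-model
#'   member) and \code{discarded}.
#' @export
dropGeneContaining <- function(tus) {
  .split_tus(tus, !(tus$contains_gene_model %||% logical(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter stage: discard TUs with significant sequence-similarity hits
#'
#' A TU is discarded iff it has at least one hit with e-value strictly
#' below the cutoff; a hit at exactly the cutoff does not discard. The same
#' predicate serves the Nt/Nr/SP screen and the miRNA-precursor screen.
#'
#' @param tus \code{GRanges} of TUs.
#' @param hits hit table from \code{\link{readHits}} (query ids are TU ids).
#' @param evalue_cutoff discard threshold (default \code{1e-5}).
#' @return list \code{retained} / \code{discarded}. Hits referencing unknown
#'   TU ids are ignored with a warning.
#' @export
applyHitFilter <- function(tus, hits, evalue_cutoff = 1e-5) {
  if (is.null(hits) || nrow(hits) == 0L)
    return(.split_tus(tus, rep(TRUE, length(tus))))
  unknown <- setdiff(unique(hits$qseqid), tus$tu_id)
  if (length(unknown)) {
    warning(sprintf("ignoring hits for unknown TU id(s): %s",
                    paste(unknown, collapse = ", ")))
    hits <- hits[!hits$qseqid %in% unknown, , drop = FALSE]
  }
  sig <- unique(hits$qseqid[hits$evalue < evalue_cutoff])
  .split_tus(tus, !tus$tu_id %in% sig)
}

#' Extract plus-strand genomic sequences of TUs
#'
#' @param tus \code{GRanges} of TUs.
#' @param genome named \code{DNAStringSet} of contig sequences.
#' @return \code{DNAStringSet} named by \code{tu_id}.
#' @export
extractTuSequences <- function(tus, genome) {
  missing_contig <- setdiff(as.character(seqnames(tus)), names(genome))
  if (length(missing_contig))
    stop(sprintf("features on unknown contig(s): %s",
                 paste(missing_contig, collapse = ", ")))
  contig_len <- setNames(width(genome), names(genome))
  if (any(end(tus) > contig_len[as.character(seqnames(tus))]))
    stop("TU extends beyond its contig")
  seqs <- DNAStringSet(lapply(seq_along(tus), function(i) {
    subseq(genome[[as.character(seqnames(tus))[i]]],
           start(tus)[i], end(tus)[i])
  }))
  names(seqs) <- tus$tu_id
  seqs
}

#' Filter stage: discard TUs encoding ORFs longer than the threshold
#'
#' Applies \code{\link{longestOrfAa}} to each TU sequence; a TU is discarded
#' iff its longest six-frame ORF is strictly longer than \code{max_orf_aa}
#' (an ORF of exactly the threshold length is retained).
#'
#' @param tus \code{GRanges} of TUs.
#' @param sequences \code{DNAStringSet} named by TU id (see
#'   \code{\link{extractTuSequences}}); must cover every TU.
#' @param max_orf_aa threshold in amino acids (default 100).
#' @return list \code{retained} / \code{discarded}; both carry a
#'   \code{longest_orf_aa} metadata column.
#' @export
dropCodingByOrf <- function(tus, sequences, max_orf_aa = 100L) {
  if (length(tus) && !all(tus$tu_id %in% names(sequences)))
    stop("sequences missing for some TUs")
  orf <- vapply(as.character(sequences[tus$tu_id]), longestOrfAa,
                integer(1), USE.NAMES = FALSE)
  tus$longest_orf_aa <- if (length(tus)) orf else integer(0)
  .split_tus(tus, tus$longest_orf_aa <= max_orf_aa)
}

#' Filter stage: discard TUs shorter than the minimum length
#'
#' Length is the genomic span of the TU (end - start + 1); a TU of exactly
#' \code{min_length_bp} is retained.
#'
#' @param tus \code{GRanges} of TUs.
#' @param min_length_bp threshold in bp (default 200).
#' @return list \code{retained} / \code{discarded}.
#' @export
dropShort <- function(tus, min_length_bp = 200L) {
  .split_tus(tus, width(tus) >= min_length_bp)
}

#' Filter stage: retain TUs whose coding potential is negative on both strands
#'
#' A TU is retained iff both its plus-strand and minus-strand
#' coding-potential scores are strictly below the cutoff (default 0); a
#' score of exactly 0 on either strand discards.
#'
#' @param tus \code{GRanges} of TUs.
#' @param scores table from \code{\link{readCodingScores}}; every TU must
#'   have a score record, otherwise an error lists the missing ids.
#' @param coding_score_cutoff cutoff (default 0).
#' @return list \code{retained} / \code{discarded}; both carry
#'   \code{plus_score} / \code{minus_score} metadata columns.
#' @export
applyCodingPotentialFilter <- function(tus, scores, coding_score_cutoff = 0) {
  idx <- match(tus$tu_id, scores$query_id)
  if (anyNA(idx))
    stop(sprintf("no coding-potential score for TU id(s): %s",
                 paste(tus$tu_id[is.na(idx)], collapse = ", ")))
  tus$plus_score <- scores$plus_score[idx] %||% numeric(0)
  tus$minus_score <- scores$minus_score[idx] %||% numeric(0)
  keep <- tus$plus_score < coding_score_cutoff &
    tus$minus_score < coding_score_cutoff
  .split_tus(tus, keep %||% logical(0))
}

.report_row <- function(stage, n_in, n_disc) {
  data.frame(stage = stage, n_input = n_in, n_discarded = n_disc,
             n_retained = n_in - n_disc, stringsAsFactors = FALSE)
}

#' Run the full lincRNA filter cascade
#'
#' Builds transcript units from the pooled features and applies, in order:
#' removal of gene-containing TUs; the sequence-similarity hit filter
#' (Nt/Nr/SP screen); the long-ORF filter; the minimum-length filter; the
#' coding-potential filter; and the miRNA-precursor similarity screen. The
#' miRNA screen annotates candidates by default (\code{mirna_hit} metadata
#' column) rather than discarding them; set \code{mirnaFilterMode =
#' "discard"} to remove them.
#'
#' @param features pooled \code{GRanges} of transcripts and gene models.
#' @param genome named \code{DNAStringSet} of contig sequences.
#' @param hits Nt/Nr/SP hit table (\code{\link{readHits}} format) or
#'   \code{NULL}.
#' @param scores coding-potential score table
#'   (\code{\link{readCodingScores}} format); must cover every TU that
#'   survives to the coding-potential stage.
#' @param mirnaHits miRNA-precursor hit table or \code{NULL}.
#' @param thresholds list as from \code{\link{defaultFilterThresholds}}.
#' @param mirnaFilterMode \code{"annotate"} (default) or \code{"discard"}.
#' @return a \code{\link{LincRNACascade}} object.
#' @examples
#' ds <- simulateLincDataset(seed = 1)
#' res <- runCascade(ds$features, ds$genome, hits = ds$hits,
#'                   scores = ds$scores, mirnaHits = ds$mirna_hits)
#' res
#' @export
runCascade <- function(features, genome, hits = NULL, scores = NULL,
                       mirnaHits = NULL,
                       thresholds = defaultFilterThresholds(),
                       mirnaFilterMode = c("annotate", "discard")) {
  mirnaFilterMode <- match.arg(mirnaFilterMode)
  missing_contig <- setdiff(as.character(seqnames(features)), names(genome))
  if (length(missing_contig))
    stop(sprintf("features on unknown contig(s): %s",
                 paste(missing_contig, collapse = ", ")))
  tus <- mergeTranscriptUnits(features)

  rep_rows <- list()
  s1 <- dropGeneContaining(tus)
  rep_rows$gene_overlap <- .report_row("gene_overlap", length(tus),
                                       length(s1$discarded))
  s2 <- applyHitFilter(s1$retained, hits, thresholds$evalue_cutoff)
  rep_rows$similarity_hits <- .report_row("similarity_hits",
                                          length(s1$retained),
                                          length(s2$discarded))
  seqs <- extractTuSequences(s2$retained, genome)
  s3 <- dropCodingByOrf(s2$retained, seqs, thresholds$max_orf_aa)
  rep_rows$long_orf <- .report_row("long_orf", length(s2$retained),
                                   length(s3$discarded))
  s4 <- dropShort(s3$retained, thresholds$min_length_bp)
  rep_rows$short_length <- .report_row("short_length", length(s3$retained),
                                       length(s4$discarded))
  s5 <- applyCodingPotentialFilter(s4$retained, scores,
                                   thresholds$coding_score_cutoff)
  rep_rows$coding_potential <- .report_row("coding_potential",
                                           length(s4$retained),
                                           length(s5$discarded))
  s6 <- applyHitFilter(s5$retained, mirnaHits, thresholds$evalue_cutoff)
  surv <- s5$retained
  surv$mirna_hit <- surv$tu_id %in% s6$discarded$tu_id
  if (mirnaFilterMode == "discard") {
    n_disc <- length(s6$discarded)
    surv <- surv[!surv$mirna_hit]
  } else {
    n_disc <- 0L
  }
  rep_rows$mirna_screen <- .report_row("mirna_screen", length(s5$retained),
                                       n_disc)

  report <- do.call(rbind, unname(rep_rows))
  new("LincRNACascade",
      candidates = surv,
      sequences = seqs[surv$tu_id],
      report = report,
      thresholds = thresholds)
}
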