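## File readers/writers for every format the pipeline touches. Coordinates
## are 1-based inclusive throughout; conversions (none are needed for the
## supported formats) would happen here and only here.

STAGES <- c("M", "P", "FB")

outfmt6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

.is_blank_annotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  all(grepl("^\\s*(#|$)", lines))
}

.check_nine_columns <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^\\s*(#|$)", lines)
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 0L)
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1L]]
    stop(sprintf("malformed annotation line %d in '%s': expected 9 tab-separated fields, found %d",
                 bad, path, nf[which(nf != 9L)[1L]]), call. = FALSE)
  }
  invisible(TRUE)
}

.empty_features <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(feature_id = character(0), role = character(0),
                         stage = character(0))
  gr
}

#' Read gene models (GFF3) or assembled transcripts (GTF)
#'
#' Reads an annotation file into a \code{GRanges} of genomic features with
#' metadata columns \code{feature_id}, \code{role} and \code{stage}.
#' GFF3 files supply gene models: rows of type \code{gene} become features
#' with role \code{"gene_model"}. GTF files supply assembled transcripts:
#' \code{exon} rows are grouped on \code{transcript_id} and each transcript
#' becomes one feature spanning min(start)..max(end) of its exons (introns
#' included — this is the genome footprint a transcript unit occupies),
#' with role \code{"transcript"}.
#'
#' @param path file path.
#' @param dialect \code{"GFF3"} or \code{"GTF"}.
#' @param stage optional stage label (\code{"M"}, \code{"P"} or \code{"FB"})
#'   attached to every returned feature; used to tag per-stage transcript
#'   sets before pooling.
#' @return \code{GRanges} with 1-based inclusive coordinates; empty (but
#'   well-formed) for a file with no records.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines("c1\tsim\tgene\t100\t500\t.\t+\t.\tID=g1", gff)
#' readAnnotation(gff, "GFF3")
#' @export
readAnnotation <- function(path, dialect = c("GFF3", "GTF"), stage = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  if (!is.null(stage)) stage <- match.arg(stage, STAGES)
  if (.is_blank_annotation(path)) return(.empty_features())
  .check_nine_columns(path)
  gr <- rtracklayer::import(path, format = tolower(dialect))
  if (dialect == "GFF3") {
    if ("type" %in% names(mcols(gr)) && any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
    out <- granges(gr)
    mcols(out) <- DataFrame(feature_id = ids, role = "gene_model",
                            stage = if (is.null(stage)) NA_character_ else stage)
  } else {
    if ("type" %in% names(mcols(gr)) && any(gr$type == "exon"))
      gr <- gr[gr$type == "exon"]
    if (is.null(gr$transcript_id))
      stop(sprintf("GTF file '%s' lacks transcript_id attributes", path))
    sp <- split(granges(gr), as.character(gr$transcript_id))
    spans <- unlist(range(sp))
    out <- spans
    mcols(out) <- DataFrame(feature_id = names(spans), role = "transcript",
                            stage = if (is.null(stage)) NA_character_ else stage)
    names(out) <- NULL
    out <- sort(out, ignore.strand = TRUE)
  }
  .validate_features(out, path)
  out
}

.validate_features <- function(gr, path = "<features>") {
  if (length(gr) == 0L) return(invisible(gr))
  if (any(start(gr) < 1L))
    stop(sprintf("invalid coordinates in '%s': start < 1", path))
  if (anyDuplicated(gr$feature_id))
    stop(sprintf("duplicate feature_id in '%s': %s", path,
                 paste(unique(gr$feature_id[duplicated(gr$feature_id)]),
                       collapse = ", ")))
  invisible(gr)
}

#' Write genomic features back to GFF3 or GTF
#'
#' Inverse of \code{\link{readAnnotation}}: gene-model features are written
#' as GFF3 \code{gene} rows; transcript features as single-exon GTF rows.
#' Coordinates and strands round-trip exactly.
#'
#' @param features \code{GRanges} as returned by \code{readAnnotation}.
#' @param path output file path.
#' @param dialect \code{"GFF3"} or \code{"GTF"}.
#' @return the path, invisibly.
#' @export
writeAnnotation <- function(features, path, dialect = c("GFF3", "GTF")) {
  dialect <- match.arg(dialect)
  gr <- granges(features)
  if (dialect == "GFF3") {
    mcols(gr) <- DataFrame(source = "lincFinder", type = "gene",
                           ID = features$feature_id,
                           Name = features$feature_id)
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    mcols(gr) <- DataFrame(source = "lincFinder", type = "exon",
                           transcript_id = features$feature_id,
                           gene_id = features$feature_id)
    rtracklayer::export(gr, path, format = "gtf")
  }
  invisible(path)
}

#' Read a 12-column tabular similarity hit file
#'
#' Parses the standard 12-column tabular output dialect
#' (\code{qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore}); e-values are parsed as reals including scientific
#' notation. Query ids are expected to reference transcript-unit ids.
#'
#' @param path file path; an empty file yields a 0-row table.
#' @return \code{data.frame} with the 12 standard columns.
#' @export
readHits <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), 12), outfmt6_cols))
    num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
             "sstart", "send", "evalue", "bitscore")
    out[num] <- lapply(out[num], as.numeric)
    return(out)
  }
  nf <- vapply(strsplit(lines, "\t", fixed = TRUE), length, 0L)
  if (any(nf != 12L))
    stop(sprintf("malformed hit file '%s': expected 12 tab-separated columns, line %d has %d",
                 path, which(nf != 12L)[1L], nf[nf != 12L][1L]))
  out <- read.delim(text = lines, header = FALSE, col.names = outfmt6_cols,
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$evalue)) || any(out$evalue < 0))
    stop(sprintf("hit file '%s' contains invalid e-values", path))
  out
}

#' Read per-strand coding-potential scores
#'
#' TSV with header \code{query_id}, \code{plus_score}, \code{minus_score}:
#' one row per scored transcript unit with the coding-potential score of
#' each strand. A TU is later deemed non-coding only if both scores are
#' below zero.
#'
#' @param path file path.
#' @return \code{data.frame(query_id, plus_score, minus_score)}.
#' @export
readCodingScores <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_id", "plus_score", "minus_score")
  if (!all(need %in% names(out)))
    stop(sprintf("coding-score file '%s' must have columns %s", path,
                 paste(need, collapse = ", ")))
  if (any(is.na(out$plus_score)) || any(is.na(out$minus_score)))
    stop(sprintf("coding-score file '%s' has missing strand scores", path))
  out[need]
}

#' Read a qPCR Ct table
#'
#' TSV with header \code{gene_id}, \code{stage}, \code{replicate},
#' \code{ct}. Stages are restricted to \code{M} (mycelia), \code{P}
#' (primordia) and \code{FB} (fruiting bodies). Undetected wells are encoded
#' as the literal \code{"ND"} and imputed to cycle 40 at parse time, so
#' downstream arithmetic never sees missing values; any numeric Ct must lie
#' in [0, 40].
#'
#' @param path file path.
#' @param reference_gene_id id of the normalizer gene (default
#'   \code{"GAPDH"}); attached as the \code{"reference_gene_id"} attribute.
#' @return \code{data.frame(gene_id, stage, replicate, ct)} with numeric Ct.
#' @export
readCtTable <- function(path, reference_gene_id = "GAPDH") {
  out <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(ct = "character"))
  need <- c("gene_id", "stage", "replicate", "ct")
  if (!all(need %in% names(out)))
    stop(sprintf("Ct table '%s' must have columns %s", path,
                 paste(need, collapse = ", ")))
  bad_stage <- setdiff(unique(out$stage), STAGES)
  if (length(bad_stage))
    stop(sprintf("Ct table '%s' has unknown stage label(s): %s", path,
                 paste(bad_stage, collapse = ", ")))
  ct <- out$ct
  nd <- ct == "ND"
  ct[nd] <- "40"
  ct <- suppressWarnings(as.numeric(ct))
  if (any(is.na(ct)))
    stop(sprintf("Ct table '%s' has non-numeric Ct values other than 'ND'", path))
  if (any(ct > 40) || any(ct < 0))
    stop(sprintf("Ct table '%s' has Ct values outside [0, 40]", path))
  out$ct <- ct
  out <- out[need]
  attr(out, "reference_gene_id") <- reference_gene_id
  out
}

#' Read an MRA band table
#'
#' TSV with header \code{lincrna_id}, \code{stage} (a stage label or
#' \code{"pooled"}), \code{lane} (\code{P4a}, \code{P4b} or \code{Pc}),
#' \code{expected_size} (bp) and \code{observed_sizes} (semicolon-separated
#' bp sizes; empty for no band).
#'
#' @param path file path.
#' @return \code{data.frame} with \code{observed_sizes} parsed into a list
#'   column of numeric vectors.
#' @export
readBandTable <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(observed_sizes = "character"))
  need <- c("lincrna_id", "stage", "lane", "expected_size", "observed_sizes")
  if (!all(need %in% names(out)))
    stop(sprintf("band table '%s' must have columns %s", path,
                 paste(need, collapse = ", ")))
  bad <- setdiff(unique(out$lane), c("P4a", "P4b", "Pc"))
  if (length(bad))
    stop(sprintf("band table '%s' has unknown lane(s): %s", path,
                 paste(bad, collapse = ", ")))
  obs <- strsplit(ifelse(is.na(out$observed_sizes), "", out$observed_sizes),
                  ";", fixed = TRUE)
  out$observed_sizes <- lapply(obs, function(x) as.numeric(x[nzchar(x)]))
  out
}
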