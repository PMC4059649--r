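#' LincRNACandidate cascade results
#'
#' \code{LincRNACascade} holds the outcome of a full lincRNA filter cascade:
#' the surviving candidate transcript units as a \code{GRanges} (with member
#' lists and per-filter provenance in the metadata columns), their extracted
#' nucleotide sequences, the per-stage cascade bookkeeping table, and the
#' thresholds the run used.
#'
#' @slot candidates \code{GRanges} of surviving TUs. Metadata columns:
#'   \code{tu_id}, \code{members} (\code{CharacterList} of member feature
#'   ids), \code{contains_gene_model}, \code{longest_orf_aa},
#'   \code{plus_score}, \code{minus_score}, \code{mirna_hit}.
#' @slot sequences \code{DNAStringSet} named by \code{tu_id} (plus-strand
#'   genomic sequence of each candidate span).
#' @slot report \code{data.frame} with columns \code{stage}, \code{n_input},
#'   \code{n_discarded}, \code{n_retained}; one row per filter stage in
#'   cascade order.
#' @slot thresholds named \code{list} echoing the filter thresholds
#'   (see \code{\link{defaultFilterThresholds}}).
#'
#' @seealso \code{\link{runCascade}}, \code{\link{candidates}},
#'   \code{\link{cascadeReport}}, \code{\link{lincSequences}}
#' @aliases LincRNACascade-class
#' @exportClass LincRNACascade
setClass("LincRNACascade",
  representation(
    candidates = "GRanges",
    sequences = "DNAStringSet",
    report = "data.frame",
    thresholds = "list"
  )
)

setValidity("LincRNACascade", function(object) {
  msg <- character(0)
  rep <- object@report
  need <- c("stage", "n_input", "n_discarded", "n_retained")
  if (!all(need %in% names(rep))) {
    msg <- c(msg, sprintf("report must have columns %s",
                          paste(need, collapse = ", ")))
  } else if (nrow(rep) > 0L) {
    if (any(rep$n_input != rep$n_discarded + rep$n_retained))
      msg <- c(msg, "report bookkeeping violated: n_input != n_discarded + n_retained")
    if (nrow(rep) > 1L &&
        any(rep$n_retained[-nrow(rep)] != rep$n_input[-1L]))
      msg <- c(msg, "report chaining violated: n_retained[k] != n_input[k+1]")
  }
  ids <- mcols(object@candidates)$tu_id
  if (is.null(ids) && length(object@candidates) > 0L) {
    msg <- c(msg, "candidates must carry a tu_id metadata column")
  } else if (!is.null(ids)) {
    if (anyDuplicated(ids))
      msg <- c(msg, "candidate tu_ids must be unique")
    if (!setequal(names(object@sequences), ids))
      msg <- c(msg, "sequence names must match candidate tu_ids")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn LincRNACascade-class compact summary of the run
#' @param object a \code{LincRNACascade}
#' @export
setMethod("show", "LincRNACascade", function(object) {
  rep <- object@report
  n0 <- if (nrow(rep)) rep$n_input[1L] else 0L
  cat("LincRNACascade object\n")
  cat(sprintf("  %d transcript units in -> %d lincRNA candidates out\n",
              n0, length(object@candidates)))
  for (i in seq_len(nrow(rep))) {
    cat(sprintf("  %-18s discarded %4d, retained %4d\n",
                rep$stage[i], rep$n_discarded[i], rep$n_retained[i]))
  }
  if (length(object@candidates)) {
    w <- width(object@candidates)
    cat(sprintf("  candidate lengths: %d-%d bp (mean %.0f bp)\n",
                min(w), max(w), mean(w)))
  }
  invisible(NULL)
})

#' Accessors for LincRNACascade objects
#'
#' \code{candidates} returns the surviving transcript units as a
#' \code{GRanges}; \code{lincSequences} their sequences as a named
#' \code{DNAStringSet}; \code{cascadeReport} the per-stage bookkeeping table;
#' \code{filterThresholds} the thresholds used.
#'
#' @param x a \code{\link{LincRNACascade}} object
#' @return see description of each accessor
#' @examples
#' ds <- simulateLincDataset(seed = 7)
#' res <- runCascade(ds$features, ds$genome, hits = ds$hits,
#'                   scores = ds$scores, mirnaHits = ds$mirna_hits)
#' candidates(res)
#' cascadeReport(res)
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' @rdname candidates
#' @export
setGeneric("lincSequences", function(x) standardGeneric("lincSequences"))

#' @rdname candidates
#' @export
setGeneric("cascadeReport", function(x) standardGeneric("cascadeReport"))

#' @rdname candidates
#' @export
setGeneric("filterThresholds", function(x) standardGeneric("filterThresholds"))

#' @rdname candidates
#' @export
setMethod("candidates", "LincRNACascade", function(x) x@candidates)

#' @rdname candidates
#' @export
setMethod("lincSequences", "LincRNACascade", function(x) x@sequences)

#' @rdname candidates
#' @export
setMethod("cascadeReport", "LincRNACascade", function(x) x@report)

#' @rdname candidates
#' @export
setMethod("filterThresholds", "LincRNACascade", function(x) x@thresholds)
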