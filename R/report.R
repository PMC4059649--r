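## Summary reporting over a finished run: candidate length statistics,
## configuration-class tallies, orientation summaries, expression groups
## and correlation classes.

#' Length statistics of a candidate set
#'
#' @param lengths numeric vector of candidate lengths in bp (possibly
#'   empty).
#' @return list: \code{n}, \code{mean_bp} (rounded to the nearest bp),
#'   \code{min_bp}, \code{max_bp}, \code{pct_gt_1kb} (percentage longer
#'   than 1000 bp, one decimal). For an empty set the statistics are
#'   \code{NA} and \code{n} is 0.
#' @examples
#' lengthStats(c(200, 400, 1200))  # mean 600, 33.3% over 1 kb
#' @export
lengthStats <- function(lengths) {
  if (length(lengths) == 0L)
    return(list(n = 0L, mean_bp = NA_real_, min_bp = NA_real_,
                max_bp = NA_real_, pct_gt_1kb = NA_real_))
  list(n = length(lengths),
       mean_bp = round(mean(lengths)),
       min_bp = min(lengths),
       max_bp = max(lengths),
       pct_gt_1kb = round(100 * mean(lengths > 1000), 1))
}

#' Build a summary report over pipeline outputs
#'
#' Collects, from whichever outputs are supplied: candidate length
#' statistics (from a \code{\link{LincRNACascade}} or a length vector), the
#' cascade bookkeeping table, the apcGene relationship census,
#' configuration-class tallies, unidirectional/bidirectional orientation
#' counts, expression-group sizes and correlation-class counts. All tallies
#' sum to their input counts; nothing is silently dropped.
#'
#' @param cascade a \code{\link{LincRNACascade}} or numeric length vector,
#'   or \code{NULL}.
#' @param assignments output of \code{\link{assignApcGenes}} or \code{NULL}.
#' @param configurations output of \code{\link{classifyConfiguration}} or
#'   \code{NULL}.
#' @param pair_analyses output of \code{\link{analyzeExpressionPairs}} or
#'   \code{NULL}.
#' @return list of class \code{"linc_report"} with elements
#'   \code{length_stats}, \code{cascade}, \code{census},
#'   \code{configuration_tally}, \code{orientation_counts},
#'   \code{group_sizes}, \code{correlation_counts} (absent inputs yield
#'   \code{NULL} entries); printable.
#' @export
lincReport <- function(cascade = NULL, assignments = NULL,
                       configurations = NULL, pair_analyses = NULL) {
  out <- list(length_stats = NULL, cascade = NULL, census = NULL,
              configuration_tally = NULL, orientation_counts = NULL,
              group_sizes = NULL, correlation_counts = NULL)
  if (!is.null(cascade)) {
    if (is(cascade, "LincRNACascade")) {
      out$length_stats <- lengthStats(width(candidates(cascade)))
      out$cascade <- cascadeReport(cascade)
    } else {
      out$length_stats <- lengthStats(as.numeric(cascade))
    }
  }
  if (!is.null(assignments)) out$census <- relationshipCensus(assignments)
  if (!is.null(configurations)) {
    key <- configurationClasses()
    tally <- table(factor(configurations$label, levels = key$label))
    out$configuration_tally <- setNames(as.integer(tally), key$label)
    out$orientation_counts <- c(
      unidirectional = sum(configurations$direction != "bidirectional"),
      bidirectional = sum(configurations$direction == "bidirectional"),
      side_5P = sum(configurations$side == "5P"),
      side_3P = sum(configurations$side == "3P"))
  }
  if (!is.null(pair_analyses)) {
    out$group_sizes <- setNames(
      as.integer(table(factor(pair_analyses$group,
                              levels = c("I", "II", "III")))),
      c("I", "II", "III"))
    out$correlation_counts <- setNames(
      as.integer(table(factor(pair_analyses$correlation_class,
                              levels = c("positive", "negative", "none")))),
      c("positive", "negative", "none"))
  }
  class(out) <- "linc_report"
  out
}

#' @export
print.linc_report <- function(x, ...) {
  cat("lincRNA pipeline report\n")
  if (!is.null(x$length_stats)) {
    ls <- x$length_stats
    cat(sprintf("  candidates: n = %d", ls$n))
    if (ls$n > 0)
      cat(sprintf("; length %d-%d bp, mean %d bp; %.1f%% > 1 kb",
                  ls$min_bp, ls$max_bp, ls$mean_bp, ls$pct_gt_1kb))
    cat("\n")
  }
  if (!is.null(x$cascade)) {
    cat("  cascade:\n")
    print(x$cascade, row.names = FALSE)
  }
  if (!is.null(x$census)) {
    cat(sprintf("  apcGene census: %d distinct apcGenes; 1:2 = %d, 2:1 = %d, n:1 genes = %d\n",
                x$census$total_apcgenes, x$census$one_to_two,
                x$census$two_to_one, length(x$census$n_to_one)))
  }
  if (!is.null(x$configuration_tally)) {
    cat("  configurations:",
        paste(names(x$configuration_tally), x$configuration_tally,
              sep = "=", collapse = " "), "\n")
    cat("  orientation:",
        paste(names(x$orientation_counts), x$orientation_counts,
              sep = "=", collapse = " "), "\n")
  }
  if (!is.null(x$group_sizes))
    cat("  expression groups:",
        paste(names(x$group_sizes), x$group_sizes, sep = "=",
              collapse = " "), "\n")
  if (!is.null(x$correlation_counts))
    cat("  correlation classes:",
        paste(names(x$correlation_counts), x$correlation_counts, sep = "=",
              collapse = " "), "\n")
  invisible(x)
}
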