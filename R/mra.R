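## Orientation calling from RACE-style band patterns. Two gene-specific
## nested PCRs (lanes P4a and P4b) interrogate the two possible strands of
## origin; lane Pc is the template control. The presence/absence pattern of
## P4a/P4b maps to a forward (F), reverse (R), bidirectional (FR) or
## undetected (NONE) call, conditional on a valid control.

#' Judge the presence of an expected band in a lane
#'
#' A band is present iff any observed size is within
#' \code{tolerance_fraction * expected_size} of the expected size. Observed
#' bands outside the tolerance are flagged as nonspecific amplification;
#' they do not contribute to the call.
#'
#' @param observed_sizes numeric vector of observed band sizes in bp
#'   (possibly empty).
#' @param expected_size expected product size in bp.
#' @param tolerance_fraction fractional size tolerance in (0, 1); default
#'   0.2, a gel-resolution-scale window.
#' @return list \code{present} (logical), \code{nonspecific} (logical: any
#'   out-of-tolerance band observed).
#' @examples
#' callBand(c(505), 500)        # present
#' callBand(c(900), 500)        # absent, nonspecific
#' callBand(numeric(0), 500)    # absent
#' @export
callBand <- function(observed_sizes, expected_size, tolerance_fraction = 0.2) {
  if (tolerance_fraction <= 0 || tolerance_fraction >= 1)
    stop("tolerance_fraction must be in (0, 1)")
  if (expected_size <= 0) stop("expected_size must be positive")
  if (length(observed_sizes) && any(observed_sizes <= 0))
    stop("observed band sizes must be positive")
  within <- abs(observed_sizes - expected_size) <=
    tolerance_fraction * expected_size
  list(present = any(within), nonspecific = any(!within))
}

#' Interpret a P4a/P4b/Pc band pattern as an orientation call
#'
#' Requires a present control band (Pc); then the (P4a, P4b) presence
#' pattern maps to: (TRUE, FALSE) -> \code{"F"}; (FALSE, TRUE) ->
#' \code{"R"}; (TRUE, TRUE) -> \code{"FR"}; (FALSE, FALSE) ->
#' \code{"NONE"} (transcript undetected, distinct from a control failure).
#'
#' @param p4a,p4b,pc logical band presences.
#' @return one of \code{"F"}, \code{"R"}, \code{"FR"}, \code{"NONE"}.
#' @examples
#' interpretPattern(TRUE, FALSE, TRUE)   # "F"
#' interpretPattern(TRUE, TRUE, TRUE)    # "FR"
#' @export
interpretPattern <- function(p4a, p4b, pc) {
  stopifnot(is.logical(p4a), is.logical(p4b), is.logical(pc),
            length(p4a) == 1L, length(p4b) == 1L, length(pc) == 1L)
  if (!pc)
    stop("invalid control: Pc band absent, no orientation call can be made")
  if (p4a && p4b) "FR" else if (p4a) "F" else if (p4b) "R" else "NONE"
}

#' Summarize per-stage orientation calls for one locus
#'
#' @param calls named character vector of per-stage calls (1 to 3 stages),
#'   values in \code{F}, \code{R}, \code{FR}, \code{NONE}.
#' @return one of \code{"bidirectional_all_stages"} (every stage FR),
#'   \code{"bidirectional_some_stages"} (FR in some but not all stages),
#'   \code{"unidirectional_consistent"} (a single F or R call in every
#'   stage), \code{"mixed"} (anything else).
#' @examples
#' stageConsistency(c(M = "FR", P = "FR", FB = "FR"))
#' stageConsistency(c(M = "FR", P = "F", FB = "F"))
#' @export
stageConsistency <- function(calls) {
  if (length(calls) == 0L) stop("no stage calls supplied")
  if (!all(calls %in% c("F", "R", "FR", "NONE")))
    stop("calls must be F, R, FR or NONE")
  if (all(calls == "FR")) return("bidirectional_all_stages")
  if (any(calls == "FR")) return("bidirectional_some_stages")
  u <- unique(calls)
  if (length(u) == 1L && u %in% c("F", "R")) return("unidirectional_consistent")
  "mixed"
}

#' Call orientations for every locus/stage in a band table
#'
#' Groups a band table (see \code{\link{readBandTable}}) by lincRNA and
#' stage, judges each lane with \code{\link{callBand}} and interprets the
#' pattern with \code{\link{interpretPattern}}. A missing or absent control
#' lane yields an \code{NA} call flagged \code{invalid_control}; extra
#' out-of-tolerance bands anywhere flag \code{nonspecific}.
#'
#' @param band_table data.frame from \code{\link{readBandTable}}.
#' @param tolerance_fraction see \code{\link{callBand}}.
#' @return \code{data.frame(lincrna_id, stage, call, flags)}.
#' @export
callOrientations <- function(band_table, tolerance_fraction = 0.2) {
  keys <- unique(band_table[c("lincrna_id", "stage")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- band_table[band_table$lincrna_id == keys$lincrna_id[i] &
                        band_table$stage == keys$stage[i], , drop = FALSE]
    lane <- function(id) {
      j <- which(sub$lane == id)
      if (length(j) == 0L)
        return(list(present = FALSE, nonspecific = FALSE, missing = TRUE))
      b <- callBand(sub$observed_sizes[[j[1L]]], sub$expected_size[j[1L]],
                    tolerance_fraction)
      b$missing <- FALSE
      b
    }
    p4a <- lane("P4a"); p4b <- lane("P4b"); pc <- lane("Pc")
    flags <- character(0)
    if (p4a$nonspecific || p4b$nonspecific || pc$nonspecific)
      flags <- c(flags, "nonspecific")
    if (pc$missing || !pc$present) {
      flags <- c(flags, "invalid_control")
      call <- NA_character_
    } else {
      call <- interpretPattern(p4a$present, p4b$present, pc$present)
    }
    data.frame(lincrna_id = keys$lincrna_id[i], stage = keys$stage[i],
               call = call, flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
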