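## qPCR delta-Ct expression profiling: relative expression against a
## reference gene, stage-maximum normalization, lincRNA/apcGene log2-ratio
## groups and Pearson-correlation classes across the three developmental
## stages (M = mycelia, P = primordia, FB = fruiting bodies).

#' Relative expression from a target and reference Ct
#'
#' Standard delta-Ct quantification at 100\% amplification efficiency:
#' \code{2^-(ct - ct_ref)}. Undetected wells enter as the sentinel Ct of 40
#' (applied at parse time), making their relative expression near zero
#' rather than missing.
#'
#' @param ct,ct_ref numeric Ct values (cycles) in [0, 40]; vectorized.
#' @return linear relative expression (dimensionless).
#' @examples
#' relativeExpression(20, 20)  # 1
#' relativeExpression(18, 20)  # 4
#' @export
relativeExpression <- function(ct, ct_ref) {
  if (any(ct < 0 | ct > 40) || any(ct_ref < 0 | ct_ref > 40))
    stop("Ct values must lie in [0, 40]")
  2^(-(ct - ct_ref))
}

#' Build per-gene expression profiles from a Ct table
#'
#' Replicates are averaged on the Ct scale (arithmetic mean of cycles) and
#' their standard deviation is reported on the same scale; the averaged Ct
#' is then normalized against the reference gene's averaged Ct in the same
#' stage via \code{\link{relativeExpression}}.
#'
#' @param ct_table data.frame from \code{\link{readCtTable}} (columns
#'   \code{gene_id}, \code{stage}, \code{replicate}, \code{ct}).
#' @param reference_gene_id the normalizer gene; defaults to the table's
#'   \code{reference_gene_id} attribute, or \code{"GAPDH"}.
#' @return \code{data.frame(gene_id, stage, mean_ct, sd_ct, rel_expr)};
#'   the reference gene itself is included (its \code{rel_expr} is 1 up to
#'   replicate noise).
#' @export
ctProfiles <- function(ct_table, reference_gene_id = NULL) {
  if (is.null(reference_gene_id))
    reference_gene_id <- attr(ct_table, "reference_gene_id") %||% "GAPDH"
  if (!reference_gene_id %in% ct_table$gene_id)
    stop(sprintf("reference gene '%s' not present in the Ct table",
                 reference_gene_id))
  agg <- aggregate(ct ~ gene_id + stage, data = ct_table,
                   FUN = function(x) c(mean = mean(x), sd = sd(x)))
  out <- data.frame(gene_id = agg$gene_id, stage = agg$stage,
                    mean_ct = agg$ct[, "mean"], sd_ct = agg$ct[, "sd"],
                    stringsAsFactors = FALSE)
  ref <- out[out$gene_id == reference_gene_id, ]
  ref_ct <- setNames(ref$mean_ct, ref$stage)
  if (!all(out$stage %in% names(ref_ct)))
    stop("reference gene lacks Ct values for some stages")
  out$rel_expr <- relativeExpression(out$mean_ct, ref_ct[out$stage])
  out[order(out$gene_id, match(out$stage, STAGES)), , drop = FALSE]
}

.profile_vector <- function(profiles, gene_id) {
  sub <- profiles[profiles$gene_id == gene_id, ]
  if (nrow(sub) == 0L) stop(sprintf("no profile for gene '%s'", gene_id))
  v <- setNames(sub$rel_expr, sub$stage)
  missing <- setdiff(STAGES, names(v))
  if (length(missing))
    stop(sprintf("profile for '%s' lacks stage(s): %s", gene_id,
                 paste(missing, collapse = ", ")))
  v[STAGES]
}

#' Normalize an expression profile to its stage maximum
#'
#' Divides each stage value by the profile's maximum so the most abundant
#' stage becomes 1 — the transformation applied before profiles of genes
#' with very different absolute abundances are compared.
#'
#' @param values numeric vector of non-negative stage expression values.
#' @return vector of the same length with maximum 1.
#' @examples
#' normalizeToStageMax(c(2, 4, 1))  # 0.5 1.0 0.25
#' @export
normalizeToStageMax <- function(values) {
  if (any(values < 0)) stop("expression values must be non-negative")
  m <- max(values)
  if (m == 0) stop("all-zero profile: stage-maximum normalization undefined")
  values / m
}

#' Per-stage log2 expression ratios for a lincRNA/apcGene pair
#'
#' @param linc,apc numeric stage-expression vectors on the same stages;
#'   \code{apc} must be strictly positive.
#' @return per-stage \code{log2(linc / apc)}.
#' @examples
#' logRatioProfile(c(16, 2, 1), c(1, 2, 1))  # 4 0 0
#' @export
logRatioProfile <- function(linc, apc) {
  if (length(linc) != length(apc)) stop("profiles differ in length")
  if (any(apc == 0)) stop("apcGene expression of 0: log ratio undefined")
  log2(linc / apc)
}

#' Assign a lincRNA/apcGene pair to an expression-ratio group
#'
#' Group I: the absolute log2 ratio is >= 3.32 (a 10-fold difference) in at
#' least one stage. Group II: the maximum absolute ratio lies strictly
#' between 1 and 3.32 (a 2- to 10-fold difference). Group III: absolute
#' ratios are <= 1 in all stages (less than a two-fold difference).
#'
#' @param ratios numeric vector of finite per-stage log2 ratios.
#' @return \code{"I"}, \code{"II"} or \code{"III"}.
#' @examples
#' assignGroup(c(4.0, 0.5, 1.2))  # "I"
#' assignGroup(c(2.0, 0.1, 0.2))  # "II"
#' assignGroup(c(1.0, 0.3, 0.9))  # "III"
#' @export
assignGroup <- function(ratios) {
  if (any(!is.finite(ratios))) stop("ratios must be finite")
  m <- max(abs(ratios))
  if (m >= 3.32) "I" else if (m > 1) "II" else "III"
}

#' Pearson correlation of two stage-expression profiles
#'
#' The standard product-moment coefficient. With a constant profile the
#' coefficient is undefined and \code{NA} is returned (reported, not an
#' error): a flat profile carries no shape to correlate.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return r in [-1, 1], or \code{NA} if either vector is constant.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  if (length(x) < 3L) stop("need at least 3 stages")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Classify a correlation coefficient
#'
#' \code{positive} iff r > 0.8 (strict), \code{negative} iff r < -0.8
#' (strict), else \code{none}; an undefined (NA) coefficient is classified
#' \code{none}.
#'
#' @param r numeric coefficient or \code{NA}.
#' @return \code{"positive"}, \code{"negative"} or \code{"none"}.
#' @examples
#' classifyCorrelation(0.95)   # positive
#' classifyCorrelation(0.8)    # none (strict threshold)
#' @export
classifyCorrelation <- function(r) {
  if (is.na(r)) return("none")
  if (r > 0.8) "positive" else if (r < -0.8) "negative" else "none"
}

#' Full expression analysis of lincRNA/apcGene pairs
#'
#' For each pair: per-stage log2 ratios of lincRNA to apcGene expression,
#' the ratio group (I/II/III), the Pearson correlation of the two
#' stage profiles, and its class. The correlation is computed on
#' stage-maximum-normalized profiles (the normalization leaves Pearson's r
#' unchanged, so this is presentational); the log2 ratios are computed from
#' raw relative expression by default — set \code{normalized_ratio = TRUE}
#' to compute them from stage-normalized profiles instead.
#'
#' @param profiles data.frame from \code{\link{ctProfiles}}.
#' @param pairs \code{data.frame(lincrna_id, apcgene_id)}.
#' @param normalized_ratio compute log2 ratios on stage-normalized
#'   profiles (default \code{FALSE}).
#' @return data.frame with one row per pair: ids, \code{log2_ratio_M/P/FB},
#'   \code{group}, \code{pearson_r}, \code{correlation_class},
#'   \code{r_undefined} flag.
#' @export
analyzeExpressionPairs <- function(profiles, pairs, normalized_ratio = FALSE) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    linc <- .profile_vector(profiles, pairs$lincrna_id[i])
    apc <- .profile_vector(profiles, pairs$apcgene_id[i])
    rl <- if (normalized_ratio) normalizeToStageMax(linc) else linc
    ra <- if (normalized_ratio) normalizeToStageMax(apc) else apc
    ratios <- logRatioProfile(rl, ra)
    r <- if (max(linc) > 0 && max(apc) > 0)
      pearsonR(normalizeToStageMax(linc), normalizeToStageMax(apc))
    else NA_real_
    data.frame(lincrna_id = pairs$lincrna_id[i],
               apcgene_id = pairs$apcgene_id[i],
               log2_ratio_M = ratios[["M"]], log2_ratio_P = ratios[["P"]],
               log2_ratio_FB = ratios[["FB"]],
               group = assignGroup(ratios),
               pearson_r = r,
               correlation_class = classifyCorrelation(r),
               r_undefined = is.na(r),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
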