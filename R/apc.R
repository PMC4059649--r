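## Adjacent protein-coding gene (apcGene) context: nearest flanking genes,
## relationship cardinalities, and the six positional/orientational
## configuration classes of a lincRNA relative to its apcGene.

#' The six lincRNA/apcGene configuration classes
#'
#' A lincRNA sits on the 5' or the 3' side of its apcGene (upstream or
#' downstream of the gene's transcription start, in the gene's strand
#' frame) and is transcribed in the same direction as the gene, the
#' opposite direction, or bidirectionally — six classes in all.
#'
#' @return \code{data.frame(label, side, direction)} with the canonical
#'   label of each class (\code{C1_5P_SAME} ... \code{C6_3P_BIDIR}).
#' @export
configurationClasses <- function() {
  data.frame(
    label = c("C1_5P_SAME", "C2_5P_OPP", "C3_5P_BIDIR",
              "C4_3P_SAME", "C5_3P_OPP", "C6_3P_BIDIR"),
    side = rep(c("5P", "3P"), each = 3),
    direction = rep(c("same", "opposite", "bidirectional"), 2),
    stringsAsFactors = FALSE)
}

#' Assign each lincRNA its adjacent protein-coding genes
#'
#' For every lincRNA, finds the nearest gene model entirely to its left
#' (the gene with maximal end among genes ending before the lincRNA starts)
#' and entirely to its right (minimal start among genes starting after the
#' lincRNA ends) on the same contig. Distances are edge-to-edge gaps in bp
#' (0 if bookended). A lincRNA at a contig end has no gene on that side
#' (\code{NA}). Ties at equal distance are broken toward the gene with the
#' smaller start coordinate and flagged.
#'
#' @param lincrnas \code{GRanges} of lincRNA candidates with a \code{tu_id}
#'   (or \code{feature_id}) metadata column.
#' @param genes \code{GRanges} of gene models with \code{feature_id}; a
#'   gene overlapping a lincRNA is an error (candidates are intergenic by
#'   construction).
#' @return \code{data.frame(lincrna_id, upstream_gene, upstream_distance,
#'   downstream_gene, downstream_distance, tie)}; "upstream"/"downstream"
#'   are genomic left/right.
#' @examples
#' g <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1000, 5000),
#'                                                    c(2000, 6000)),
#'                             strand = c("+", "-"))
#' g$feature_id <- c("g1", "g2"); g$role <- "gene_model"
#' l <- GenomicRanges::GRanges("c1", IRanges::IRanges(3000, 3500))
#' l$tu_id <- "linc1"
#' assignApcGenes(l, g)  # g1 at gap 999, g2 at gap 1499
#' @export
assignApcGenes <- function(lincrnas, genes) {
  linc_ids <- lincrnas$tu_id %||% lincrnas$feature_id
  if (is.null(linc_ids)) stop("lincrnas must carry a tu_id or feature_id column")
  if (length(lincrnas) &&
      length(findOverlaps(lincrnas, genes, ignore.strand = TRUE)))
    stop("gene model overlaps a lincRNA: candidates must be intergenic")
  res <- lapply(seq_along(lincrnas), function(i) {
    ctg <- as.character(seqnames(lincrnas))[i]
    g <- genes[as.character(seqnames(genes)) == ctg]
    left <- g[end(g) < start(lincrnas)[i]]
    right <- g[start(g) > end(lincrnas)[i]]
    tie <- FALSE
    if (length(left)) {
      best <- max(end(left))
      cand <- which(end(left) == best)
      if (length(cand) > 1L) {
        tie <- TRUE
        cand <- cand[which.min(start(left)[cand])]
      }
      up_gene <- left$feature_id[cand]
      up_dist <- start(lincrnas)[i] - best - 1L
    } else {
      up_gene <- NA_character_; up_dist <- NA_integer_
    }
    if (length(right)) {
      best <- min(start(right))
      cand <- which(start(right) == best)
      if (length(cand) > 1L) tie <- TRUE
      cand <- cand[which.min(start(right)[cand])]
      down_gene <- right$feature_id[cand]
      down_dist <- best - end(lincrnas)[i] - 1L
    } else {
      down_gene <- NA_character_; down_dist <- NA_integer_
    }
    data.frame(lincrna_id = linc_ids[i],
               upstream_gene = up_gene, upstream_distance = up_dist,
               downstream_gene = down_gene, downstream_distance = down_dist,
               tie = tie, stringsAsFactors = FALSE)
  })
  if (length(res) == 0L)
    return(data.frame(lincrna_id = character(0),
                      upstream_gene = character(0),
                      upstream_distance = integer(0),
                      downstream_gene = character(0),
                      downstream_distance = integer(0),
                      tie = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Census of lincRNA/apcGene relationship cardinalities
#'
#' A lincRNA flanked by two distinct genes is in a 1:2 relationship; a gene
#' that is the apcGene of two lincRNAs (one on each side) is in a 2:1
#' relationship; a gene shared as apcGene by n >= 2 lincRNAs (consecutive
#' lincRNAs with no intervening gene — automatic under nearest-gene
#' assignment) is in an n:1 relationship.
#'
#' @param assignments output of \code{\link{assignApcGenes}}.
#' @return list: \code{one_to_two} (count of lincRNAs with two distinct
#'   apcGenes), \code{two_to_one} (count of genes adjacent to exactly two
#'   lincRNAs), \code{n_to_one} (named integer vector, genes shared by
#'   >= 2 lincRNAs and their n), \code{total_apcgenes} (distinct apcGenes).
#' @export
relationshipCensus <- function(assignments) {
  if (nrow(assignments) == 0L)
    return(list(one_to_two = 0L, two_to_one = 0L,
                n_to_one = setNames(integer(0), character(0)),
                total_apcgenes = 0L))
  up <- assignments$upstream_gene
  down <- assignments$downstream_gene
  one_to_two <- sum(!is.na(up) & !is.na(down) & up != down)
  per_linc <- mapply(function(u, d) unique(stats::na.omit(c(u, d))),
                     up, down, SIMPLIFY = FALSE)
  counts <- table(unlist(per_linc))
  n_to_one <- counts[counts >= 2L]
  list(one_to_two = one_to_two,
       two_to_one = sum(counts == 2L),
       n_to_one = setNames(as.integer(n_to_one), names(n_to_one)),
       total_apcgenes = length(counts))
}

#' Classify lincRNA/apcGene pairs into configuration classes
#'
#' Determines, for each pair, on which side of the apcGene the lincRNA
#' sits — 5' if it lies upstream of the gene's transcription start (to the
#' genomic left of a \code{+} gene, to the right of a \code{-} gene),
#' else 3' — and in which direction it is transcribed relative to the gene:
#' \code{bidirectional} if the orientation call is \code{FR}, otherwise
#' \code{same}/\code{opposite} by comparing the lincRNA's called genomic
#' strand (\code{F} = \code{+}, \code{R} = \code{-}) to the gene's strand.
#'
#' @param lincrnas \code{GRanges} of lincRNAs (one per pair).
#' @param genes \code{GRanges} of the paired apcGenes, parallel to
#'   \code{lincrnas}; strand must be \code{+} or \code{-}.
#' @param orientation character vector of orientation calls per pair:
#'   \code{"F"}, \code{"R"} or \code{"FR"}.
#' @return \code{data.frame(side, direction, label)}; labels as in
#'   \code{\link{configurationClasses}}.
#' @examples
#' l <- GenomicRanges::GRanges("c1", IRanges::IRanges(500, 900))
#' g <- GenomicRanges::GRanges("c1", IRanges::IRanges(2000, 3000),
#'                             strand = "+")
#' classifyConfiguration(l, g, "F")   # C1_5P_SAME
#' @export
classifyConfiguration <- function(lincrnas, genes, orientation) {
  if (length(lincrnas) != length(genes) ||
      length(genes) != length(orientation))
    stop("lincrnas, genes and orientation must be parallel")
  if (!all(orientation %in% c("F", "R", "FR")))
    stop("orientation must be one of 'F', 'R', 'FR'")
  gs <- as.character(strand(genes))
  if (any(!gs %in% c("+", "-")))
    stop("apcGene strand must be '+' or '-'")
  if (length(lincrnas) == 0L)
    return(data.frame(side = character(0), direction = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  same_contig <- as.character(seqnames(lincrnas)) ==
    as.character(seqnames(genes))
  if (!all(same_contig)) stop("paired lincRNA and apcGene on different contigs")
  left <- end(lincrnas) < start(genes)
  right <- start(lincrnas) > end(genes)
  if (any(!(left | right)))
    stop("lincRNA overlaps its apcGene: pair violates the intergenic precondition")
  side <- ifelse(left == (gs == "+"), "5P", "3P")
  linc_strand <- c(F = "+", R = "-")[orientation]
  direction <- ifelse(orientation == "FR", "bidirectional",
                      ifelse(linc_strand == gs, "same", "opposite"))
  key <- configurationClasses()
  label <- key$label[match(paste(side, direction),
                           paste(key$side, key$direction))]
  data.frame(side = side, direction = direction, label = label,
             stringsAsFactors = FALSE, row.names = NULL)
}
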