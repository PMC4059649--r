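suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

## Independent oracles used to cross-check the implementation. Each is a
## deliberately naive re-implementation (exhaustive scan, brute force,
## direct formula) kept free of the code paths it checks.

## longest ATG-initiated ORF by scanning every start position on both strands
orf_oracle <- function(s) {
  s <- toupper(s)
  stops <- c("TAA", "TAG", "TGA")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  best <- 0L
  for (str in c(s, rc)) {
    n <- nchar(str)
    for (i in seq_len(max(0L, n - 2L))) {
      if (substr(str, i, i + 2L) != "ATG") next
      len <- NA_integer_
      j <- i + 3L
      while (j + 2L <= n) {
        if (substr(str, j, j + 2L) %in% stops) {
          len <- (j - i) %/% 3L
          break
        }
        j <- j + 3L
      }
      if (is.na(len)) len <- (n - i + 1L) %/% 3L
      best <- max(best, len)
    }
  }
  best
}

## brute-force transitive-closure partition of intervals into clusters;
## returns a canonical string signature of the partition
merge_oracle_signature <- function(contig, start, end, id) {
  n <- length(start)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- contig[i] == contig[j] &&
        start[i] <= end[j] && start[j] <= end[i]
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  groups <- split(id, comp)
  paste(sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                    "")), collapse = "|")
}

signature_of_tus <- function(tus) {
  paste(sort(vapply(as.list(tus$members),
                    function(g) paste(sort(g), collapse = ","), "")),
        collapse = "|")
}

## nearest flanking genes by linear scan over a plain data.frame
apc_oracle <- function(linc_start, linc_end, gene_start, gene_end, gene_id) {
  up_i <- which(gene_end < linc_start)
  down_i <- which(gene_start > linc_end)
  up <- if (length(up_i)) {
    k <- up_i[order(-gene_end[up_i], gene_start[up_i])][1]
    list(gene = gene_id[k], dist = linc_start - gene_end[k] - 1L)
  } else list(gene = NA_character_, dist = NA_integer_)
  down <- if (length(down_i)) {
    k <- down_i[order(gene_start[down_i])][1]
    list(gene = gene_id[k], dist = gene_start[k] - linc_end - 1L)
  } else list(gene = NA_character_, dist = NA_integer_)
  list(upstream = up, downstream = down)
}

## direct evaluation of the product-moment formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  num / den
}

## random feature set on a handful of contigs, for merge property tests
random_feature_set <- function(n_max = 50L) {
  n <- sample(seq_len(n_max), 1L)
  contig <- sample(c("cA", "cB"), n, replace = TRUE)
  start <- sample(1:2000, n, replace = TRUE)
  width <- sample(1:300, n, replace = TRUE)
  gr <- GenomicRanges::GRanges(contig,
                               IRanges::IRanges(start, start + width - 1L))
  gr$feature_id <- sprintf("f%03d", seq_len(n))
  gr$role <- sample(c("transcript", "gene_model"), n, replace = TRUE,
                    prob = c(0.8, 0.2))
  gr
}

## reconstruct a pair set realizing given per-configuration-class counts;
## geometry and orientation alternate between the two genomic realizations
## of each class
pairs_from_class_counts <- function(counts) {
  variants <- list(
    C1_5P_SAME  = list(c("left", "+", "F"),  c("right", "-", "R")),
    C2_5P_OPP   = list(c("left", "+", "R"),  c("right", "-", "F")),
    C3_5P_BIDIR = list(c("left", "+", "FR"), c("right", "-", "FR")),
    C4_3P_SAME  = list(c("right", "+", "F"), c("left", "-", "R")),
    C5_3P_OPP   = list(c("right", "+", "R"), c("left", "-", "F")),
    C6_3P_BIDIR = list(c("right", "+", "FR"), c("left", "-", "FR")))
  rows <- list()
  for (lab in names(counts)) {
    for (k in seq_len(counts[[lab]])) {
      v <- variants[[lab]][[(k %% 2L) + 1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        label = lab, geometry = v[1], gene_strand = v[2],
        orientation = v[3], stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  n <- nrow(df)
  contigs <- sprintf("pc%02d", seq_len(n))
  linc_start <- ifelse(df$geometry == "left", 1000L, 8000L)
  lincs <- GenomicRanges::GRanges(contigs,
                                  IRanges::IRanges(linc_start,
                                                   linc_start + 500L))
  genes <- GenomicRanges::GRanges(contigs, IRanges::IRanges(5000L, 6000L),
                                  strand = df$gene_strand)
  list(lincs = lincs, genes = genes, orientation = df$orientation,
       expected_label = df$label)
}
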