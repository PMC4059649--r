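---
title: "Methods: lincRNA discovery, context and expression analysis"
author: "lincFinder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lincRNA discovery, context and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincFinder)
```

# Scope and model

lincFinder implements a desk-scale workflow for identifying long intergenic
non-coding RNAs (lincRNAs) from assembled RNA-Seq transcripts plus a draft
gene annotation, and for characterizing candidates by (i) their nearest
protein-coding neighbours, (ii) strand-of-origin calls from RACE-style band
patterns, and (iii) qPCR expression profiles across three developmental
stages (mycelia `M`, primordia `P`, fruiting bodies `FB`). The operational
definition of a lincRNA is positional and compositional: an intergenic
transcript unit at least 200 bp long, with no open reading frame longer
than 100 amino acids, no significant similarity to known coding or
structural sequences, and negative coding-potential scores on both strands.

Assembly, similarity searching and coding-potential scoring are upstream of
this package: transcripts arrive as GTF, similarity hits as 12-column
tabular files, coding-potential scores as a per-strand TSV. The one
sequence-level computation done natively is the six-frame ORF scan, because
the 100-aa criterion is the load-bearing part of the coding filter and must
be exactly reproducible.

# Transcript units

Features (transcripts pooled across stages, plus gene models) are merged
into transcript units (TUs): connected components of the pairwise-overlap
graph per contig, with the TU span the union hull of its members.
Three choices matter:

* **Strand-agnostic overlap.** The transcript sets this workflow consumes
  come from non-strand-specific libraries, so annotated strands on
  assembled transcripts are not trustworthy for merging; features on
  opposite strands merge if they share a base.
* **Zero-gap policy.** Merging requires at least one shared base;
  bookended features (`end + 1 == start`) stay separate. Without
  experimentally delimited UTRs there is no defensible distance cutoff for
  joining nearby fragments, so none is applied.
* **Pooling before merging.** Per-stage transcript sets are pooled and
  merged once; stage labels are kept on members, and per-stage presence is
  recoverable from member stage tags rather than from separate per-stage TU
  sets.

TU identifiers are deterministic (`TU_<contig>_<start>_<end>`), which makes
runs reproducible and lets side tables reference TUs stably.

# The filter cascade

Order: gene-overlap → similarity hits (Nt/Nr/SP) → long ORF → short length
→ coding potential → miRNA-precursor screen. All six are independent
predicates of a TU, so the surviving set is order-invariant (a property the
test suite asserts); the order only shapes the per-stage bookkeeping, which
is reported as `(stage, n_input, n_discarded, n_retained)` with
`n_input = n_discarded + n_retained` enforced by the result class's
validity method.

Boundary conventions follow the definitions stated above exactly and are
asserted at their boundaries in the tests:

* similarity hits discard on E-value strictly below `1e-5`; a hit at
  exactly `1e-5` does not;
* the ORF filter discards strictly above 100 aa (100 aa is retained);
* the length filter keeps 200 bp exactly;
* the coding-potential filter requires both strand scores strictly below
  zero (a score of exactly 0 discards).

**ORF definition.** The scanner reports the longest ATG-initiated ORF over
both strands and all three frames: codons from the ATG to the codon before
the first in-frame stop, Met included. ORFs that reach the sequence end
without a stop are counted to the last complete codon — the conservative
choice for a filter, since a truncated-but-long ORF is evidence of coding
potential. Codons containing `N` never match ATG or a stop but do count as
ordinary codons inside an ORF. The implementation is checked against an
exhaustive every-start-position oracle on random sequences.

**Length.** The 200-bp filter uses the genomic span of the TU. For
single-exon transcripts (the common case in compact fungal genomes) span
and transcript length coincide; where exon structure is available the
spliced length could be substituted, but the span is the default because it
is what the TU construction defines.

**miRNA-precursor screen.** The screen annotates survivors
(`mirna_hit` column) rather than discarding by default: in the motivating
use case it removes nothing, so its discard semantics are unobservable;
`mirnaFilterMode = "discard"` switches behaviour.

# Adjacent protein-coding genes

For each candidate, the nearest gene entirely to its genomic left and right
become its apcGenes, with edge-to-edge gaps (0 bp if bookended) and `NA` at
contig ends. Ties at equal distance are broken deterministically toward the
smaller start coordinate and flagged. The relationship census counts
lincRNAs with two distinct flanking genes (1:2), genes adjacent to exactly
two lincRNAs (2:1), and genes shared by n ≥ 2 lincRNAs (n:1; under
nearest-gene assignment such lincRNAs are necessarily consecutive).

Configuration classification works in the *gene's* strand frame: a lincRNA
upstream of the gene's transcription start (left of a `+` gene, right of a
`-` gene) is on its 5′ side, otherwise 3′; the direction is `bidirectional`
for an `FR` orientation call, else `same`/`opposite` by comparing the
called genomic strand (`F` = `+`, `R` = `-`) with the gene strand. The six
classes carry canonical labels `C1_5P_SAME` … `C6_3P_BIDIR`; the 12
geometric input cases (left/right × gene strand × call) are enumerated
exhaustively in the tests and each class is reachable. Which of a
candidate's two apcGenes enters pair-level analysis is a user selection —
pair choice is a scientific decision (e.g. pathway membership), not
something the geometry determines.

# Orientation calls from band patterns

Lanes P4a and P4b interrogate forward and reverse transcription; Pc is the
template control. A band is present when an observed size is within a
fractional tolerance of the expected size; the default tolerance of 0.2 is
a gel-resolution-scale default (agarose sizing is rarely better than
10–20%), and out-of-tolerance bands raise a `nonspecific` flag without
affecting the call. The pattern maps `(P4a, P4b)` to `F`, `R`, `FR`, or —
with both absent but a valid control — `NONE`, which is reported as
"undetected" rather than raised as an error, and distinct from a control
failure (absent Pc), which invalidates the call. Per-stage call sets
summarize to bidirectional-in-all-stages, bidirectional-in-some,
consistently unidirectional, or mixed. Pooled-sample and per-stage calls
are treated as separate experiments; conflicts are reported, not resolved.

# Expression analysis

Quantification is standard ΔCt at 100% assumed amplification efficiency:
`2^-(Ct - Ct_ref)` against a GAPDH reference. Replicates are averaged on
the Ct scale (arithmetic mean of cycles; SD reported on the same scale),
then transformed. Undetected wells carry the sentinel Ct of 40, entering
downstream arithmetic as near-zero expression (`2^-20` relative to a Ct-20
reference) rather than as missing values, so profiles with undetected
stages still participate in ratios and correlations.

Pairs are grouped by the maximum absolute per-stage log₂ ratio:
group I at ≥ 3.32 (log₂ 10; a 10-fold difference), group III at ≤ 1 in all
stages, group II between them. The boundaries land in groups I and III
respectively, leaving II the open interval (1, 3.32). The base-2 logarithm
is pinned by the 3.32 ↔ 10-fold equivalence.

Correlation classes use Pearson's r on stage-maximum-normalized profiles
with strict thresholds (`positive` iff r > 0.8, `negative` iff r < −0.8).
Since stage-max normalization is a positive rescaling of each profile, it
leaves r unchanged — a property the tests verify to 1e-12 — so normalizing
is presentational, not substantive. Log ratios default to raw relative
expression (the normalized variant is available via `normalized_ratio`,
and changes ratios by a per-pair constant). With only three stages r is
statistically fragile; it is reported without a p-value, and a constant
profile yields an undefined r, reported as `NA` and classified `none` with
a flag.

# Synthetic data: what it emulates, and what it does not

The generator plants, per contig, alternating genes and non-coding elements
separated by 300–800 bp gaps on 2 × 50 kb contigs by default — gene
density and intergenic spacing in the range of compact fungal genomes.
Genes embed an ATG-initiated ORF of 120–200 aa on their annotated strand;
lincRNA loci are 250–1200 bp, rejection-sampled to carry no ORF over
100 aa on either strand; decoys each violate exactly one filter (150 bp;
an unannotated 120-aa ORF; a planted similarity hit at E = 1e-20; a
positive plus-strand coding score). Base composition is uniform over ACGT
(GC content is configurable but no compositional realism is claimed).
Orientations are planted as F/R/FR with probabilities 0.4/0.4/0.2, in line
with bidirectional loci being the minority.

qPCR simulation draws a lincRNA log₂ profile with a baseline in
[−5, 1] and two stage offsets of magnitude 1.5–4 log₂ units — clearly
stage-regulated profiles, as expected for developmentally dynamic loci. The
apcGene profile is then a positive scaling (planted `positive`, r = 1
exactly at zero noise), a reflection about the profile's midrange
(`negative`, r = −1), or an independent draw. For the independent case one
subtlety matters: with n = 3 the null distribution of r is U-shaped
(density ∝ (1−r²)^(−1/2)), so truly independent profiles exceed |r| = 0.8
in a large fraction of draws and "independent" would not define a
recoverable class. The planted `none` class is therefore rejection-sampled
to |r| ≤ 0.5 — "demonstrably uncorrelated" rather than merely independent.
Replicate noise is Gaussian on the cycle scale; Ct values beyond cycle 40
are recorded as undetected.

Passing on these data shows the logic is right — bookkeeping, boundary
conditions, planted-truth recovery (precision = recall = 1 at zero noise;
correlation-class recovery ≥ 0.95 at 0.25-cycle noise over 500 pairs). It
does not show robustness to what real data add: fragmented and chimeric
assemblies, repeat-driven spurious overlaps, variable amplification
efficiencies, or database-dependent similarity screens. Genome-scale counts
from any particular study depend on those externalities and are not
reproduced here.

# Problem sizes and numerical choices

The test suite runs at deliberately small scale: merge and nearest-gene
oracle comparisons on 200 random instances of ≤ 50 intervals / ≤ 100
genes, ORF oracle comparisons on 100 random sequences up to 600 nt,
cascade runs on genomes of 2 × 50–70 kb with ≤ 25 planted elements, and
500 simulated qPCR pairs — sizes chosen so the full suite completes in
about a minute while still exercising every code path and boundary.
Floating-point tolerances appear only where justified: 1e-12 for the
Pearson invariance (pure arithmetic identity), exact comparison for integer
bookkeeping, and default `testthat` tolerance elsewhere. Degenerate inputs
are defined, not accidental: empty feature sets yield empty results and
all-zero reports; an all-zero expression profile is an error for
normalization; a constant profile is an undefined (not erroneous)
correlation.

# Known limitations

* Natural antisense and intronic ncRNAs are out of reach by construction:
  strand-agnostic merging plus the intergenic requirement restricts
  discovery to lincRNAs.
* The 200-bp filter uses genomic span; for multi-exon transcripts with
  long introns this overestimates transcript length.
* Pearson on three stages has essentially no inferential power; the
  classes are descriptive screens, not hypothesis tests.
* The configuration-class labels C1–C6 are canonical to this package;
  studies using roman numerals may order their classes differently, so
  cross-study comparisons should match on (side, direction), not label.
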