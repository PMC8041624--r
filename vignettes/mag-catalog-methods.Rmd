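---
title: "Methods behind the magcat pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the magcat pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magcat)
```

`magcat` re-implements, as a tested and reusable toolkit, the analytics
used to build large catalogs of metagenome-assembled genomes (MAGs): who
gets in (quality gating), how genomes are grouped into species
(ANI-based dereplication), how the resulting diversity is measured and
ranked on a phylogeny (phylogenetic diversity and relative evolutionary
divergence), and how MAGs are connected to uncultivated viruses and to
secondary-metabolite potential. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic
data generators do and do not emulate.

## Quality gating and MIMAG tiers

A MAG's quality score is its estimated completeness minus five times its
estimated contamination, both taken from an upstream tool such as CheckM
(estimating them is explicitly out of scope here). The catalog gate
requires completeness ≥ 50%, contamination ≤ 5% and score ≥ 50. Published
descriptions of this rule mix strict and inclusive operators for the
score bound; we adopt the inclusive reading on all three bounds, because
that is the form used to describe the released catalogs, and expose each
operator in `mag_thresholds()` so either convention can be enforced. On
continuous inputs the difference affects only measure-zero boundary
cases. The MIMAG `high` tier additionally requires ≥ 90% completeness,
≤ 5% contamination, at least 18 of the 20 standard tRNA isotypes
(supplied as a precomputed count, not inferred from sequence) and the
presence of 5S, 16S and 23S rRNA genes.

## Two-stage ANI with aligned fractions

Pairwise genome distance is computed in the standard two stages: a cheap
MinHash sketch prefilter over all pairs, then an alignment-based ANI
only for pairs estimated near the species threshold.

**Sketching.** Bottom-`s` MinHash over canonical k-mers (`k = 21`,
`s = 10000` by default; the sketch size matches the catalog pipelines
this emulates, the k-mer size is the conventional default for genome
sketching). The hash is a fixed 64-bit splitmix-style mixer with seed
42 — a parameter of the hash family, not a source of randomness — so
sketches are reproducible across runs and machines. The Jaccard index
`j` from the merged bottom-`s` sketch converts to a distance
`d = -ln(2j/(1+j))/k` and an ANI estimate `1 - d`.

**Alignment ANI.** `align_ani()` is a desk-scale anchor-chain aligner,
not a clone of a production whole-genome aligner: k-mers unique in both
genomes (counting both strands, mirroring unique maximal matches) seed
anchors; anchors on the same diagonal within `max_gap` are chained into
gap-free blocks; blocks then claim genome positions greedily by
decreasing length with a symmetric tie-break, so the retained runs are
one-to-one on both genomes and the statistic is exactly symmetric under
argument swap. ANI is identical columns over retained aligned columns;
each aligned fraction (AF) divides aligned bp by that genome's total
residue length.

`max_gap` defaults to 1000 bp. Two anchors on the same diagonal that far
apart are effectively never produced by unrelated sequence (a shared
unique 21-mer at a matching offset is already rare; two of them on one
diagonal is vanishing), while mutation-dense patches between conserved
anchors are exactly the regions a too-small gap would exclude —
excluding them biases ANI upward and AF downward. With the
substitution-only truth model the aligner recovers the planted identity
to well within ±0.005 at 1–10% divergence with AF ≈ 1. Contigs are
concatenated with a sentinel so no k-mer or aligned run crosses a
contig boundary; runs shorter than `min_block` (default `anchor_k`) are
discarded. The aligner is gap-free by construction: genomes with
substantial indel or rearrangement structure will show reduced AF
rather than gapped alignments, which is the conservative direction for
species clustering.

## Species-level OTUs and novelty

Clustering is greedy and centroid-based: genomes are visited by
decreasing quality score (ties broken by ascending identifier, for
determinism); each unassigned genome seeds an OTU and recruits every
unassigned genome within the species threshold (ANI ≥ 0.95) whose
aligned fractions pass. The published filter discards alignments
"covering <30% of either genome"; we read that literally as requiring
AF ≥ 0.30 **of both** genomes and expose `af_mode` for the
either/one-sided variants. Within-catalog recruitment uses an inclusive
ANI bound while novelty against references uses a strict one (matching
the "within 95%" vs ">95%" phrasings); both operators are configurable.
A centroid is `known` only if its best reference exceeds the species
threshold with passing AF, where candidates are ranked by the sketch
prefilter before alignment (`top_n` controls how many are aligned; the
default 1 mirrors the best-hit strategy).

## Tree analytics: PD, RED, rank calibration

Phylogenetic diversity (PD) of a leaf set is the branch length of the
minimal subtree connecting the set to the root; the PD gain of set *a*
over baseline *b* is `(PD(a∪b) − PD(b)) / PD(b)`, and the edge sets
decompose exactly (uniquely-a + b-side = union), which the tests assert.

Relative evolutionary divergence (RED) uses the standard recurrence:
`red(root) = 0`, `red(leaf) = 1`, and for an internal node with parent
RED `p`, branch `d` and mean parent-to-descendant-leaf distance `u`,
`red = p + (d/u)(1 − p)`. The source describing the catalog method
names RED but not the recurrence; we take it from the taxonomy-database
method it cites. Degenerate zero-length subtrees (`u = 0`) inherit the
parent's RED — the limit of the recurrence as branch lengths go to
zero. RED is clamped at 1, monotone along root-to-leaf paths, and
invariant under uniform branch scaling.

Rank clustering emits a clade at the shallowest node whose RED reaches
the cutoff and whose support exceeds 0.7 (strict, matching ">0.7");
nodes failing the support bound are split into their children, and
uncovered leaves become singletons. Multifurcations are handled
naturally by the traversal; absent support values default to 1 (local
supports are not always present on fixtures), configurable. Calibration
grid-searches cutoffs in (0, 1) — default step 0.001, coarser steps are
used in tests and the acceptance script where the planted optimum is
exactly on the grid — maximizing adjusted mutual information (AMI)
against a reference taxonomy, scored on labelled leaves only while
clustering the full tree; ties go to the smallest cutoff. Whether
calibration should be global or per-domain is not specified by the
source method; the default here is global, and per-domain calibration
is simply two calls on the domain subtrees. AMI is implemented from the
hypergeometric permutation-model definition with natural logarithms and
arithmetic-mean normalization, and is checked against the standard
Python reference implementation to 10⁻⁹ on frozen fixtures. Identical
labelings score 1; constant labelings score 0 by convention. The
marker-gene "centroid gene" rule is `medoid_select()`: the element with
the highest mean off-diagonal identity, ties to the lowest index (the
caller enforces any cap on genomes pooled per OTU, conventionally ten).

Rooting between two leaf sets (e.g. the two prokaryotic domains) places
the root at the midpoint of the unique separating edge and errors if no
single edge separates the sets.

## Virus–host linkage rules

Three linkage routes are implemented with their published filters:

1. **CRISPR spacers.** Arrays are kept with ≥ 3 spacers, mean repeat
   identity to the consensus ≥ 97%, and ≥ 4 Cas proteins in the MAG;
   spacers ≤ 25 bp are then discarded. The consensus repeat is the
   per-column majority over repeats of the modal length (ties
   alphabetical; off-length repeats compared after end-anchored
   trimming) — the sources are silent on the consensus construction, and
   majority rule is the field standard. Protospacer matching accepts a
   spacer substring covering ≥ 95% of the spacer (truncated only at the
   ends) with ≤ 1 mismatch, on either strand (strandedness is not
   specified upstream; both are searched). Whether truncation and the
   mismatch may combine is also unspecified: the default treats them as
   a joint budget, and `strict = TRUE` forbids mismatches in truncated
   matches. "≤1 SNP" and "up to one mismatch" are treated as the same
   rule.
2. **Sequence similarity.** A hit at > 90% identity over > 500 bp marks
   the virus as integrated when the contig is > 1.5× the virus length;
   shorter contigs are discarded as full viral sequences (no host
   information, and plausibly binned by viral composition), and no
   linkage is ever emitted for them.
3. **De novo prophages.** Detector categories 4 and 5 are accepted
   (category 6 — the low-confidence extension — is not, in the default
   route), minus predictions with ≥ 30% of genes carrying a Pfam best
   hit (decayed-prophage signature) or overlap with a known virus.

Aggregation reports per-virus modal host-family agreement, the fraction
of viruses with perfectly consistent families, per-phylum linkage rates
by method, and virus–MAG environment concordance.

## BGC screening and read recruitment

BGC regions (detection is out of scope; regions are inputs) are mapped
to six broad groups — PKS, NRPS, terpene, RiPP, AAmodifier, other —
through a shipped, editable table covering the common detector family
labels; the exact table used for the published counts is not printed
anywhere, so ours is a curated approximation following the groupings
popularized by BGC network tools, and unknown families fall through to
`other` with a warning. Redundancy requires a hit with ≥ 80% query
coverage and ≥ 75% mean identity (inclusive bounds, identity evaluated
per hit); regions touching a contig end (0-based half-open coordinates)
are flagged as likely fragmented.

Read filters drop reads below Q30 mean quality, shorter than 70 bp or
with any ambiguous call, and alignments whose edit distance exceeds 5
per 100 bp of read length — the proportional reading, equivalent to the
"<95% identity" phrasing, applied as a strict comparison. Mapped
fractions divide kept-and-mapped reads by all subsampled reads per
sample; a read counts as mapped to a database when any retained
alignment to it passes the filters (the best-alignment-only variant is
not distinguishable from the published description; "any retained" is
the default here). The fold change between two databases uses an
infinity sentinel for a zero denominator.

## Synthetic data: what it does and does not emulate

All generators are pure functions of (configuration, seed): i.i.d.
genomes at a target GC; per-site substitution with site-level truth (so
Hamming identity is the true ANI; substitution-only by design — with
indels, truth identity would only be defined on matched columns);
fragmentation with length-targeted dropout (completeness truth) and
foreign-contig admixture (contamination truth); planted repeat-spacer
arrays whose spacers are virus substrings with a configured mismatch
count, plus prophage insertions; and random bifurcating trees with
exponential branch lengths whose taxonomy labels are generated by the
package's own rank clustering at planted cutoffs, so calibration has an
exact optimum at the planted value.

The cohorts deliberately emulate the *statistical contracts* the
pipeline assumes, not real metagenomes: no assembly error, no strain
mixtures, no indels or rearrangements, no compositional bias, and
reference pools that are mutated copies rather than independently
assembled genomes. Passing the planted-recovery tests therefore shows
the rules and estimators are implemented correctly, not that the
upstream detectors (binning, CRISPR detection, BGC detection, read
alignment) would perform equally well on real data — those are inputs
by contract.

Problem sizes used in the tests and the acceptance script — 200-kb
genomes for ANI recovery, 30-genome/6-species cohorts, 200-leaf trees,
up to 1,000 spacer-matching trials, 500-linkage concordance cohorts —
are the package's chosen desk-scale study conditions: large enough that
binomial noise sits well inside the asserted tolerances, small enough
to be rerun casually. The catalog-scale headline numbers from the
motivating literature (tens of thousands of genomes against
half-million-genome references) depend on those proprietary inputs and
are not reproducible at this scale; nothing in the test suite claims
them.

## Known limitations

* The aligner is gap-free; divergence estimates are only calibrated for
  the substitution regime (roughly ANI ≥ 0.85).
* Sketch hashes are truncated to 53 bits for exact round-tripping
  through doubles; collisions are negligible at any realistic sketch
  size but the full 64-bit space is not exposed.
* `root_between()` re-roots via the standard phylogenetics machinery,
  which does not guarantee preservation of internal node labels
  (supports) through the re-rooting; supports should be re-read from
  the inference output when rank-clustering a re-rooted tree.
* The BGC family table is an editable approximation; counts by group
  are only as good as the mapping supplied.
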