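---
title: "Methods: lncRNA identification, classification and conservation in lncscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA identification, classification and conservation in lncscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncscout)
```

# Scope and data model

`lncscout` implements the downstream half of a multi-tissue lncRNA study:
it consumes the artifacts an assembly/quantification workflow produces
(reference and assembled GTFs, transcript-by-library expression tables,
BLAST tabular hit tables, ortholog-group tables) and performs
identification, classification, tissue-specificity scoring, co-expression
analysis and cross-species conservation. Read trimming, alignment,
assembly, quantification and alignment-tool execution are out of scope by
design; their outputs are this package's inputs.

Internally all coordinates are 0-based half-open; GTF I/O (1-based
inclusive) converts at the boundary, which keeps length and overlap
arithmetic free of off-by-one cases. A transcript is an ordered list of
disjoint exons on one chromosome and strand; its intron chain is the
ordered list of gaps between consecutive exons, and its spliced length is
the sum of exon lengths. Transcripts violating these invariants (exons on
two strands or chromosomes, overlapping exons) are rejected at parse time
rather than repaired: the pipeline assumes well-formed assemblies and
refuses to guess. Both common GTF attribute dialects (`key "value";` and
`key=value`) are accepted, since reference annotations and assemblers
disagree on this point. Interval overlap and nearest-neighbour queries go
through GenomicRanges/IRanges.

Unstranded (`.`) features are admitted but never take part in a
sense/antisense decision: they can only receive class codes `o` or `u`,
and in positional classification they fall into an explicit
"Unclassified Strand" bucket. This is deliberately conservative — guessing
a strand would silently corrupt every antisense statistic downstream.

# Class codes

Each assembled transcript receives exactly one code from
`{=, j, o, x, s, u}` describing its relationship to the reference, with
fixed precedence `=` > `j` > `o` > `x` > `s` > `u` (same-strand structure
first, opposite-strand relations later, intergenic last):

* `=` — identical intron chain with some same-strand reference transcript.
  Terminal exon boundaries are free to differ: two transcripts with the
  same splice structure but ragged ends are the same transcript as far as
  assembly evidence goes. Mono-exonic transcripts have no chain and can
  never be `=`.
* `j` — shares at least one splice junction with a same-strand reference
  transcript and carries at least one junction absent from every
  same-strand span-overlapping reference transcript: a novel isoform.
* `o` — same-strand exonic overlap (≥ 1 bp) that is neither `=` nor `j`.
  The textbook case is overlap with no matching splice sites. One corner
  needs a decision: a multi-exon query whose junctions are all annotated
  but whose chain matches no single reference transcript (a contained
  sub-isoform). The six-code universe has no "contained" code, and a
  literal reading of the definitions would leave such a query without any
  code; we assign it `o`, the weakest same-strand exonic relation. This
  keeps the classifier total, and the randomized oracle tests enforce the
  same convention.
* `x` — opposite-strand exonic overlap (≥ 1 bp).
* `s` — the query lies entirely inside an intron of an opposite-strand
  reference transcript with no exonic overlap.
* `u` — none of the above: an unknown intergenic transcript. A same-strand
  intron-contained query (no exonic overlap) also lands here, because the
  six-code universe has no sense-intronic code.

Witness transcripts (the `matched_reference_id`) are chosen
deterministically: lexicographically smallest among equally valid
witnesses, and for `j` the reference sharing the most junctions.

# Identification cascade

The lncRNA set is built de novo by four removals applied in a fixed,
reported order: (1) transcripts classed `=` against a **coding-only**
reference — the full annotation's noncoding entries are deliberately left
out so that previously annotated lncRNAs are rediscovered rather than
trusted; (2) mono-exonic transcripts, which are enriched for
transcriptional noise; (3) transcripts with spliced length ≤ 200 bases
(the lncRNA definition is *greater than* 200, so the threshold is strict);
(4) transcripts with any protein-database hit at e-value < 10⁻³. Stages
(2) and (3) commute with each other and with (1) and (4); the
`FilterReport` records the declared order and reconciles counts
(input = removed + surviving) regardless.

Novelty categorization then runs against the **full** annotation:
`previously_annotated` when the intron chain matches an annotated
transcript of any biotype, `novel_locus` when the span overlaps no
annotated transcript at all, `novel_isoform` otherwise. The catch-all
third branch makes the three categories a partition; exonic overlap
without junction sharing (and span overlap inside an annotated intron)
counts as `novel_isoform`, since such a locus is not "a region from which
no annotated transcript originates".

Coding-potential scores are not part of the decision rule; the cascade's
output can carry externally computed scores as annotation only. The
noncoding-database screen (`noncode_overlap`) is reporting, not filtering:
a lncRNA "overlaps" the database when some hit passes e-value < 10⁻⁵,
identity > 50% and query coverage > 50% (all strict), and the
highest-bitscore passing hit is reported.

# Positional classification

Gene coordinates are union spans over each gene's transcripts ("the
transcribed region"). The pairing distance is the gap between spans —
zero when they overlap — and a lncRNA with no gene within 50 kb is
excluded as distal. The window applies to the span gap, not to TSS
distance. Equidistant genes are resolved by smaller distance, then
lexicographically smaller gene id, making runs reproducible. A boundary
convention worth stating: a gene at a gap of exactly 50 kb is still
paired (exclusion requires gap > window).

Paired lncRNAs are classified by three orthogonal axes:

* orientation: sense iff strands are equal;
* location: genic when the spans overlap (gap 0), split into *exonic*
  when any lncRNA exon overlaps any gene exon by ≥ 1 bp, else *intronic*;
  intergenic otherwise, split into *upstream*/*downstream* judged from the
  **gene's** transcriptional direction (a lncRNA physically left of a
  minus-strand gene is downstream);
* containment (genic only): *nested* = lncRNA span inside the gene span,
  *containing* = gene span inside the lncRNA span, *overlapping* =
  partial; equal spans count as nested.

One edge case is resolved in favour of the partition invariant: a gene
falling entirely inside a lncRNA intron produces span overlap with no
lncRNA-exon/gene overlap. We key "genic" on span overlap (distance 0), so
such a pair is genic-intronic-containing rather than intergenic-at-distance-0.

`distal_genome_fraction` computes, by merged-interval arithmetic, the
fraction of genome positions farther than the window from every gene span
(genes expanded by the window, merged, complemented). It is monotone
non-increasing in the window and in the gene set.

# Expression analysis

Spearman's rank correlation is computed for every pair across all
libraries (8 tissues × 2 replicates by default; a per-tissue mode
restricts to one tissue's libraries). No expression cutoff is applied —
every classified pair enters — but pairs where either member is constant
(e.g. all zero) have undefined rank correlation and are excluded from
aggregates with a logged count rather than entered as zero. Gene-level
expression is the sum over the gene's transcripts. Group summaries are
deviations of the group mean from the global mean correlation, so the
size-weighted deviations sum to zero by construction. Distance profiles
of divergent (antisense-upstream) pairs use half-open bins
`[edge, next_edge)`; a distance on an inner edge goes to the upper bin,
and a distance outside all bins is an error, since it indicates a
pairing/window mismatch rather than data.

# Tissue specificity

The tissue specificity index is

$$\tau = \frac{\sum_{i=1}^{N} (1 - x_i)}{N - 1}, \qquad
  x_i = \frac{e_i}{\max_j e_j},$$

over the N tissues of one replicate (each replicate contributes one
library per tissue). τ is 1 for single-tissue expression, 0 for uniform
expression, scale invariant, and monotone in the dominant tissue's level.
All-zero transcripts have undefined τ and never enter specificity calls —
only transcripts expressed at some non-zero level are evaluated.
Replicates are combined as F1 = 2AB/(A+B) (with F1(0,0) = 0 by
continuity); the combined score is reported, but the *call* requires
τ > 0.9 strictly in **every** replicate, with the same argmax tissue in
all replicates. The agreement rule is the conservative resolution of an
underdetermined point — each specific transcript must be assigned one
tissue, and when replicates disagree about the dominant tissue the
transcript is not called rather than arbitrated. Ties at exactly 0.9
fail (the rule is "greater than").

Cutoff curves report, per tissue, the fraction of that tissue's specific
transcripts expressed at or above a sliding level (mean of the tissue's
libraries); they start at 1 and are monotone non-increasing. The paired
genes of specific lncRNAs are scored with the same τ rule on gene-level
sums, giving the tissue-specific gene fraction per tissue. A locus-level
mode is obtained by summing member transcripts before scoring; on planted
data it reproduces the transcript-level calls, which is all the package
asserts about it.

# Conservation

Two independent routes:

* **Reciprocal best hits.** Per query the best hit is the minimal
  e-value, with ties broken by maximal bitscore then lexicographic
  subject id (the tie-break is a determinism choice, nothing more). A
  pair is orthologous when each member is the other's best hit and both
  e-values are below 10⁻⁵. The cutoff is a parameter: the threshold is
  sometimes written ambiguously ("10e-5") in the field, and a single flag
  switches readings.
* **Positional (synteny) conservation.** Only ortholog groups with at
  least one gene in every analysed species enter (mirroring the design of
  keeping complete groups). A lncRNA of species A paired to gene g is
  conserved in species B when g's group contains a B gene that is itself
  paired with a B lncRNA. The matrix diagonal counts each species'
  evaluable lncRNAs (paired gene in a complete group); off-diagonal cells
  can therefore never exceed the row diagonal, and the percentage view
  divides rows by their diagonal. lncRNAs whose paired gene is in no
  complete group are counted separately as unevaluable. Groups in which
  every species contributes a paired lncRNA are reported with full
  membership. The matrix computes all directions; restricting reporting
  to particular directions (e.g. assessing only some species against
  reference annotations) is a presentation choice left to the caller.

# The synthetic study generator

`generate_study()` plants every relationship the pipeline is supposed to
find, then lets the pipeline rediscover it. Its defaults emulate the
structure of a five-species, eight-tissue, two-replicate atlas design.

**Genome layout.** Per species, chromosomes of 1.36 Mb carry 8 coding
genes at a 120 kb pitch with 60 kb margins and a 400 kb gene-free tail.
Neighbouring genes are > 100 kb apart, so a lncRNA placed within 40 kb of
its host gene has that gene as its unambiguous nearest neighbour and only
that gene within the 50 kb window; the tail is > 50 kb from every gene,
so distal-excluded lncRNAs exist by construction. Genes have 3–5 exons
(150–400 bp, introns 500–1500 bp, intron 2 fixed at 3 kb so intronic
lncRNAs fit), and every third gene has a second isoform.

**Planted truth.** Assembled transcripts are built per category: exact
chain copies with ragged ends (`=`), junction-shifted isoforms (`j`),
same-strand exon-overlappers with offset junctions (`o`), antisense
exon-overlappers (`x`), antisense intron-nested transcripts (`s`),
intergenic multi-exon transcripts at 1–40 kb gaps in all four
sense/antisense × up/downstream combinations (`u`), distal transcripts in
the tail, mono-exonic noise, sub-200-base fragments, and transcripts with
protein hits below (removed) or above (kept) the 10⁻³ cutoff. A subset of
intergenic lncRNAs is copied into the reference annotation (planting
`previously_annotated`) or given a shorter annotated sibling sharing one
junction (planting `novel_isoform`). Ortholog groups are indexed by gene
position so group membership is orthologous across species; conserved
lncRNA loci are planted by hosting a lncRNA at the same gene index in
every species for k groups, while every other host index is missing from
at least one species, so exactly k all-species groups exist. The expected
conservation matrix is derivable from the host scheme and stored with the
truth ledger.

**Expression model.** Levels are log-normal: the generator draws a
per-tissue base level and multiplies per-library replicate noise,
`value = exp(meanlog + sd_tissue·z_t·noise) · exp(sd_rep·z_{t,r}·noise)`.
mRNAs use meanlog log 30, lncRNAs log 3 — lncRNAs are expressed lower
than mRNAs, qualitatively matching real data — with spreads 0.4 (tissue)
and 0.25 (replicate). Tissue-specific transcripts use a low base
(log 0.5) multiplied by an enrichment factor of 100 in their tissue, in
both replicates, giving noise-free τ = 1 − 1/100 = 0.99 and τ > 0.9 with
overwhelming probability under default noise. Antisense-upstream lncRNAs
track their host gene's library profile times 0.1 with small log-noise,
planting the elevated divergent-pair correlation; other lncRNAs are
independent of their genes. The master `noise` factor scales every spread:
`noise = 0` gives deterministic levels (uniform across tissues except
planted enrichment), the setting used for exact-recovery tests. A
log-normal was chosen for strictly positive, right-skewed FPKM-like
values; the generator makes no attempt at sequence-level realism, library
size effects, count noise, or correlated tissues, so passing tests
demonstrate algorithmic correctness on well-posed inputs, not robustness
to real-data pathologies.

**Determinism.** One master seed derives per-species and per-component
sub-seeds; identical seeds give byte-identical serialized studies and
pipeline outputs, which the test suite and acceptance script verify by
hashing.

# Problem sizes and numerical choices

The test suite validates the class-code assignment against an exhaustive
pairwise oracle on 500 randomized annotations of up to 50 reference plus
50 query transcripts; positional classification against a brute-force
interval oracle on randomized instances; Spearman against an explicit
average-rank + product-moment oracle at 10⁻¹² on tied data; and τ
properties on 10,000 random vectors. End-to-end recovery runs on a
reduced study (40 genes, ~38 assembled transcripts per species, five
species) whose planted counts keep the whole suite fast while exercising
every category at least twice. The acceptance script uses the full
default study (60 genes, 71 assembled transcripts per species).

Numerical conventions collected in one place: strict inequalities at
every published threshold (length > 200, τ > 0.9, e-value < cutoffs,
identity/coverage > 50); pairing keeps gap ≤ window; distance bins are
half-open; nearest-gene and best-hit ties break lexicographically;
containment ties count as nested; undefined values (all-zero τ, constant
correlation vectors) are excluded and counted, never imputed.

# Limitations

The class-code reconstruction covers the six codes above; rarer
assembler codes (contained, sense-intronic, polymerase run-on) are not
modeled and map onto `o`/`u` as described. Correlation is association,
not regulation: no attempt is made to infer causality or trans-targets.
The conservation analysis transfers annotations through ortholog groups
and is only as good as the groups; paralog-rich groups can overstate
conservation. GO enrichment of associated genes is out of scope — the
package emits the gene lists a user would submit to an enrichment
service.
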