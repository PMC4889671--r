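---
title: "Scoring strain-specific gene content with strainpan"
author: "strainpan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring strain-specific gene content with strainpan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainpan)
library(Biostrings)
```

## The problem

Wild and industrial strains of *Saccharomyces cerevisiae* routinely
carry genes absent from the S288c reference genome. These genes
concentrate in subtelomeric regions, arrive in clusters (sometimes by
horizontal transfer), and are exactly the loci that short-read
assemblies and reference-based annotation handle worst. Analyzing
them requires a set of computations that sit between a genome
assembler and a comparative-genomics interpretation: scoring the
presence of a gene in an assembly without relying on annotation,
reconciling disagreeing annotation pipelines, validating predicted
genes against expression and proteomic evidence, and describing where
in the genome the strain-specific genes live. `strainpan` implements
that layer and ships a synthetic-data generator that plants all of
the relevant structure so each stage is testable against truth.

## The Novelty Metric

For query gene $q$ and genome $G$ in a panel that includes a
reference genome $R$, with $B(q, G)$ the best translated-search bit
score of $q$'s protein against $G$:

$$\mathrm{NM}(q, G) = \frac{B(q, G) - B(q, R)}
                           {\max_{G'} B(q, G')}$$

Properties the implementation guarantees (and the test suite checks):

* $\mathrm{NM}(q, R) = 0$ wherever defined — the reference column of
  a novelty matrix is identically zero.
* Defined values lie in $[-1, 1]$; the value is `NA` exactly when the
  per-query panel maximum is zero (no hit anywhere).
* Scale invariance: multiplying all of a query's bit scores by a
  positive constant leaves the metric unchanged.
* A genome absent from the hit table for a query contributes
  $B = 0$, so "no hit" and "hit below the reporting floor" behave
  identically.

Negative values are possible (a strain whose best hit is weaker than
the reference's) and meaningful; the matrix stores numbers and leaves
color maps to the caller.

### Translated search

The internal hit source emulates a protein-vs-genome search at desk
scale: every contig is translated in all six frames (codons
containing `N` become `X`; trailing partial codons are dropped), each
frame is aligned to the query with Smith–Waterman local alignment
under BLOSUM62 and affine gaps, and the best raw score is converted
to bits with the standard Karlin–Altschul form
$\mathrm{bits} = (\lambda S - \ln K)/\ln 2$. Defaults are the
conventional gapped-protein-search constants: gap existence 11,
extension 1, $\lambda = 0.267$, $K = 0.041$. Two deliberate choices:

* `X` scores 0 against every residue, so ambiguous bases neither
  reward nor penalize an alignment; stop symbols keep their BLOSUM62
  penalty of $-4$, discouraging extension through an in-frame stop.
* Hits with raw score below a floor (default 35, about 18 bits) are
  reported as absent. The floor is a reporting threshold, not an
  inference about any particular search tool's e-value cutoff; it was
  chosen so that random ~15-residue peptides essentially never hit
  random kilobase-scale sequence (the suite checks 100 random
  query/genome pairs), and it is exposed as a parameter.

The alignment engine is `Biostrings::pairwiseAlignment`, whose gap
convention (a gap of length $L$ costs $\mathrm{open} + L \cdot
\mathrm{ext}$) matches the existence/extension convention of the
scoring constants; the test suite verifies it cell-for-cell against
an independent textbook dynamic-programming implementation. Hits can
also be read from standard 12-column tabular search output, in which
case only per-query-per-genome best bit scores are used.

Coordinates are 1-based inclusive on the forward strand at every
user-facing interface (GFF3 and tabular conventions); reverse-frame
alignments are mapped back through the reverse complement.

### Clustering strains by gene content

`cluster_strains()` performs average-linkage hierarchical clustering
on Euclidean distances between strain columns, with `NA` treated as 0
for distance purposes. Columns are sorted lexicographically before
clustering, which fixes the leaf order under ties and makes the
result invariant to input column order. This is a presentation
ordering, not a phylogeny.

## Annotation reconciliation

Two annotation tracks for the same assembly (in practice: one
homology-transfer pipeline and one de novo pipeline) are merged into
a single call set:

1. **Validation.** A model is `valid_coding` iff its oriented
   sequence starts `ATG`, ends in a stop codon, contains no internal
   in-frame stop, and has length divisible by 3; defects are
   enumerated (`no_start`, `no_stop`, `internal_stop`,
   `frame_length`).
2. **Correction.** `correct_orf()` searches within a window (default
   300 bp) of the annotated boundaries, in the annotated frame, for
   the nearest repair: candidate starts are in-frame `ATG` codons;
   for each start the end is the first in-frame stop, required to lie
   within the window of the annotated end. Among valid repairs the
   minimal total boundary displacement wins; ties break toward
   extension. Corrections therefore never change frame and never move
   a boundary beyond the window.
3. **Pairing and precedence.** Models are paired across tracks by
   reciprocal overlap > 50% on the same strand — a standard
   locus-matching heuristic; the threshold is exposed. Within a pair,
   a member that validates wins over one that does not; when both
   validate, a member that validated *without* repair outranks a
   repaired one, and track A wins remaining ties. The no-repair
   preference exists because boundary repair can occasionally lock
   onto a nearer in-frame `ATG` than the true start, and the other
   track's untouched call is then the better estimate. When neither
   member validates, the locus is retained as a `pseudogene`, keeping
   the longer-spanning member (annotation errors truncate; real
   disruptions do not shrink the locus). Unpaired valid models are
   kept from either track; `dubious` labels are carried through
   untouched (they are an imported designation, not something this
   package computes); `tRNA` rows pass through unmodified.

The merge is idempotent, and the status partition
(`valid_coding` / `pseudogene` / `dubious` / `invalid` + tRNA) is
exhaustive and exclusive, both checked by tests.

## Evidence validation

Three per-gene validation methods, with thresholds collected in
`validation_thresholds()`:

* transcript overlap: a transcript mapping uniquely to the locus
  (`n_loci == 1`) covers at least 60% of the gene's genomic span
  (inclusive at 0.60). The fraction is measured on the *gene* span,
  the locus-centric reading; measuring on transcript length is the
  other defensible choice and would differ only for transcripts
  shorter than their gene.
* FPKM: $\mathrm{FPKM} = c \cdot 10^9 / (\ell \cdot N)$ with $c$ the
  fragment count, $\ell$ the gene length, $N$ the per-condition
  library total (computed from the count table); validated iff
  FPKM > 1 (strict) in at least one condition.
* peptides: at least one peptide with q-value < 0.01 (strict) that is
  an exact substring of exactly one predicted protein, that protein
  being the gene's product. Peptides matching two or more proteins
  are ambiguous and validate nothing. Upstream FDR estimation is
  consumed as q-values, never recomputed.

`venn_partition()` counts the eight evidence combinations over a
selected subset (all genes, nondubious, non-reference, non-reference
excluding repeat-flagged genes — the repeat flag is an input, since
repeat masking is upstream of this package); the cells always sum to
the subset size.

`fisher_exact_log()` computes the two-sided Fisher exact test
entirely in log space: hypergeometric terms via `lgamma`, the
two-sided tail as the log-sum-exp of all tables (at fixed margins)
whose probability does not exceed the observed table's, with the
conventional $1 + 10^{-7}$ relative tolerance. The result is finite
for any table — including tables whose p-value underflows a double,
which is the case that motivates the function: the dubious-vs-
nondubious protein-validation table (3225/5920 vs 3/641) has
$\log_{10} p \approx -195.2$. Empty margins return $p = 1$ by
convention. The suite checks 200 random small tables against a full
`dhyper` enumeration and, where p does not underflow, against
`stats::fisher.test`.

## Gene geography

* **Subtelomeres.** A gene is subtelomeric when
  $\min(\mathrm{start} - 1, L - \mathrm{end}) \le s$ with span
  $s = 50$ kbp by default. The boundary is counted inclusive —
  "within 50 kbp" without stated boundary semantics; inclusive is the
  declared choice and is pinned by a test.
* **Missing genes.** A reference gene is missing from a target genome
  iff its best translated-search bit score there falls below a floor
  (default: the search scheme's reporting floor). This
  operationalizes "missing" as "undetectable by homology", which
  deliberately conflates true absence with divergence beyond
  detection; the floor is exposed, and raising it can only grow the
  missing set (monotonicity is tested). Assembly-gap explanations for
  absences are annotation a caller can add; the package does not
  infer them.
* **Nonsyntenic homologs.** A pair is reported when two proteins are
  mutual best hits between the annotated gene sets and their
  neighborhoods disagree: the flanking gene-id sets (up to
  `synteny_flank = 2` genes each side, order-insensitive) share no
  common id. Shared ids are how orthologous context is recognized, so
  this assumes the two annotations use a common gene namespace for
  conserved genes (as any liftover-style annotation does).
* **Clusters.** Maximal runs of flagged genes on one contig with
  inter-gene gaps at most `cluster_max_gap` (default 20 kbp — of the
  order of a few genes' spacing in yeast; exposed because the
  underlying notion of "present in clusters" has no canonical gap)
  and at least 2 members. Each call carries a subtelomeric flag
  judged at its span midpoint.
* **N50** is the largest $L$ such that sequences of length $\ge L$
  sum to at least half the total; permutation-invariant and linear
  under uniform scaling.
* **Reference-guided scaffolding.** Windows sampled every 500 bp
  (length 200, up to 2 mismatches) along each contig are located in
  the reference; a window matching more than one place is discarded
  as repetitive. A contig goes to the chromosome holding the majority
  of its anchors, ordered by median anchor position, oriented by
  majority anchor strand. Contigs with no located anchors are
  reported unplaced, never dropped. Exact-window anchoring assumes
  the contigs derive from a genome close to the reference; for
  diverged genomes the anchor tolerance must be raised or an external
  hit table used.

## The synthetic panel generator

`generate_strain_panel()` builds the study conditions every test runs
under: one reference strain carrying only core genes, a focal derived
strain carrying all planted features, and further derived strains
carrying each novel gene (clusters travel as a unit) with probability
1/2. Its design choices:

* Background DNA is i.i.d. uniform over A/C/G/T and genes are random
  codon sequences between `ATG` and a stop. No biological realism
  beyond the ORF grammar is needed: the quantities under test are
  alignment scores, coordinates, and set memberships.
* Novel genes are generated unrelated to every other gene, so their
  best cross-hits sit at the noise floor and the Novelty Metric
  separation between carrier and non-carrier strains is analyzable
  (about 0.85 under the defaults).
* Pseudogenes carry a mid-gene in-frame stop in a long (≥ 240 codon)
  body with no in-frame `ATG` after the disruption, so no boundary
  repair within a few hundred bp can rescue them — they must be
  retained as pseudogenes by the merge, not corrected away.
* Annotator perturbations (5' codon shifts, 3' codon truncations,
  drops) act in whole codons, keeping frame-consistent annotator
  error distinguishable from pseudogenization.
* A configurable number of core-gene pairs share an 11-codon block;
  the resulting shared peptides are emitted into the peptide table to
  exercise the ambiguity filter.
* Expression truth: a fraction (default 0.7) of the focal strain's
  valid nondubious genes is expressed; expressed genes receive all
  three evidence types, non-expressed genes none. Real evidence is
  noisier in every direction (partial coverage, condition-specific
  expression, one-hit-wonder peptides); passing recovery tests on
  this generator therefore demonstrates the correctness of the
  validation logic and thresholds, not robustness to evidence noise.

The default geometry is scaled down from a real yeast genome: 4
strains, 2 chromosomes of 20 kbp, a 5 kbp subtelomere span, 50--100
codon genes (about 44 genes on the focal strain). This keeps a full
panel search to seconds while preserving everything structural:
subtelomeric vs interior placement, cluster adjacency, strand
symmetry, and a clear noise floor. The geometry invariant
`chromosome_length >= 2 * subtelomere_span` guarantees both placement
classes exist. Larger panels used in the checks (100 genes across 3
strains; 200 genes across 8 chromosomes) stretch the same geometry
rather than changing it. Identical seed and configuration give
byte-identical FASTA output; all generator randomness flows through
one seed.

What the generator does **not** emulate: sequencing reads and their
error models, assembly artifacts and gaps, repeat families
(Ty elements, tandem arrays), mitochondrial codes, introns, and
biased base composition. Conclusions about those belong to real-data
analyses upstream of this package.

## Numerical and degenerate-input choices

* Absent hits are bit score 0 everywhere downstream; a query with no
  hit in any panel genome yields an `NA` novelty row rather than 0/0.
* `local_align` never returns a negative score (local alignment floor
  at 0) and scores empty inputs 0; hit coordinates are `NA` at score
  0.
* `fisher_exact_log` clamps at $\log_{10} p = 0$ against floating-
  point drift above $p = 1$.
* Fewer than two strains cluster as the identity ordering; an empty
  annotation set summarizes to zeros; a contig with zero anchors is
  unplaced, never dropped; tabular hit parsing reports the first
  malformed line number.
* Sub-seeds for the annotator and evidence generators are taken as
  offsets from the panel seed, keeping every derived seed well below
  $2^{31}$.

## Known limitations

* The internal search is exhaustive Smith–Waterman: right for
  kilobase-scale panels and for exactness against oracles, wrong for
  full genomes — at real scale, run an external translated search and
  feed the tabular output in.
* Best-hit bit scores ignore multiple HSPs per locus; a gene split
  across an assembly gap scores as its best fragment.
* The synteny test requires a shared gene namespace between the two
  annotations being compared.
* The merge precedence cannot recover a gene dropped by both
  annotator tracks, and a locus perturbed in both tracks keeps the
  less-damaged interval rather than the truth; both effects are
  visible (and small) in the recovery rates the acceptance script
  reports.
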