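---
title: "Mitochondrial gene-order rearrangement analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitochondrial gene-order rearrangement analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorearr)
```

## The problem

Insect mitochondrial genomes are circular molecules of ~14–20 kb carrying 37
genes (13 protein-coding genes, 2 rRNAs, 22 tRNAs) plus a large non-coding
control region (CR). Most insects retain the putative ancestral pancrustacean
arrangement, but several lineages — conspicuously the true bugs
(Heteroptera), and within them the assassin bugs (Reduviidae) — show derived
gene orders: tRNA translocations, duplications, and outright gene losses.
Because rearranged orders are rare, discrete, and effectively irreversible,
they are prized both as phylogenetic markers (potential synapomorphies) and
as windows into the mechanics of mitogenome evolution.

`mitorearr` implements the comparative workflow used in heteropteran surveys:

1. a data model and text grammar for circular, stranded, possibly
   incomplete gene orders, with catalog I/O and a GenBank feature-table
   reader;
2. classification of rearrangement events against the ancestral ground
   pattern;
3. localisation of rearrangements into three gene blocks and six
   rearrangement units, and the family-level *rearrangement richness*
   statistic;
4. inference of minimal tandem duplication/random loss (TDRL) scenarios,
   with prediction of the intergenic remnants they leave behind;
5. nucleotide composition and strand-skew statistics; and
6. seeded synthetic generators so every stage is testable against known
   ground truth.

## The data model

A `gene_order` is a circular sequence of gene tokens read on the majority
strand. The grammar writes a minority-strand gene with a `~` prefix
(`~trnQ`), an unsequenced stretch as `//`, a confirmed gene loss as `[trnI]`,
and an absence that may instead be a translocation into an unsequenced
region as `[trnY?]`. Absent genes live in a separate absence set, never in
the positional sequence. Serine and leucine tRNAs are always disambiguated
(`trnS1`/`trnS2`, `trnL1`/`trnL2`); bare `trnS`/`trnL` are rejected unless a
legacy alias table resolves them, because positional context in the
ancestral order makes the assignment unambiguous but silent guessing would
not be reproducible.

Circular equality is decided on a canonical rotation: anchored at CR when
the order has exactly one CR (the standard presentation of mitogenome maps),
otherwise at the lexicographically smallest rotation so that equality stays
deterministic when CR is missing or duplicated. Orders containing gaps are
compared as laid out: two partial orders are the same arrangement only if
everything observable agrees, which keeps differently-sequenced partial
genomes apart rather than speculatively merging them.

The packaged catalog (`heteroptera_catalog()`) transcribes the published
survey of heteropteran rearrangements. Published tables print only the
rearranged excerpt of each genome; the fixture embeds every excerpt in the
ancestral background so that records are full circles, and keeps `//` gaps
verbatim. Since no inversion is known in Heteroptera, every gene keeps its
ancestral strand. Where the printed table marks a lost gene typographically
(and a plain-text transcription cannot), the fixture fixes one assignment,
documented in its header, chosen to be consistent with the published
richness denominators; the affected cells are marked *expected fragile* in
the test-suite comments because they hinge on that transcription choice.

## Event classification

`classify_events()` scores an observed order against the ancestral one:

* **loss** — genes in the (confirmed) absence set;
* **duplication** — genes with multiplicity above one;
* **inversion** — shared single-copy genes whose strand differs (never
  observed in true bugs, but detected for completeness);
* **translocation** — the minimal set of shared, same-strand genes whose
  removal restores circular order agreement.

Translocations are found with a breakpoint-style analysis on cyclic
adjacency rather than positional indices, so rotation, duplication and loss
never masquerade as movement. Tandem duplicate runs are collapsed to one
copy first; copies that remain dispersed are moved by definition. The
minimal removal set is the complement of a maximum-weight common circular
subsequence between the two orders (computed by dynamic programming over
all rotations). Weights implement the tie-breaks: keeping protein-coding
and rRNA genes outweighs keeping tRNAs — so equal-sized explanations move
tRNAs, matching the field's reading that `trnW` moved rather than
`ND2`-plus-flanks — and, after that, the moved set is pushed toward
lexicographically first names so results are deterministic.

An absence flagged uncertain (`[trnY?]`) is reported as `unresolved`, not
forced into loss or translocation: for a partial genome the gene may sit in
the unsequenced region, and the two readings have different downstream
consequences. Confirmed absences in partial genomes (`[trnC]`) still count
as losses.

## Units, signatures, and richness

Heteropteran rearrangements concentrate in three blocks of the ancestral
order — block A (CR→COI), block B (the ND3→ND5 tRNA cluster), block C
(ND5→CR) — subdivided into six units (1: *trnI-trnQ-trnM*, 2:
*trnW-trnC-trnY*, 3: *trnA-trnR-trnN-trnS1-trnE-trnF*, 4: *trnT-trnP*, 5:
*ND6-CYTB-trnS2-ND1*, 6: *rrnL-trnV-rrnS*). Both lists are data
(`unit_definitions()`, `block_definitions()`) and can be overridden.

The identity key under which distinct arrangements are counted is the
**unit signature**: the minimal circular window of the observed order that
contains every occurrence of the unit's members, including intruding genes,
plus the unit members recorded absent and those falling in unsequenced
regions. A design alternative — cutting the region between the unit's
nearest conserved flanks — was rejected: when a member gene is translocated
far away but re-inserts next to its old neighbours (as trnI does in
unique-headed bugs, landing immediately upstream of trnQ), the flank-based
region sweeps in the entire displaced stretch and scores the unit as
rearranged, whereas the published unit attribution scores it as intact. The
member-window definition reproduces the published per-unit attribution for
every record with no per-record exceptions. Windows interrupted by a gap,
or units none of whose members are observable, give an *unknown* signature
that compares equal to nothing and conservatively counts as unrearranged.
Partial evidence still scores: members lost to unsequenced regions are
dropped from the ancestral reference before comparison, so a positively
displaced gene counts even when a fellow member is unsequenced.

**Rearrangement richness** of family *F* for unit *u* is
$$R(F, u) = \frac{|\,\text{distinct rearranged signatures of } u \text{ in } F\,|}{|\,\text{distinct rearranged signatures of } u \text{ catalog-wide}\,|},$$
and analogously for the whole mitogenome with canonical whole-order keys.
An arrangement shared verbatim by several families counts once in the
denominator but once per carrying family in numerators — sharing inflates
numerators, never denominators. Ratios are rendered as percentages with one
decimal, rounded half away from zero (`percent1()`), the convention under
which 3/7 prints as 42.9%. Records carrying the ancestral pattern
contribute to no numerator; the ground pattern itself is the "+1" in the
distinct-order count reported by `survey_counts()`.

```{r richness}
cat0 <- heteroptera_catalog()
survey_counts(cat0)
format_richness(richness(build_index(cat0)))
```

## The TDRL model

Under tandem duplication/random loss, a contiguous segment of the circle is
duplicated in tandem and, for each duplicated position, one redundant copy
decays. Survivors keep their strand — the model has no inversion — and the
gene content is conserved unless the loss extension is enabled, under which
a position may lose both copies (modelling true gene loss in the same
framework, including loss of a duplicated control region).

`apply_tdrl()` executes one step; `enumerate_single_tdrl()` is the
brute-force oracle over all segments and loss patterns;
`search_scenarios()` runs a breadth-first search over canonical orders and
returns **all** scenarios of minimal step count, ordered by total
duplicated length and then by segment position. Two scenarios are the same
mechanism if and only if their intermediate order sequences agree — and the
intermediates include the tandem-duplicated (pre-loss) order, not just each
step's result. This matters: alternative duplication boundaries reaching
the same final order are genuinely different mechanisms (they predict
different remnants) and must stay distinct, while coordinate
re-parameterisations of one mechanism must not be double-counted.

Default bounds are `max_steps = 2` and `max_segment = 8`: all published
heteropteran scenarios are single-step with segments of at most six genes,
and these bounds keep the search desk-scale. The bounds are explicit
arguments, not tuning constants.

`predict_remnants()` replays a scenario keeping a marker wherever a copy
was deleted and reports the adjacencies of the final order where remnant
non-coding sequence is expected; adjacent deletions merge into one site.
This is a site prediction only — measuring remnant lengths requires the
nucleotide sequences and is out of scope. Notably, the strict duplication
of *trnQ-trnM-ND2-trnW* predicts remnants only at (trnI, trnW) and
(ND2, trnC); a spacer between trnW and trnQ requires one of the
broader-boundary variants, which is why the search reports the full minimal
set rather than a single winner and ranks by duplicated length only.

```{r tdrl}
anc <- ancestral_gene_order()
plemur <- parse_gene_order(paste0(
  "CR-trnI-trnW-~trnQ-trnM-ND2-~trnC-~trnY-COI-trnL2-COII-trnK-trnD-",
  "ATP8-ATP6-COIII-trnG-ND3-trnA-trnR-trnN-trnS1-trnE-~trnF-~ND5-~trnH-",
  "~ND4-~ND4L-trnT-~trnP-ND6-CYTB-trnS2-~ND1-~trnL1-~rrnL-~trnV-~rrnS"))
sc <- search_scenarios(anc, plemur, max_steps = 2, max_segment = 6)
length(sc)
sc[[1]]
predict_remnants(sc[[2]], plemur)
```

## Composition statistics

`composition()` computes base counts, A+T content, and the strand
asymmetries AT-skew = (A − T)/(A + T) and GC-skew = (G − C)/(G + C) on the
majority strand as deposited, case-insensitively, folding U into T and
excluding ambiguity codes from counts (they still enter the length, so
A+T, G+C and ambiguity fractions sum to one exactly). A skew with a zero
denominator is undefined (`NA`), not zero. Display conventions: two
decimals for skews, one for percentages. `composition_report()` breaks a
GenBank-annotated genome into per-region rows; whole-genome and
coding-region rows are both reported because published A+T figures do not
always state whether the control region is included.

## Synthetic data: what it emulates, what it does not

The generators provide ground truth for validation:

* `simulate_tdrl_evolution()` applies `k` random valid TDRL steps (segment
  start uniform on the circle, length uniform within bounds, loss pattern
  uniform over first/second choices). Degenerate draws that leave the
  order unchanged are rejected, so every recorded event is real. Default
  segment bounds (1–6 tokens) mirror the segment sizes of real scenarios.
* `generate_catalog()` plants a richness structure: each arrangement
  permutes one unit's members in place (strands kept), families receive
  arrangements through a sharing matrix, and the implied richness table is
  computed arithmetically from the matrix at construction — independently
  of the analysis code — and validated for consistency before any record
  is emitted, so recovery tests cannot pass vacuously.
* `random_sequence()` draws i.i.d. bases whose probabilities meet target
  A+T content and skews exactly in expectation.

All generators are pure functions of their seed. What passing recovery
tests show: the pipeline inverts its own forward model — signatures,
dedup, sharing, and ratios are internally coherent, and single TDRL events
on a full 38-token mitogenome are always re-derivable. What they do not
show: real mitogenomes violate several idealisations — rearrangements can
overlap unit boundaries, annotation errors and partial sequencing blur
signatures, duplicated control regions decay gradually, and per-base
composition is not i.i.d. The packaged real catalog, not the simulator, is
the evidence that the statistics reproduce published values.

## Numerical and design choices

* Canonical anchor CR, else smallest rotation; ties between equally
  minimal signature windows resolve to the first maximal gap, making every
  key deterministic.
* Translocation minimality tie-breaks: fewer genes, then prefer moving
  tRNAs, then lexicographically first — encoded as weights in one dynamic
  program rather than post-hoc filtering.
* Unit attribution of genes that leave their home block follows the
  published table's convention (the displaced trnI of unique-headed bugs
  does not rearrange unit 1, because its window re-forms intact); records
  where this convention matters are exactly the C1-type records, and the
  choice is localised in the signature definition, not special-cased.
* The two identically-printed Nabidae records are kept distinct (their
  losses differ); the transcription's loss assignments are pinned in the
  fixture header.
* Problem sizes used by the validation suite: exhaustive oracle
  equivalence on all circular orders of 3–5 genes; 200 seeded single-event
  recoveries and 50 random planted-richness plans on the full 38-token
  order — sizes at which the exhaustive oracles are exact.

## Known limitations

* No inference of rearrangement polarity along a phylogeny: the package
  compares each order to the ground pattern, it does not reconstruct
  ancestral states on a tree.
* No recombination or inversion operators in the mechanism search; no
  tRNA-remolding detection.
* Remnant prediction is positional; sequence-level verification of
  remnants (alignment of intergenic spacers to decayed copies) is out of
  scope.
* The GenBank reader consumes existing annotations; it performs no de novo
  gene finding, and product-name mapping, while covering the common
  conventions, falls back to `NCR` tokens (with a report) on exotic
  labels.
* Multi-step TDRL search is exact but exponential in the frontier; it is
  intended for the short scenarios (≤ 2 steps) relevant here, not for
  distant order pairs.
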