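---
title: "Target-species barcoding under incomplete sampling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-species barcoding under incomplete sampling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Classical DNA barcoding assumes a comprehensively sampled reference
library: every species of the group, several individuals each. For a
species-rich genus — the motivating case is a genus of well over a
thousand species containing a handful of quarantine weeds — that library
will never exist. `cladegap` implements the alternative: identify a
*specific* target species reliably from an *incomplete* library, by
exploiting the genus's known phylogenetic structure.

The workflow rests on three components:

1. **Clade barcoding (step 1).** The library samples a few representative
   species from each major clade of the genus. Because divergence between
   clades is much larger than divergence within them, a query can be
   assigned to its clade even when its species is unsampled.
2. **Species confirmation (step 2).** Within the assigned clade — where
   sampling is dense around the target species and its closest relatives —
   the query is tested against the nearest species S on two criteria:
   it must nest exclusively inside a bootstrap-supported monophyletic
   group of S, and S must retain a *target-specific barcode gap* with
   the query counted among its individuals.
3. **Two-genome cross-examination.** Chloroplast loci are maternally
   inherited, nuclear loci biparentally. Building the trees separately
   per genome turns their disagreement into signal: a clade-scale
   conflict between an individual's cpDNA and nuclear placements marks a
   putative hybrid (maternal parent from the cpDNA side), while
   placements that agree with each other but contradict the nominal
   label mark a suspected misidentification.

## Distances and trees

Pairwise distances use the Kimura 2-parameter model: with transition
proportion $P$ and transversion proportion $Q$ over the sites where both
sequences carry an unambiguous nucleotide,

$$d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q).$$

When either logarithm's argument is non-positive the pair is *saturated*
and the distance is `NA`; saturated pairs propagate as `NA` rather than
being capped, and tree building refuses matrices containing them (the
user is told to prune or change the deletion policy). The default
missing-data policy is pairwise deletion — each pair is compared over
its own shared sites — because complete deletion discards entire columns
for a single gapped individual, which is wasteful in multi-genus
matrices with patchy indels. Both policies are available
(`distance_matrix(..., deletion =)`), as is the uncorrected p-distance.

Trees are Saitou–Nei neighbor joining. Tips are sorted lexicographically
before agglomeration, making tie-breaks deterministic and the output
invariant to input order. Negative estimated branch lengths are clamped
to zero with the deficit transferred to the sibling branch, preserving
tip-to-tip path lengths; an all-zero matrix is returned as a star tree.
Branch support is the classical column bootstrap: resample aligned
columns with replacement, rebuild distance matrix and tree, and report
for each internal bipartition of the reference tree the percentage of
replicate trees containing it. Replicates with saturated distances are
skipped and counted (a warning fires above 10%). All resampling is
driven by a single integer seed. Internally, columns are collapsed to
site patterns with multiplicities, so each bootstrap replicate costs a
reweighting rather than a re-scan of the alignment.

Maximum-parsimony *search* is out of scope; Fitch small-parsimony
*scoring* of a given topology is provided (`fitch_score`, via phangorn)
so users can compare candidate topologies, with gaps and missing data
treated as unknown states and optional binary indel characters appended.

## Alignment statistics and indel coding

`alignment_stats` reports the marker-comparison table familiar from
barcode screening studies: ungapped length range, aligned length, counts
and percentages of variable and parsimony-informative characters, and
the mean pairwise divergence Pi (the mean of the off-diagonal K2P
distances by default; percentages use half-up rounding to two decimals,
matching how such tables are printed). Column variability counts only
the four nucleotides — gaps and missing data are not states — which
keeps indel signal confined to indel coding and matches common
distance-software reporting conventions. Whether Pi should instead be an
uncorrected diversity is configurable by passing a p-distance matrix;
K2P is the default because it is the matrix the rest of the pipeline
consumes.

Simple indel coding turns every distinct maximal gap run (start/end
column pair) into one binary presence/absence character: a sequence
scores 1 when it carries exactly that run, `?` when one of its runs
strictly contains the range with different endpoints (presence is then
unknowable), 0 otherwise. Terminal gap runs are coded like internal ones
by default — they are often alignment-length artifacts, so
`ignore_terminal_gaps = TRUE` drops them.

## The barcode-gap tests

`gap_report` gives the classical all-species picture: the distributions
of intraspecific and interspecific distances and their overlap fraction
(the proportion of interspecific distances at or below the largest
intraspecific one). In heterogeneous genera this global gap routinely
fails even when every individual species is identifiable.

`target_gap` is the target-specific variant: only the focal species'
maximum intraspecific distance and its minimum distance *to its closest
relatives* enter the comparison. Distances among the relatives
themselves are irrelevant — a pair of sister relatives being close to
each other says nothing about the focal species' identifiability. The
relatives default to `"auto"`: the `k = 2` species with the smallest
*mean* interspecific distance to the target. Mean rather than minimum
makes the choice robust to a single aberrant individual; a field user
with prior phylogenetic knowledge can name the relatives explicitly.
Histograms are exported as binned counts (default bin width 0.002
distance units, configurable) rather than rendered plots.

When the gap fails, `pca_scatter` offers the complementary view used in
practice: the symmetric distance matrix is treated as a data table
(rows = individuals, columns = variables), columns are centered (not
standardized — the columns share units), and the covariance matrix is
eigendecomposed. This is deliberately *not* principal coordinates
analysis of the distances; it reproduces the behaviour of the simple
multivariate packages used in such studies, and clusters of individuals
with similar distance profiles separate on the first two components
even when the one-dimensional gap is blurred.

## Incongruence classification

`classify_incongruence` operationalizes "reading placements off the two
trees". An individual's assignment in a tree is the species — or,
failing a strict species majority, the clade — of the *other*
individuals in its smallest bootstrap-supported enclosing clade, walking
rootward until a supported clade yields a strict majority. Verdicts are
resolved at clade scale:

* both assignments corroborate the nominal species (species match, or
  clade match — a tip attaching beside a same-clade sister species is a
  sampling artifact, not a conflict) → `concordant`;
* supported assignments in *different* clades → `putative_hybrid`, with
  the cpDNA side reported as maternal and the nuclear side as paternal;
* assignments that agree with each other but contradict the nominal
  label → `suspected_misidentification`;
* anything else → `unresolved`.

Species-level discordance within one clade is never flagged: it is
indistinguishable from incomplete lineage sorting at this resolution,
and the verdict vocabulary deliberately stays at "putative"/"suspected".
The support threshold defaults to 75%, the conventional display cutoff
for parsimony bootstrap trees in this literature; it is a parameter
everywhere it is used.

## The two-step identification

`assign_clade` scores a query against each clade by mean combined-locus
K2P distance to the clade's individuals and reports the winning clade
with its margin (runner-up mean minus best mean). The distance verdict
is cross-checked by NJ placement — the query must attach inside the best
clade's subtree — because a mean can be won degenerately when a clade is
represented by a single exemplar. A zero margin or a placement
disagreement raises a `placement_conflict` flag and the identification
stops as `unresolved`.

`identify_species` then restricts the library to the assigned clade plus
the outgroup, rebuilds the bootstrapped NJ tree with the query included,
and applies the species criteria to the nearest species S:

* **monophyly with exclusive nesting** — S's individuals plus the query
  must form a supported clade (threshold 75%), *and* S's reference
  individuals must not retain a decisively supported clade of their own
  that excludes the query. The second condition rejects queries that
  merely attach as sister to the species cluster — the signature of a
  related but unsampled species. "Decisive" defaults to 90% support
  (`separation_threshold`): under a within-species star radiation a pair
  of conspecific references can pair up with borderline support by
  chance, and treating that as separation would reject genuine
  conspecific queries, whereas a true species stem is essentially always
  recovered at ~100%.
* **target-specific gap** — `target_gap` for S with the query counted
  among S's individuals must still hold.

A candidate species with a single reference individual is never
confirmed: its intraspecific variation is unknowable and the gap test
would be driven by the query itself, so the result is `clade_only` with
a "densify sampling" advisory — the procedure's sampling instruction
surfaced to the user rather than automated, since how many added species
suffice is a judgement call on real data.

## The simulator

`simulate_library` generates the data regime the method assumes, with
truth tables, so every stage can be validated end to end:

* an ultrametric genealogy: major clades radiate at depth `d_clade`
  (default 0.08 expected substitutions/site), species within a clade at
  `d_species` (0.03), individuals within a species in a star at
  `d_intra` (0.005), one outgroup individual at `d_outgroup` (0.12).
  Expected pairwise divergences are twice the depths: ~0.01 within
  species, ~0.06 within clades, ~0.16 between clades. The within- to
  between-species ratio mirrors the barcode-gap regime of congeneric
  plant groups scored with moderately variable phylogenetic markers;
* three loci with the aligned lengths of a typical two-cpDNA + one
  nuclear supplementary-barcode panel (1745, 681, 1527 bp), partition
  labels `cpDNA`, `cpDNA`, `nuclear`;
* a two-parameter (transition/transversion, κ = 2) substitution process
  matching the K2P estimator, so distance estimates are consistent with
  the simulation depths and parameter-recovery tests are meaningful;
* indels as deletion-only events (rate 0.02 per site per unit depth,
  geometric lengths, mean 3 bp), keeping all sequences in shared
  coordinates — the pipeline consumes pre-aligned data, so insertions
  would only add a realignment step that is out of scope;
* planted anomalies: hybrids take their cpDNA loci from a maternal
  lineage and their nuclear locus from a paternal lineage in a different
  clade, and carry the maternal species' label; mislabels are
  individuals relabeled to a species in a different clade. Parent
  species need at least two individuals and mislabel sources at least
  three, so the remaining true-labeled individuals still dominate their
  cluster — without this, a two-individual species containing a planted
  anomaly leaves a single genuine individual whose "other cluster
  members" are all foreign, and the classifier would be forced into
  false verdicts by construction rather than by any property of the
  method.

What the simulator does *not* emulate: coalescent topology variance
within species (star coalescence only), rate heterogeneity across sites,
insertions, recombination, and the heterogeneous per-clade sampling of
real herbarium-and-GenBank libraries. Passing the simulated checks
therefore demonstrates the pipeline's correctness and its statistical
behaviour *in the regime the method assumes*, not its performance on any
particular real genus.

## Validation scale and numerical choices

The shipped tests and the acceptance script exercise the pipeline on a
reduced library — 5 clades × 3 species, 1–5 individuals per species,
loci of 600/250/500 bp, bootstrap with 100 replicates — with all
evolutionary parameters at the simulator defaults. These sizes are the
package's chosen validation scale: large enough that species have
multi-individual clusters and clades have internal structure, small
enough to replicate a hundred times. Pooled over seeds 1–100, the
package requires ≥95% target-gap detection, ≥90% hybrid and mislabel
sensitivity with ≤5% false flags on normal individuals, ≥95%
identification of held-out conspecific queries, and zero wrong-species
identifications of absent-species queries; the accompanying acceptance
script recomputes the same quantities over 30 replicates.

Other numerical choices: bootstrap supports are integer percents;
support bookkeeping canonicalizes bipartitions by the block not
containing the alphabetically first tip; half-up rounding for printed
percentages; distance round-trips through the PHYLIP/TSV writers are
exact to 10^-6; IUPAC ambiguity codes other than `N` map to `?` with a
warning (missing is the conservative reading of an ambiguity); `-` is an
indel state distinct from missing, participating in indel coding but in
nothing else.

## Known limitations

* Clade assignment inherits the library's clade definitions; a query
  from a clade absent from the library will be forced into the nearest
  sampled clade (the placement-conflict flag is the only defence).
* Hybrid detection requires the parental clades to be distinct; within-
  clade hybridization is invisible by design.
* The incongruence classifier assumes the two partitions' trees are
  comparably resolved; a very short nuclear locus with weak support
  produces `unresolved` verdicts rather than errors.
* Queries must be pre-aligned to library coordinates; alignment itself
  is out of scope.
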