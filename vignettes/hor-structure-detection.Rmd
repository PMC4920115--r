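---
title: "Detecting higher-order repeat structure in satellite long reads"
author: "horscan developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting higher-order repeat structure in satellite long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(horscan)
```

## The model

Satellite arrays are tandem repeats of a short monomer (~171 bp in human
alpha satellite). In many arrays the monomers are not interchangeable:
*k* diverged monomer classes repeat in a fixed order, and that k-monomer
unit — the higher-order repeat, HOR — is itself the tandem unit, with
unit-to-unit identity far higher than monomer-to-monomer identity within
a unit. A long read spanning the unit more than once therefore contains,
for each monomer class, several occurrences spaced exactly one unit
apart. `horscan` turns that observation into a per-read classifier.

The per-read statistic is the clustered monomer index. Let `X_i` be the
ordered start positions of the monomers assigned to cluster X, let
`d_X,i = X_{i+1} − X_i`, and let `d` pool these distances over all
clusters. Four conditions define regularity:

1. every monomer lies in a cluster with more than one member;
2. `0.95 ≤ d_X,i / median(d) ≤ 1.05` for all X and i (closed interval:
   a ratio of exactly 0.95 or 1.05 passes);
3. the gap between the tail of one monomer and the head of the next is
   at most 5 bases (computed as `start_{k+1} − end_k`; negative values,
   i.e. tolerated overlaps, pass);
4. all monomers within a cluster share one orientation.

A read failing any condition is *irregular*; condition-4 failures are
additionally flagged as *inversions*. Reads without usable cluster
structure are *no-HOR*; the subset whose monomers are mutually below 88%
identity is flagged *monomeric* (divergent satellite without
higher-order organization). A dimer is the minimal HOR, so every
reported period is at least 2.

## Pairwise identity and clustering

All sequence comparison in the classification path uses one convention:

    identity(a, b) = 1 − D(a, b) / max(|a|, |b|)

with `D` the unit-cost edit distance (substitutions, insertions,
deletions), computed by Ukkonen's O(ND) band-doubling scheme — the
diagonal band is doubled until the computed distance fits inside it, at
which point it is exact. For the near-identical sequences compared here
(≥ 88% identity) this is effectively linear-time. The max-length
denominator is symmetric and conservative; the 88% monomeric boundary
inherits it. The test suite proves exact equivalence with a full O(nm)
dynamic-programming oracle (`utils::adist`) on 1000 seeded pairs.

Clusters at a threshold t are the connected components of the graph with
an edge wherever identity ≥ t (single linkage). This is the simplest
deterministic reading of similarity-based grouping; labels are letters
in order of first appearance along the read, so relabeling is stable
under re-runs. Thresholds are scanned over the 11-point grid 0.98, 0.97,
…, 0.88 and the scan keeps the **highest** threshold whose clustering
satisfies condition 1. We deliberately let condition 1 alone drive the
threshold choice: conditions 2–4 diagnose *irregularity* at the chosen
resolution and should not be able to push the scan to a coarser one
(otherwise an inverted monomer could hide its own inversion by forcing a
lower threshold). If no grid point satisfies condition 1, the 0.88
assignment is kept, flagged as unable to support HOR inference.

## Monomer detection

The built-in detector aligns each training monomer semi-globally against
the read and its reverse complement: the model must align end to end,
the read contributes free end gaps. A single O(mn) scan produces, for
every read position, the best edit distance of the model against a
substring ending there; local minima under the identity budget (default
70%) become candidate hits, hit starts are recovered by the mirrored
scan on reversed sequences, and candidates from all models and strands
are tiled greedily by score with at most 10% overlap of the shorter hit
(ties: leftmost start, then model id — fully deterministic). Hits
shorter than 150 bases are never emitted.

Hit identity is the same edit-distance identity defined above, taken
against the matched model. An earlier draft used alignment-column
identity (matches over alignment length) from `Biostrings`; the two
agree on substitution-only differences, and the edit-distance form keeps
one convention across the package and is orders of magnitude faster in
this environment, which matters for the simulation-based test suite.
This is the package's stand-in for the score cutoff of an external
profile search, and it is exposed in `detection_config()`.

The detector is one of two interchangeable front ends: a hit table from
an external profile-HMM search (`nhmmer --tblout` dialect) can be
ingested with `parse_external_hits()`, which converts the 1-based,
strand-encoded coordinates to this package's single convention —
0-based, half-open, forward strand — exactly once, at the parse
boundary. External hits carry no identity value (the tabular format has
none); all downstream identity logic works from monomer sequences
re-extracted from the read, so the classification core is front-end
agnostic.

## Classification decisions at the margins

Three cases are not settled by the four conditions alone and were
decided as follows:

* **Period-1 "HORs".** A read whose monomers all merge into one cluster
  with uniform spacing passes all four conditions, but a one-monomer
  unit is plain monomeric tandem, not higher-order structure; likewise a
  single HOR copy (each class seen once) merges into one cluster near
  the identity floor. Both estimate period < 2 and are classified
  no-HOR (`single-copy-or-incomplete` / `no-higher-order-structure`
  notes), keeping the invariant that a reported period is ≥ 2.
* **Disrupted arrays.** If condition 1 fails at every grid point (e.g. a
  deleted monomer leaves a singleton cluster) but at least two clusters
  still repeat at the 0.88 floor, the read shows repeat structure that
  is broken rather than absent: irregular.
* **Monomer re-use.** A unit that re-uses a near-identical monomer twice
  (as some centromeric arrays do) makes that cluster's spacing alternate
  around the pooled median, failing condition 2: irregular, matching the
  published taxonomy for such arrays.

Condition 2 is implemented literally on the pooled median; for arrays
whose clusters have very unequal membership the pooled median is
dominated by the largest cluster. Medians over an even count are the
midpoint of the two central values. Ratio and threshold comparisons use
a 1e-9 epsilon so boundary values stored in binary floating point fall
inside their closed intervals.

The HOR period is `round(median(d) / median monomer span)`; with gaps
bounded by 5 bases this counts monomers per unit. Consensus sequences
(regular reads only) anchor each cluster on its medoid member, take
column-wise majorities over unit-cost global alignments of the members
to the medoid (insertions relative to the medoid are ignored, majority
deletions drop the column, ties keep the medoid base), and concatenate
cluster consensi in order of first appearance to form the unit
consensus.

## Transitions into non-satellite sequence

The complement of the (unioned) hit intervals partitions each read into
covered and uncovered stretches. Any single uncovered interval of at
least 1 kb marks the read as containing a transition into non-satellite
sequence — typically a transposable-element insertion or an array edge —
and is exported as FASTA and BED for external repeat-library
annotation, which this package intentionally does not re-implement. The
1 kb rule is applied per interval, not per read total: a transition is a
contiguous block, and scattered sub-kilobase slivers (detector boundary
slack) should not qualify. Sub-threshold intervals still count toward
`n_nonsat_bases` in the summary.

## The synthetic world

`synthetic_read_spec()` describes a read as flank + `n_units` tandem
copies of a `period_k`-monomer unit + flank. Defaults state the world
the tests probe: 171 bp monomers; `period_k = 4`, `n_units = 3` (a read
of ~2 kb, matching the minimum read length of the intended input);
between-cluster divergence 0.08 (monomer classes at ~92% identity,
inside the 88–98% scan window); within-cluster divergence 0.005
(unit-to-unit copies at ~99.5%); residual read error 0.01 (substitutions
1/2, single-base insertions 1/4, deletions 1/4), the regime of
error-corrected long reads; monomeric mode at divergence 0.20 (~80%
identity, clearly below the 88% floor).

Two numerical choices matter. Divergence scales that must respect an
identity band — between-cluster and monomeric — apply a deterministic
substitution count (`round(rate/2 × length)` per copy, random
placement), so the planted identity structure is a property of the
world rather than a binomial-tail outcome; within-cluster divergence and
read error are ordinary per-base draws. And every mutation step is
applied per segment (per monomer copy, flank, or insertion), so
ground-truth coordinates remain exact even when read error introduces
indels. All randomness derives from one seed through a fixed per-read
counter scheme, making fixture sets byte-reproducible.

Planted anomalies: in-place monomer inversion (reverse complement of one
copy), monomer deletion, monomer duplication, non-satellite insertion of
chosen length, and whole-read reverse complement. The generator records
the expected classification by construction.

What the generator does **not** emulate: realistic long-read error
profiles (homopolymer bias), array-scale gradients of divergence,
chromosome-specific monomer phylogenies, and genuine transposable
element sequence (non-satellite segments are uniform random DNA). A
green recovery test therefore establishes that the classifier implements
its stated rules on reads with the stated statistical structure — not
that those rules capture every behavior of real centromeric data.

## Validation scope

The suite's acceptance tier checks, at fixed seeds: exact equivalence of
the O(ND) identity with the DP oracle (1000 pairs ≤ 400 bp); exact
condition arithmetic on hand-built indices (ratio 1.05 passes, 1.06
fails; gap 5 passes, 6 fails; one flipped strand ⇒ inversion); 100%
regular classification with correct period over k ∈ 2…12 × 2–3 units at
zero error, and ≥ 95% planted-label recovery over 200 replicates per
anomaly class at default error; classification invariance under
whole-read reverse complement; and agreement of the threshold scan with
exhaustive oracle evaluation of all 11 grid points on two-scale
fixtures.

The published method's headline numbers (category counts over a 6438-read
CHM1 cohort) were computed on an externally distributed dataset; without
that download they cannot be recomputed, so this package reports no
numeric acceptance targets (`scripts/acceptance.R` writes an empty JSON
object after a seeded end-to-end smoke run). Re-running the benchmark
would additionally be sensitive to the external HMM search's unstated
score cutoffs, for which `min_model_identity` is this package's explicit
stand-in.

## Known limitations

* The built-in detector assumes monomer-scale models (~100–500 bp); very
  short or very long models change the valley structure of the scan and
  have not been characterized.
* External hit tables lack identity values, so
  `median_monomer_identity` is unavailable through that front end.
* Condition 2's pooled median can mask spacing defects in small clusters
  on reads dominated by one large cluster (implemented literally by
  design; see above).
* Consensus calling ignores insertions relative to the medoid; for
  clusters whose members carry systematic insertions the consensus
  follows the medoid.
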