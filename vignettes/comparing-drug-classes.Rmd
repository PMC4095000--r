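---
title: "Comparing drug classes through their targets, pathways and disease networks"
author: "PharmNetCompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing drug classes through their targets, pathways and disease networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PharmNetCompare)
```

## The question and the data model

Western anti-CVD drugs and the active ingredients of anti-CVD Chinese
herbs act on partly different sets of protein targets. This package
implements a target-centred comparison of the two compound classes. Its
data model has three tables: a **compound table** (one row per
compound–target link, with the compound class and a direct/indirect
flag), a **target annotation table** (TTD development status, associated
diseases, Pfam-style domain identifiers, biochemical family, GO
compartments, transcription-factor status) and a **pathway collection**
(GMT gene sets, each labelled `basic` or `disease`). The direct/indirect
distinction exists only for herbal ingredients — an ingredient may bind a
protein itself or regulate it downstream — and every class comparison in
the package uses herbal *direct* targets by default, so the two classes
are compared on the same footing. Western-drug links are direct by
construction and the container validity methods enforce this.

Target identifiers are opaque accession-like strings; the package does
no cross-database identifier mapping, because the mapping used to build
the original censuses is not reproducible without the live source
databases. `ttd_status = "absent"` is an explicit category rather than a
missing record, which keeps every tally denominator unambiguous.

## The statistics

**TTD tallies.** For a target group, the count and percentage per
development status and the in-TTD total. Percentages (and every other
printed ratio) use *half-up* rounding — `roundHalfUp(2.375, 2)` is
`2.38` — because that is the convention the reference tables follow;
`base::round()`'s round-half-even would disagree on exactly such ties.

**Diseases per target (d/t).** For the targets of one group and status,
the total number of disease *associations* divided by the number of
targets. Associations are summed per target: two targets sharing a
disease name contribute two associations. Only this reading reproduces
the reference numerators (e.g. 221 associations over 81 targets giving
2.73); a union-of-disease-names reading does not. Discontinued targets
are kept in the tallies but excluded from d/t reporting, which covers
the successful, clinical-trial and research statuses.

**Profiles.** Domain-count and family profiles partition the group, so
their fractions sum to one. Location profiles count a target once per
annotated compartment; their fraction total may exceed one. This is a
deliberate resolution of an under-specified point: rather than collapse
multi-compartment proteins to a single location by some precedence rule,
the full compartment set is stored and each compartment is counted.

**TF enrichment.** A one-sided Fisher's exact test of the group's TF
count against a proteome background. The background is an explicit
parameter with documented defaults of 20,000 proteins and 618 TFs (the
TRANSFAC census); the reference analysis never states its background, so
conclusions of the form "herbal p below 0.01, western p above 0.05" are
reproduced under this default only, and the package treats the exact
p-values as background-dependent.

**Pathway enrichment.** For target set $S$ in universe $U$ and a pathway
with member set $M$ (intersected with $U$ before testing), the 2×2 table
$a = |S \cap M|$, $b = |S| - a$, $c = |M| - a$, $d = |U| - a - b - c$ is
tested with the one-sided (over-representation) Fisher's exact test:

$$p = \sum_{k = a}^{\min(a+b,\,a+c)}
  \frac{\binom{a+b}{k}\binom{c+d}{a+c-k}}{\binom{N}{a+c}},\qquad
  N = a+b+c+d.$$

Terms are computed through `lchoose` and accumulated in log space
(log-sum-exp), which keeps the tail exact to well below $10^{-12}$
relative error for populations up to at least $10^4$. Significance uses
the strict inequality $p < \alpha$ with $\alpha = 0.01$ by default, on
*raw* p-values — the procedure being reproduced thresholds raw p.
A Benjamini–Hochberg mode is available but off by default. Borderline
ties are guarded: a tail that equals $\alpha$ up to floating-point
roundoff (e.g. exactly $1/100$ at $\alpha = 0.01$) is classified
non-significant, honouring the strict inequality.

The background universe is configurable — union of pathway members
(default), all annotated targets, or an explicit set — because the
reference analysis does not state it. Enrichment is provided both for
pooled class target sets and per compound (each compound's direct-target
set), since the original description is ambiguous about which was used
for the network figures; both modes share one code path.

## Networks

The target–pathway network links a target to every pathway containing
it; the compound–pathway network links a compound to every pathway
containing one of its direct targets. Zero-degree nodes are retained in
the containers (they appear in target lists) but excluded from
power-law fits, where $\log x$ is undefined. The degree distribution
$f(x)$ is the fraction of nodes on one side with degree $x$.

Power-law fitting is least squares of $\log f(x)$ on $\log x$ over
$x \ge x_{\min}$, chosen for transparency over maximum-likelihood
alternatives. Points are weighted by their bin counts: the variance of
an empirical log-frequency scales inversely with the number of nodes in
the bin, and an unweighted fit is dominated by the noisy one-node tail
bins, biasing the slope shallow by several tenths. With count weights
the fit recovers a planted exponent of 2.5 from 2,000 sampled degrees to
within about ±0.15 in practice (the tests assert ±0.4), and on noiseless
input all weights act equally, so the exact exponent is recovered to
machine precision. GraphML serialization (with node kind, degree,
p-value and significance attributes) is delegated to igraph.

## Disease subnetworks

Curated local disease networks are node/edge TSV pairs: nodes carry a
compartment and an upstream/downstream cascade position, edges carry an
activation/inhibition sign that is stored and round-tripped but not
interpreted — no signed propagation model is implied. After
`annotateRegulators()`, coverage summaries count herbal-, western- and
common-regulated nodes per position and compartment, and
`positionPreference()` reports the herbal downstream and western
upstream fractions over position-assigned nodes only.

The two shipped subnetworks (`cvdsSubnetworkFixtures()`) are *synthetic
illustrative stand-ins*: cascades with the documented class asymmetry —
many herbal targets but exactly two western targets on the
apoptosis-centred network, many western targets but exactly two herbal
targets on the vascular endothelial cell contraction (VECC) network —
because the exact membership of the original curated networks is not
recoverable from text. All quantitative claims about this module are
therefore property-based (accounting identities, relabeling invariance,
planted-bias recovery) plus those two coverage counts.

## The synthetic generator

`generateDataset()` plants every effect the analysis is supposed to
detect, with known ground truth:

- **TTD status mix** per class, drawn categorically from proportions
  close to the published censuses (herbal 27.1/8.5/27.1/2.5% and western
  39.7/7.4/14.2/1.0% across successful/clinical/research/discontinued).
- **d/t gap**: disease counts per target are Poisson with per-class
  means 5 (herbal) and 2.5 (western). The mean is applied uniformly
  across statuses so the planted gap equals the difference of class
  means, which the recovery tests assert to ±0.5.
- **TF fractions** 0.093 vs 0.049 (11/118 and 10/204).
- **Family and location weights** biased the way the two classes are
  described: herbal toward enzymes and factors/regulators in cytoplasm
  and nucleus, western toward receptors and channels/transporters on the
  plasma membrane. Domain counts Poisson with means 2.5 vs 1.5.
- **Planted enrichment**: 5 of 50 pathways sample members with an
  8:1 odds weight for herbal-class targets; the remainder sample
  uniformly. With 200 targets per class this yields planted pathways
  whose herbal fraction is ~0.9 against a null of ~0.5.
- **Position bias**: herbal-regulated subnetwork nodes are downstream
  with probability 0.8, western-regulated with probability 0.2.

Generation is fully reproducible from the integer seed. What the
generator does *not* emulate: real pathway topology or overlap
structure, realistic identifier semantics, correlation between a
target's family and its status, or compound-level pharmacology beyond
membership. Passing tests on synthetic data therefore demonstrate that
the statistics recover planted effects of the stated size at the stated
sample sizes — not that the biological conclusions hold on live
database snapshots.

`paperFixture()` is different in kind: a deterministic dataset whose
marginals equal the published counts exactly (204/118/862 targets;
status counts 81/15/29/2, 32/10/32/3; association totals 221/45/56 and
160/39/76; TF censuses of 10 and 11 with four TFs common to both
groups, carrying the published transcriptional-gene counts). Per-target
disease counts are a fixed composition summing to the printed totals;
disease identities are synthetic labels. Two of the source table's
cells are internally inconsistent and are deliberately not reproduced:
the western discontinued percentage printed as 1.7% (2/204 is 1.0%),
and the herbal all-target status rows, which sum to 366 while the
printed in-TTD total is 358 — the fixture realizes the printed 358/862
by carrying 172 research targets in the all-target group (printed 180)
and keeping the 84/88/14 rows exact.

## Numerical conventions and edge cases

- Half-up rounding everywhere a ratio is printed; exact values are kept
  internally and rounded only at reporting.
- Enrichment results are sorted by ascending p-value with lexicographic
  pathway-id tie-break, so outputs are stable across platforms.
- Empty target sets, empty universes, all-zero contingency tables and
  groups with no target of a requested status are errors; dataset-level
  referential problems (dangling ids, undersized universe) are
  *reported* by `validateDataset()` rather than thrown.
- Compounds with no direct target in the universe are skipped with a
  warning by per-compound enrichment; compounds with no direct targets
  at all are classified `other` by the multi-target classifier, with a
  warning.
- The multi-target classifier resolves its vague source wording with a
  fixed precedence: single target, then same family ("different
  subtypes of one protein type"), then co-membership in at least one
  pathway ("same biological process"), then other.

## Problem sizes used in validation

The shipped validation uses 1,000 random contingency tables against an
exhaustive enumeration oracle, 10,000 null draws for type-I calibration
(observed rate ≈ 0.003 at α = 0.01 — conservative, as the discrete
tail guarantees), 50 generator seeds for recall/false-positive-rate and
position-bias recovery, and degree samples of 2,000 nodes for exponent
recovery. These sizes make the whole suite run in well under a minute
while leaving the Monte-Carlo error far below every asserted tolerance.

## Known limitations

- Database retrieval, identifier mapping and live-census reproduction
  (compound counts, the 65/35 enriched-pathway counts) are out of
  scope; those numbers are snapshots of version-dependent sources.
- The power-law fit is descriptive; no model comparison against
  alternatives (log-normal, exponential) is attempted.
- Edge signs in disease subnetworks are carried, not modelled.
- The TF-enrichment background is an assumption; sensitivity to it is
  the user's to explore via the explicit parameters.
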