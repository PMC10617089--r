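---
title: "Reconstructing the temporal assembly of a regional flora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the temporal assembly of a regional flora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floristics)
```

## The problem

A regional flora is assembled over geological time by immigration and
in-situ diversification. Given a time-calibrated phylogeny of the region's
species (branch lengths in millions of years, Mya) and distribution data,
three questions can be answered quantitatively:

1. **When did the flora's taxa arise?** For each family, genus and species,
   the earliest possible time its lineage was present in the flora.
2. **How did its biogeographic character change?** Each genus carries a
   distribution type (Wu's 15 areal types) that groups it into widespread,
   tropical or temperate floristic elements; the balance of tropical versus
   temperate elements diverging in each time window traces, e.g., the
   transformation of a lowland tropical flora into a temperate mountain
   flora.
3. **When did its endemics arise?** Species whose range is essentially
   confined to the region, and confined East Asian / Chinese-endemic
   genera, binned on the same timescales.

`floristics` implements this pipeline with a synthetic-data generator that
produces all inputs with known ground truth, so every stage is testable
without access to any particular (often undeposited) regional dataset.

## Divergence times: the maximum-stem-age rule

All ages live on the "Mya before present" axis: present = 0, increasing
into the past; a node's age is tree height minus its root-to-node path
length. Input trees are required to be ultrametric within a relative
tolerance (default $10^{-6}$ of tree height, guarding against float drift
in published trees); clearly non-ultrametric trees are rejected unless
explicitly allowed, in which case tips may have positive ages.

The age of a higher taxon is its **stem age** — the age of the node where
its subtending branch attaches — because that is the earliest time the
lineage can be shown to have existed. Taxa in regional trees are often not
monophyletic (para- or polyphyly after pruning to the region), so the taxon
is first decomposed into **maximal monophyletic lineages**: the unique
coarsest partition of its tips into clades containing no foreign tips.
Each lineage's stem age is the age of the parent of its MRCA (for a
singleton tip, the parent of the tip), and the taxon age is the **maximum**
over lineages. Species ages are the ages of their tips' parent nodes, which
on an ultrametric tree equal the terminal branch lengths.

Two boundary decisions the data force:

* **Root-attached taxa.** If a lineage's MRCA is the tree root there is no
  stem node. We use the root age and set an `at_root` flag so downstream
  binning can include or exclude such taxa. This matches the
  "earliest possible time" reading and errs, knowingly, toward
  overestimating ages.
* **Monotypic taxa.** A single tip is a valid lineage; its stem age is its
  parent's age. This is the only reading consistent with the stem-node
  rule.

Ages are never rounded internally; report-time rounding only.

The implementation is a single post-order pass per taxon (a node is "pure"
when all its descendant tips belong to the taxon; lineages are pure nodes
with impure parents). The test suite checks it against an independent
brute-force oracle that enumerates every node of the tree, on hundreds of
random birth–death trees, for exact equality.

## Pruning

Regional species lists rarely match a supertree's tips exactly. Pruning
keeps the intersection (reporting how many requested names were absent),
suppresses the degree-two nodes this creates, and — rather than trusting
floating-point edge re-summation — carries the ages of surviving internal
nodes over from the input tree exactly, rebuilding branch lengths as age
differences. Retained node ages are therefore bitwise invariant under
pruning. Name matching is exact after normalization (underscores to
spaces, whitespace collapsed, case preserved); we deliberately do no fuzzy
name resolution.

## Floristic elements

Genera map to Wu's areal types 1–15; the grouping is type 1 widespread,
2–7 tropical, 8–15 temperate, with the temperate block subdivided into
northern temperate (8–11), Tethys (12–13) and East Asian (14–15) elements.
A small set of genera (notably five Chinese-endemic, type-15 genera with
tropical affinities: *Calcareoboea*, *Craspedolobium*, *Malania*,
*Musella*, *Whytockia*) has a genuinely ambiguous placement; the package
ships both override files (`revise_to_tropical.tsv`,
`revise_to_temperate.tsv`) and applies **neither by default** — the
configuration must pick a direction, and overrides are logged. A related
ambiguity — whether type 15 belongs in the temperate count at all — is the
`temperate_includes_type15` flag (default `TRUE`).

## Time binning and the HT ratio

Timescales are ordered, contiguous half-open bins $(\mathrm{old},
\mathrm{young}]$ covering $[0, \mathrm{oldest}]$. An age equal to a bin's
old bound belongs to that bin; the oldest bound is inclusive and age 0
falls in the youngest bin, so bins partition all admissible ages. Two
scales are built in: fixed-width windows (default 5 My from 145 Mya, the
base of the Cretaceous) and the period-level ICS geological scale
(Early/Late Cretaceous, Paleocene, …, Quaternary, with an optional
Pleistocene/Holocene split). Custom scales are validated for contiguity.
When a tree is older than 145 Mya the pipeline prepends a single
"Pre-Cretaceous" bin instead of failing.

Per bin and rank we report the divergence count, the percentage of the
rank total (so percentages sum to 100 across bins), and a divergence rate
(count per My of bin width — rates are reported alongside counts because
geological bins have very unequal widths).

The tropical–temperate balance in a bin is
$$\mathrm{HT} = \frac{H - T}{H + T}$$
with $H$ and $T$ the tropical and temperate genus counts (widespread
genera enter neither). The ratio is scale invariant (counts or percentages
give the same value), bounded in $[-1, 1]$, antisymmetric, and **undefined
— reported as missing, never 0 —** when $H + T = 0$. The element
trajectory is computed from per-period divergence counts by default (a
cumulative standing-diversity mode exists but is off by default, as
per-period counts are what "genera diverging during a period" means). The
**crossover time** is the old bound of the youngest bin where the ratio
changes sign from positive to negative, scanning old to young; exact zeros
and undefined bins are skipped when determining signs.

## Endemism

"Range" is operationalized as the set of distinct occupied counties
(presence/absence), because the source data for such analyses are
county-level checklists; record counts or polygon areas would need data we
do not have. A species is endemic when at least 90% (inclusive — 9 of 10
counties qualifies) of its counties lie inside the region; the threshold
is configurable. Endemic genera are the type-14/15 genera confined to the
region; confinement comes from a curated flag table when available,
otherwise it is derived by pooling member-species counties under the same
threshold rule. Raising the threshold can only shrink the endemic set
(tested as a monotonicity property).

## The synthetic-data generator

The generator stands in for regional datasets that are typically not
redistributable. It emulates:

* **A dated tree** from a constant-rate birth–death process, conditioned
  on tip count or crown age. Defaults (birth 0.06, death 0.02 per lineage
  per My, 400 tips) give ultrametric trees typically ~100–140 My tall —
  a Cretaceous-rooted flora at desk scale (roughly 1/20 of a realistic
  regional angiosperm flora, keeping the full test suite around a minute).
* **A nested taxonomy** painted by cutting the tree where exactly
  `n_genera` (and, older, `n_families`) lineages cross, so taxa are clades;
  tips are relabeled `Genus### sp####` so binomial parsing is exercised. A
  chosen fraction of genera is made non-monophyletic by swapping tips
  between paired genera, and ground-truth ages are recomputed afterwards by
  a brute-force all-nodes scan, independent of the pipeline's traversal.
* **Era-dependent element labels**: each genus is temperate with
  probability $1/(1+e^{-k(c-a)})$ in its stem age $a$ — crossover $c = 10$
  Mya, steepness $k = 0.5$/My by default, mirroring a late-Miocene
  tropical-to-temperate overtaking — otherwise tropical, with a small
  widespread fraction (5%); Wu types are drawn uniformly within the group.
* **Occurrences**: endemics receive at most $\lfloor(1-0.9)m\rfloor$ of
  their $m$ counties outside the region (so the 9-of-10 boundary case
  occurs), non-endemics at least one more than that. Endemic species are
  designated by whole genera, because endemism is phylogenetically
  clustered in real floras and independent draws would make pooled genus
  ranges essentially never confined — i.e., no endemic genera to find.

All draws flow from one `set.seed(seed)` per run (the R idiom for seeded
generation), making datasets and pipeline outputs byte-reproducible.

What passing tests on these data do **not** show: robustness to taxonomic
name errors, non-ultrametric supertrees, rate heterogeneity through time
or across clades, spatially autocorrelated sampling of counties, or the
behaviour of the stem-age rule under heavy polyphyly caused by tree
estimation error. The generator's clean nesting and constant rates are a
best case; conclusions about real floras rest on the correctness of the
rules, which is what the oracle tests establish.

## Numerical choices

* Ultrametricity: relative tolerance $10^{-6}$ of tree height.
* Newick output: 15 significant digits, so write/read round trips preserve
  ages to well under $10^{-9}$ My.
* Bin boundaries: exact comparisons (`old >= a > young`); no epsilon,
  because ages and bounds are exact doubles in both scales.
* Endemism construction: `floor((1 - threshold) * m + 1e-9)` — the naive
  floor loses the boundary case to binary representation of 0.9.
* Percentages are reported unrounded in CSVs; display rounding (1 decimal)
  happens only in `summary()`.

## A worked run

```{r demo, eval = FALSE}
out <- run_pipeline(demo_config_file(), out_dir = tempfile("demo"))
summary(out)
plot(out)
```

The pipeline stages everything in a temporary directory and moves it into
the output directory only on success, so failed runs leave no partial
outputs; a `manifest.json` (package/R versions, full configuration, key
counts) suffices to reproduce the run. There is deliberately no shell
wrapper: the exported functions, a YAML config and `run_pipeline()` are
the interface an R user scripts against.

## Known limitations

* Family ages require a genus-to-family lookup; binomials alone cannot
  supply one.
* `prune_to_taxa` re-identifies internal nodes via MRCA queries, which is
  quadratic-ish in tree size; fine to a few thousand tips, not tuned for
  hundred-thousand-tip supertrees.
* Whether higher-taxon ages should be computed before or after pruning to
  the region is scientifically ambiguous; the pipeline computes them on
  the tree it is given (i.e., after pruning when a species list is
  supplied), and the question remains the user's.
* The generator draws element labels (from ages) and endemism (from the
  occurrence model) independently, whereas in real floras confined genera
  are East Asian / Chinese-endemic types almost by definition. Synthetic
  endemic-genus counts are therefore small (a genus must independently be
  temperate, type 14/15, and range-confined); the endemic-genus rule
  itself is exercised against curated confinement tables in the tests.
* No crown ages, diversification-rate model fitting, or ancestral-area
  reconstruction — this package measures divergence timing and
  composition, it does not model process.
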