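# floristics

Tools for reconstructing the temporal assembly of a regional flora from a
time-calibrated phylogeny and species distribution data. The package is
aimed at plant biogeographers asking *when* a flora's families, genera and
species arose, *how* its biogeographic character (tropical vs temperate
floristic elements) shifted through geological time, and *when* its
endemics diversified.

## What it computes

Given a dated, ultrametric phylogeny (tips = species binomials, branch
lengths in Mya), a taxonomy, a genus-to-distribution-type table (Wu's 15
areal types) and optionally county-level occurrences:

* **Divergence times.** Species ages are terminal branch lengths (the age
  of the tip's parent node). Higher taxa get **stem ages**: a taxon is
  decomposed into its maximal monophyletic lineages (the coarsest partition
  of its tips into clades containing no foreign tips); each lineage's stem
  age is the age of the parent of its MRCA; the taxon age is the maximum —
  the earliest possible time the lineage was present.
* **Floristic elements.** Wu type 1 = widespread, 2–7 = tropical, 8–15 =
  temperate (8–11 northern temperate, 12–13 Tethys, 14–15 East Asian),
  with a logged override mechanism for genera of disputed placement.
* **Time binning.** Counts, percentages and rates of diverging taxa per
  five-million-year window and per geological period since the Cretaceous,
  and the per-bin tropical–temperate balance

  HT = (H − T) / (H + T)

  (H, T = tropical and temperate genus counts; positive = tropical
  dominance, undefined when H + T = 0), plus the crossover time at which
  temperate elements overtake tropical ones.
* **Endemism.** A species is endemic when ≥ 90% of its occupied counties
  lie inside the focal region (inclusive boundary, configurable
  threshold); endemic genera are confined type-14/15 genera. Endemic
  divergence statistics use the same binning.

A seeded synthetic-data generator (`simulate_flora()`) produces every
input with known ground truth — birth–death trees with painted taxonomy
(including forced non-monophyly), era-dependent element labels following a
logistic temperate probability, and occurrence tables with a known endemic
set — so the whole pipeline is testable end to end.

## Worked example

```r
library(floristics)

f <- simulate_flora(seed = 42)
f
#> Synthetic flora (seed 42): 400 species, 100 genera, 25 families; tree height 144.25 Mya; 120 endemic species

fa <- flora_assembly(f$tree, f$taxonomy, f$type_table,
                     occurrences = f$occurrences, region = f$region)
fa
#> Flora assembly analysis
#>   tree: 400 species, height 144.25 Mya
#>   taxa: 25 families, 100 genera, 400 species
#>   classified genera: 100
#>   tropical->temperate crossover: 10 Mya
#>   endemics: 120 species, 0 genera

summary(fa)
#> Divergence by geological period (counts and % of rank total):
#>            period family_count family_pct genus_count genus_pct species_count species_pct
#>  Early Cretaceous            1          4           1         1             0         0.0
#>   Late Cretaceous           13         52          10        10             1         0.2
#>         Paleocene            4         16           1         1             1         0.2
#>            Eocene            6         24          30        30             8         2.0
#>         Oligocene            1          4          44        44            17         4.2
#>           Miocene            0          0          12        12           180        45.0
#>          Pliocene            0          0           2         2            80        20.0
#>        Quaternary            0          0           0         0           113        28.2
#> ...
#> Tropical->temperate crossover: 10 Mya
#> Endemics: 120 species, 0 genera
```

Reading this: families arise mostly in the Cretaceous, genera peak in the
Eocene–Oligocene, species in the Miocene–Quaternary — the generator's
birth–death process reproduces the characteristic rank-ordered waves of
divergence. The element trajectory's HT ratio flips sign at 10 Mya, the
crossover built into the synthetic labels; `fa$endemism` recovers exactly
the 120 species the generator constructed as endemic.

Individual stages are plain functions: `read_dated_tree()`,
`prune_to_taxa()`, `stem_age()`, `divergence_table()`, `classify_genera()`,
`make_timescale()`, `element_trajectory()`, `crossover_time()`,
`endemic_species()` … For a config-driven run writing the full CSV bundle
plus a manifest:

```r
run_pipeline(demo_config_file(), out_dir = "demo_out")
```

See the vignette (`vignettes/flora-assembly.Rmd`) for the model, its
assumptions, and all numerical choices.

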