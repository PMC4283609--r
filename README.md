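# gabifauna

Beta diversity and interchange timing for Neogene South American mammal
faunas.

During most of the Cenozoic, South America was an island continent with
an endemic mammal fauna. As the Isthmus of Panama closed (~10–3 Ma),
North and South American mammals began exchanging in both directions —
the Great American Biotic Interchange (GABI). Quantifying that history
from fossil occurrence data raises three coupled statistical problems,
and this package implements the full workflow for all of them:

1. **Faunal dissimilarity structure.** Genus-level presence/absence
   lists per fossil assemblage are compared with the binary Bray–Curtis
   (Sørensen-complement) index,
   `d = (b + c) / (2a + b + c)`,
   where `a` is the number of shared genera and `b`, `c` the numbers
   unique to each assemblage (`d = 1` when nothing is shared). The
   dissimilarity matrix feeds UPGMA clustering (with a deterministic
   lexicographic tie-break and Newick export), nonmetric
   multidimensional scaling (Kruskal stress-1, pool-adjacent-violators
   monotone regression inside a SMACOF majorization loop, multi-start),
   and a distance-decay analysis (great-circle distance vs.
   dissimilarity, Mantel test, within-epoch pairs only).
2. **Richness-equalized group comparison.** Tropical and temperate
   faunas differ in richness, which biases raw dissimilarity. Every
   assemblage in a contrast is subsampled with replacement to the
   contrast's minimum richness (1000 replicates), replicate Bray–Curtis
   values are pooled across pairs, and groups are compared with
   Mann–Whitney U (exact null distribution when feasible, tie-corrected
   normal approximation otherwise).
3. **Interchange timing under age uncertainty.** Each immigrant genus'
   first appearance datum (FAD) is known only to an interval
   `[age_min, age_max]` Ma. Cumulative FAD curves are built by drawing
   one uniform age per record per replicate (1000 replicates) and
   counting records with age ≥ t at each 1-Myr edge; means and standard
   deviations are reported per edge, with a closed-form expected curve
   as an analytic cross-check. Genus accumulation curves over fossil
   collections (random method plus exact expectation) diagnose the
   sampling effort behind the record.

A seeded synthetic-data module generates occurrence matrices,
collection tables and FAD records with the statistical structure the
analysis assumes (biome-structured genus pools, epoch turnover,
per-collection detection, immigration schedules with interval noise),
so the entire pipeline is testable without any data download.

## Worked example

The `analysis/` directory holds the workflow as numbered scripts
(`01_simulate.R` … `06_fad_curves.R`), each a thin driver over the
package functions that writes its tables under `results/`. Running them
in order prints, among other things:

```
Mean pairwise dissimilarity: 0.904 (all > 0.6)
First bipartition separates biomes cleanly: TRUE
Distance decay (within-epoch pairs, n = 28): Mantel r = 0.617, p = 0.001

NMDS (2 dimensions, 1000 starts)
Best stress-1: 0.1148

              contrast n_pairs target_richness      mean         sd
              tropical       1              11 0.9361154 0.07499170
             temperate      10              20 0.8675601 0.08035331
 tropical vs temperate      10              11 0.9908740 0.03124386

temperate  cumulative FAD mean: 2.0 by 10 Ma, 7.0 by 5 Ma, 21.0 by 3 Ma
tropical   cumulative FAD mean: 0.0 by 10 Ma, 6.0 by 5 Ma,  9.0 by 3 Ma
```

Read: assemblages of the same biome and age share more genera than
cross-biome pairs even after richness equalization; dissimilarity grows
with geographic distance within a time slice; and the first interchange
migrants accrue in the temperate record around 10 Ma, with the
temperate count pulling ahead of the tropics after ~4 Ma — the same
qualitative structure the method recovers from real compilations. The
occurrence data here are simulated (seeded); the FAD table is the
packaged synthetic stand-in `inst/extdata/synthetic_gabi_fad_records.csv`.

The same workflow runs as one orchestrated call with a config:

```r
library(gabifauna)
run_pipeline(list(occurrences = "results/data/occurrences.csv",
                  metadata = "results/data/metadata.csv",
                  fads = system.file("extdata",
                                     "synthetic_gabi_fad_records.csv",
                                     package = "gabifauna"),
                  out_dir = "results/pipeline", seed = 1))
```

which writes per-stage CSV/JSON outputs and a manifest with input
digests, per-stage seeds and timings; rerunning with the same seeds
reproduces every file byte for byte.

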