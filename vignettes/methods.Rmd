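---
title: "Faunal dissimilarity and interchange timing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Faunal dissimilarity and interchange timing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabifauna)
```

This vignette documents the statistical machinery of the package: the
models and estimators, the tunable parameters and their defaults, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the design decisions that were genuinely open.

## The data model

The unit of analysis is the **assemblage**: a fossil locality treated
as one community sample, coded as a genus-level presence/absence
vector. Genus is the taxonomic unit because species-level
identifications are unresolved or incomparable across many Neogene
localities; open-nomenclature qualifiers (*cf.*, *aff.*) are merged
onto the bare genus by `normalize_genus()`, which is idempotent and
rejects empty names. Other qualifiers ("?", quotation marks) are not
interpreted — they are stripped with a warning rather than silently
dropped, since their inclusion criteria are a curatorial decision, not
a computable one.

Assemblage metadata (latitude, longitude, biome, epoch, optional
paleolatitude and elevation) come from a curated table and are
validated against closed vocabularies. Biome is **never inferred from
latitude**: a high-elevation site at 22°S can be temperate, so a
latitude rule would misclassify exactly the sites where the
tropical/temperate contrast is most interesting. The latitude fallback
`region_from_latitude()` (|lat| ≤ 23.437°) exists only for raw
coordinate inputs in the FAD module and is documented as an
approximation.

## Dissimilarity, clustering, distance decay

`bray_curtis_binary()` implements the presence/absence Bray–Curtis
index \((b+c)/(2a+b+c)\) — identically one minus the Sørensen
similarity, and exactly what ecological software computes as "binary
Bray–Curtis". It is 0 for identical genus sets and 1 for disjoint
ones; the tests verify the algebraic identity \(1 - 2a/(2a+b+c)\) on
random set pairs and cross-check the pairwise matrix against an
independent community-ecology implementation.

`upgma()` is written here rather than delegated, for two reasons: the
merge heights must follow the cophenetic convention (height = mean
between-cluster dissimilarity, so a two-leaf merge at 0.5 exports as
`(A:0.25,B:0.25);`), and ties must resolve identically on every
platform. Among equal-height candidate merges the pair whose
concatenated sorted labels sort lexicographically first wins. On
tie-free inputs the result is provably the same as average-linkage
`hclust`, and the test suite checks cophenetic equality on hundreds of
random matrices; ties are broken differently from `hclust`, which is
the point. Newick export goes through `ape` (whose `hclust` conversion
already uses the half-height ultrametric layout) with 6 significant
digits.

`distance_decay()` tabulates each assemblage pair's great-circle
distance (haversine on a sphere of radius 6371.0088 km — at
continental scales the difference from ellipsoidal or map-measured
distances is far below the scatter of the dissimilarities) against its
Bray–Curtis value, classifies pairs by biome, and quantifies the
association with a Mantel test: Pearson correlation of the vectorized
matrices, significance from random row/column permutations of one
matrix (default 999, seeded; identity draws are rejected so the
minimum attainable p is 1/(permutations+1)), with exact enumeration of
all label permutations available for n ≤ 7. Only within-epoch pairs
enter by default: cross-epoch pairs confound time and space. A
zero-variance matrix (all dissimilarities equal) is flagged degenerate
and returns NA rather than crashing.

## Nonmetric multidimensional scaling

`nmds_fit()` minimizes Kruskal's stress-1
\[
\sigma_1 = \sqrt{\frac{\sum_{i<j} (d_{ij} - \hat d_{ij})^2}
                      {\sum_{i<j} d_{ij}^2}},
\]
where \(d_{ij}\) are configuration distances and \(\hat d_{ij}\) their
least-squares monotone regression onto the rank order of the input
dissimilarities. The optimizer alternates a SMACOF (Guttman-transform)
majorization step with pool-adjacent-violators monotone regression
(`monotone_regression()`, weighted, stack-based). Numerical choices:

* **Ties** use the primary approach: tied dissimilarities are processed
  in order of the current configuration distances, so ties impose no
  constraint.
* **Disparity normalization**: after each regression the fitted vector
  is rescaled so \(\sum \hat d^2 = \sum d^2\) before the Guttman step,
  which keeps the configuration scale stable; stress itself is
  scale-invariant (verified by property test).
* **Convergence**: relative stress change below 1e-6, cap of 500
  iterations per start. The recorded stress trajectory is
  non-increasing to 1e-10 on every start, and the tests assert it.
* **Multi-start**: `n_starts` random Gaussian configurations (default
  1000), all drawn from one seeded generator so the same seed gives
  bit-identical results; the best final stress wins. Tests run 10–50
  starts; the random-search and classical-scaling baselines in the
  test suite confirm the refinement is doing real work.
* **Identifiability**: the winning configuration is centered, rotated
  to principal axes, and sign-fixed (largest-magnitude coordinate on
  each axis positive), since stress is invariant under rotation,
  reflection and translation.

All-equal dissimilarities give a degenerate instance: the fit warns
and returns an arbitrary valid configuration. Fewer than three points
is an error.

Which axis captures which factor depends on the relative strength of
the gradients, not on the algorithm: with the default generator the
biome gap (pools 10% shared) exceeds the epoch gap (50% turnover per
step), so axis 1 tracks biome; when turnover is pushed above the
province overlap the ordering flips and axis 1 tracks age, which is
the configuration the acceptance suite exercises.

## Richness-equalized group comparison

Richer faunas look more dissimilar under any incidence index simply
because they have more genera to fail to share. The comparison
therefore subsamples, per contrast, every involved assemblage down to
the **minimum richness in the contrast** (the per-subgroup reading; a
`rarefy_per_pair` flag offers the per-pair alternative, since the
procedure description admits both): `target` genera drawn *with
replacement*, duplicates collapsed to a presence set, Bray–Curtis on
the subsampled sets, 1000 replicates, pooled across all pairs of the
contrast. Pooling across pairs (rather than averaging per pair first)
is what makes a group's distribution a single object with one mean and
sd spanning several pairs.

One subtlety is worth stating precisely. Within a replicate, each
*distinct genus list* is subsampled once, sequentially from the seeded
generator, and assemblages sharing a genus list share the draw. This
has two consequences that the naive per-assemblage-independent scheme
lacks: two identical faunas have rarefied dissimilarity exactly 0
(indistinguishable communities should not acquire apparent
dissimilarity from the resampling machinery), and an assemblage
appearing in several pairs of a contrast is subsampled once per
replicate, as "resample all the localities" implies. Distinct lists
still receive independent draws, and the replicate mean matches the
exhaustive enumeration of draw outcomes on small instances (tested).

`mann_whitney_u()` compares the pooled distributions: midrank U, exact
null tail when \(n_a n_b \le 400\) with no ties, tie-corrected normal
approximation with continuity correction otherwise. Two-sided by
default; directional claims are read from the means, with one-sided
alternatives available.

**A calibration caveat, and a deliberate design decision.** Replicates
of the same assemblage pair are dependent, so Mann–Whitney on pooled
replicate vectors is pseudoreplicated: under a true null its rejection
rate at α = 0.05 is far above nominal (we measured ~0.8 at full pool
overlap). This is also why such comparisons produce astronomically
small p values on real data. The pooled test is retained as the
default because it is the procedure this workflow exists to implement,
and its p values should be read as descriptive strength-of-separation
summaries. For a calibrated test, `compare_groups(test_unit =
"pair_mean")` compares one mean per assemblage pair; its measured size
at the null is ~0.08 and its power against province structure at 20%
pool overlap is ~0.9, and it is what the package's own power/size
tests use.

## Accumulation curves

`accumulation_random()` implements the random method: cumulative
distinct-genus counts over `n_perm` random orderings of collections
(default 1000, seeded), reporting per-step mean, sd and a 95% interval
(mean ± 1.96 sd by convention; permutation quantiles by flag — the
normal band can exceed the data range at tiny n, which is why the flag
exists). Collections with no genus records are retained by default
(they stall the curve honestly, since a fossil collection can lack
genus-level mammal records); `drop_empty` removes them.
`accumulation_exact()` is the closed-form expectation
\(E[S_k] = \sum_g \left(1 - \binom{N-n_g}{k}\big/\binom{N}{k}\right)\),
computed with log-binomials for stability; it is non-decreasing and
concave, and the permutation mean converges to it at the Monte-Carlo
rate. Exclusion of problematic collections (e.g. material without
stratigraphic provenance) is the caller's decision via the input
table, never hard-coded.

## FAD curves under age-interval uncertainty

Each FAD record carries an age interval \([a_{\min}, a_{\max}]\) Ma.
`cumulative_fad_curve()` draws one uniform age per record per
replicate (zero-width intervals return the point exactly) and counts
records with age ≥ t at each grid edge (default 12 → 0 Ma by 1), so
"by 10 Ma" includes a record at exactly 10 — the closed-edge
convention that makes a record whose interval bottoms out at 10 Ma
count fully at the 10 Ma edge. Means and sds are taken across 1000
replicates. `expected_fad_curve()` is the exact expectation
\(\sum_r P(U_r \ge t)\) and anchors the Monte-Carlo tests; per
replicate the count is non-decreasing toward the present by
construction, and tropical + temperate curves sum to the unfiltered
curve in expectation. Histogram binning of collections uses interval
midpoints with bins closed at the younger edge. Origin classification
(which continent a genus belongs to before the interchange) is input
data, validated for consistency — one origin per genus, recording
continent different from origin — but never inferred: that is
phylogenetic judgment, not computation.

The packaged table `synthetic_gabi_fad_records.csv` is a **synthetic
stand-in** for a curated interchange FAD compilation: 68 records whose
counts and intervals were constructed once to emulate the qualitative
immigration history — two late-Miocene ground-sloth records in the
temperate north around 10 Ma, slow accrual to the mid-Pliocene
(tropical and temperate counts comparable through the late Miocene), a
steep post-4-Ma rise concentrated at temperate latitudes, and a
Pleistocene surge in both regions. It lets the timeline analyses run
end to end and is labelled synthetic everywhere; it is not the
published compilation and is never presented as data about the fossil
record.

## The synthetic-data generator

`simulate_occurrences()` builds, per epoch, two province genus pools
sharing a fraction `overlap` of their `pool_size` genera; per epoch
step, a fraction `turnover` of the shared block (jointly) and of each
unique block (independently) is replaced by new genera. Each
assemblage draws a true genus list (richness uniform in
`richness_range`) from its province-epoch pool and is observed through
`collections_per_assemblage` independent collections, each detecting
each locally present genus with probability `detection_prob`; the
observed matrix is the union of detections, and the truth (pools and
true lists) is returned for recovery tests. Defaults mirror the study
design this package was built around: the 2/2, 2/5, 0/2
assemblage-per-biome-per-epoch layout of a thirteen-assemblage
compilation, pools of 120 genera, 10% between-province overlap, 50%
turnover per epoch, richness 10–45, and 20 collections detecting at
0.15 — chosen so that observed richness visibly undersamples the
fauna, as the accumulation curves of real tropical assemblages do.

What the generator deliberately does **not** emulate: real taxon
names, body-size or ecological covariates, spatially explicit
dispersal, taphonomy beyond per-collection Bernoulli detection, and
gradual (rather than stepwise) faunal turnover. Passing recovery tests
therefore shows that the estimators recover the structure this model
encodes — province pools, epoch turnover, detection-thinned sampling —
not that real Neogene data satisfy the model.

`simulate_fads()` draws true first-appearance ages uniformly in
`true_fad_range` per direction, reports each as an interval of width
drawn from `interval_width_range` centered on the true age (clipped at
0), and assigns the recording region by a Bernoulli `region_mix`. The
expected curve of the reported records brackets the true step function
within half the maximum interval width — the parameter-recovery bound
the acceptance suite checks.

## Pipeline and reproducibility

`run_pipeline()` executes read → dissimilarity → clustering → NMDS →
distance decay → group comparison → accumulation → FAD curves from a
validated config (list or YAML), writing flat CSV/JSON plus a manifest
of input digests, per-stage status, seeds and wall-clock. Per-stage
seeds derive from the master seed by fixed offsets, so any stage rerun
in isolation reproduces its numbers; a stage whose outputs exist is
skipped unless an upstream stage ran, which makes the pipeline
restartable by deleting a stage's files. Every stochastic function in
the package takes an integer seed, restores the caller's RNG state on
exit, and is bit-reproducible.

Problem sizes in the shipped scripts and tests — a thirteen-assemblage
study emulation, 1000 resampling replicates and NMDS starts in the
analysis scripts, 10–50 starts and 100–400 replicates in the tests —
were chosen as the sizes at which every Monte-Carlo check sits well
inside its tolerance while the whole suite stays quick to run.

## Known limitations

* Abundance-weighted Bray–Curtis, alternative linkages, PERMANOVA /
  ANOSIM, and ≥3-D ordination tuning are out of scope.
* The Mantel test quantifies a distance-decay relationship described
  only qualitatively in the literature this workflow mirrors; r and p
  are this package's quantification, not a published value.
* The pooled Mann–Whitney p is anticonservative by construction (see
  above); use `test_unit = "pair_mean"` when a calibrated test is the
  goal.
* Published-value reproduction requires the source study's
  supplementary occurrence and FAD tables, which are not
  redistributable here; the corresponding acceptance block documents
  where to place them and fails visibly in their absence.
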