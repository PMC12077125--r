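# glycoferm

Structure–function analysis of prebiotic dietary fibers screened against
panels of human fecal donor microbiotas in vitro.

Fiber preparations are complex substrates — distributions over
monosaccharides, glycosidic linkages and molecular sizes — and fecal
communities differ strongly between donors. `glycoferm` implements the
full analysis chain for a multi-donor fermentation screen:

* **Glycomics** — linkage peak areas normalized to monosaccharide
  composition (per parent sugar, conserving mass to machine precision),
  hierarchical *phyloglycomic* grouping of fibers under Euclidean
  distance, size-bin summaries, and nearest-group classification of novel
  fibers.
* **Ecology statistics, from first principles** — Bray–Curtis, Gower and
  weighted UniFrac dissimilarities
  ($\sum_b \ell_b\,|A_b - B_b|$ over phylogeny branches), non-metric
  multidimensional scaling by stress majorization (Kruskal stress-1,
  monotone descent enforced), and one-way PERMANOVA
  ($F = \frac{(SS_T - SS_W)/(a-1)}{SS_W/(N-a)}$ on squared distances)
  with exact enumeration for small designs and +1-corrected permutation
  p-values otherwise.
* **Determinism scoring** — the headline statistic of this kind of
  screen: ordinate all donors × treatments jointly, shift each donor's
  untreated control to the origin, and average the pairwise cosine
  similarity of donor displacement vectors per fiber. Scores near 1 mean
  the glycan drives the response in every donor; near 0, donor
  idiosyncrasy dominates.
* **SCFA summaries** — per-metabolite max-scaling for heatmaps with
  two-way hierarchical ordering, butyrate:propionate ratios, and
  donor-penetrance CCDF curves ("what fraction of donors reach at least
  this butyrate level?") with their survival-level inverse.
* **Group statistics** — Kruskal–Wallis, Dunn's test against a reference
  treatment with Benjamini–Hochberg correction (the "not significantly
  different from the reference prebiotic" call), and random-forest
  attribution of structural features to fermentation outcomes.
* **Assay calibrations** — qPCR standard curves (efficiency, LOD,
  censored absolute quantification) and BCECF ratiometric pH.
* **A seeded synthetic-data generator** that emulates the whole design —
  donor-sparse communities, functionally redundant SCFA-producer guilds,
  and a single knob `lambda` setting the glycan-driven fraction of the
  response — so every statistic is validated against planted truth.

## Worked example

```r
library(glycoferm)

cfg   <- simulation_config(seed = 42)   # 20 donors, 100 taxa, 12 fibers + untreated
study <- simulate_study(cfg)
study$dataset
#> <fermentation_dataset> 1040 samples, 20 donors, 13 treatments
#>   time points (h): 0, 6, 10, 24
#>   taxa matrix: 100 taxa
#>   metabolites: acetate, propionate, butyrate, lactate
#>   phylogeny: 100 tips

# phyloglycomic grouping of the fibers by monosaccharide composition
grp <- phyloglycomic_cluster(build_profile_matrix(study$fibers, "mono"), k = 5)
grp
#> <phyloglycomic_grouping> 12 fibers in 5 groups (complete linkage)
#> A B C D E
#> 3 2 2 2 3

# determinism of the SCFA response: joint NMDS at 24 h, per-donor
# untreated-normalization, mean pairwise cosine similarity per fiber
res <- fermentation_shift_scores(study$dataset, layer = "metabolites", seed = 42)
res$ordination
#> <ordination> 260 samples in 2 dimensions, stress-1 = 0.0417 (converged, 2 restarts, seed 42)
head(res$scores[order(-res$scores$score), ], 4)
#>    treatment     score n_pairs n_excluded
#> 6   fiber_06 0.9923125     190        0
#> 11  fiber_11 0.9905869     190        0
#> 1   fiber_01 0.9896906     190        0
#> 4   fiber_04 0.9769953     190        0

# donor penetrance: the butyrate level at least half the cohort reaches
at24 <- subset(study$dataset$samples, time_h == 24 & treatment == "fiber_01")
cc <- ccdf_curve(study$dataset$metabolites[at24$sample_id, "butyrate"])
level_at_survival(cc, 0.5)
#> [1] 4738.609
```

The grouping recovers the five planted fiber families exactly. The scores
near 1 reflect the generator's default `lambda = 0.9` (a strongly
glycan-driven response): all 20 donors shift the same way under the same
fiber, across 190 donor pairs each. The penetrance summary says half the
cohort produced at least ~4.7 mg/mL butyrate under `fiber_01`.

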