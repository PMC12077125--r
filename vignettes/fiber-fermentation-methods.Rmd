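---
title: "Methods: scoring fiber structure-function relationships across donor microbiotas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring fiber structure-function relationships across donor microbiotas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoferm)
```

## The problem

Dietary fibers are screened for prebiotic potential by fermenting them in
vitro with human fecal microbiotas and measuring the short-chain fatty
acids (SCFAs) and community shifts they elicit. Two facts complicate the
analysis. First, the substrate itself is complex: a fiber preparation is a
distribution over monosaccharides, glycosidic linkages, and molecular
sizes, and chemically similar fibers tend to behave similarly — so fibers
must first be placed into *phyloglycomic groups* by their composition.
Second, donors differ enormously: fecal communities share only part of
their membership, so the same fiber can recruit different taxa in
different people. The central scientific question is whether the
*functional* outcome (the SCFA profile) is nevertheless determined by the
glycan structure — i.e. whether functionally redundant taxa make the
response deterministic even when the responding taxa differ.

`glycoferm` implements the complete analysis chain for this design, plus a
generative model of the whole experiment so that every statistic can be
validated against planted ground truth.

## Glycomic normalization and grouping

Raw glycosidic-linkage peak areas are not mutually comparable because
linkages ionize at different rates (terminal linkages inflate their
signal). `normalize_linkages()` therefore rescales, for each parent
monosaccharide, the raw areas of its annotated linkages so that they sum
exactly to that monosaccharide's measured relative abundance. This
conserves mass by construction: the per-parent subsums equal the
monosaccharide composition to machine precision, and the full normalized
linkage vector sums to 1. A monosaccharide with measured abundance but no
annotated linkages keeps its mass under an explicit `unannotated-<m>`
feature rather than being dropped, because linkage catalogues are always
incomplete.

Fibers are grouped by agglomerative hierarchical clustering of their
monosaccharide composition under Euclidean distance
(`phyloglycomic_cluster()`). The monosaccharide layer, not the sparser
linkage layer, is the default grouping basis: linkage sparsity fragments
the dendrogram into many singleton groups. The linkage method defaults to
`"complete"` — the convention of the standard heatmap tooling in this
field — and is configurable. The group count `k` is user-supplied; the cut
is recorded as an explicit height so labels are reproducible from the
dendrogram. All tie-breaks resolve to the lowest input index, and group
letters are assigned in dendrogram left-to-right order, which need not
match any particular published lettering.

Novel fibers are classified by nearest mean distance to each group's
reference members (`classify_novel_fiber()`), with Euclidean distance on
the monosaccharide layer or Bray-Curtis on the normalized linkage layer.
Features unseen in the references are zero-filled; a novel fiber whose
mass lies mostly off-support is still classified but flagged, since all
its distances are then near-maximal and the prediction carries little
information.

## Ecology statistics from first principles

The dissimilarity measures and inference used downstream are implemented
directly from their definitions, and the test suite holds them against
independent brute-force oracles:

* **Bray-Curtis** $\sum_i |x_i-y_i| / \sum_i (x_i+y_i)$ for SCFA and
  community profiles.
* **Gower** — the mean range-normalized absolute difference — for
  mixed-scale SCFA panels; zero-range features are excluded with a
  warning. Both Gower and Bray-Curtis are offered for SCFA dissimilarity
  and the choice is a parameter, since either is defensible for
  concentration panels.
* **Weighted UniFrac** $\sum_b \ell_b\,|A_b - B_b|$ over branches, with
  $A_b$ the summed relative abundance of taxa descending branch $b$. The
  default is the raw (unnormalized) form, the common "weighted UniFrac" of
  16S pipelines; the normalized form (dividing by
  $\sum_j d_j (A_j+B_j)$) sits behind a flag. Relative abundances are used
  directly, without rarefaction.
* **NMDS** by stress majorization: each iteration alternates a Guttman
  transform with monotone regression of configuration distances on the
  dissimilarity order. Ties in the dissimilarities are pooled (tied blocks
  share one fitted disparity), which keeps the descent stable. A
  step-halving safeguard enforces that Kruskal stress-1 never increases
  within a restart; the first restart starts from classical scaling,
  subsequent restarts from seeded random configurations, and the
  best-stress solution wins. Convergence tolerance is `1e-6` on the
  stress change, capped at 200 iterations.
* **PERMANOVA** with the squared-distance decomposition
  $SS_T = \frac{1}{N}\sum_{i<j} d^2_{ij}$,
  $SS_W = \sum_g \frac{1}{n_g}\sum_{i<j\in g} d^2_{ij}$ and pseudo-F
  $\frac{(SS_T-SS_W)/(a-1)}{SS_W/(N-a)}$. When the number of distinct
  label assignments is no larger than the requested permutation count the
  enumeration is exhaustive and the p-value exact; otherwise the
  Monte-Carlo p-value uses the +1 correction and never reports 0. A
  constant distance matrix yields F = 1 identically (every relabeling
  gives the same decomposition), so the result is flagged degenerate
  rather than treated as evidence.

## The determinism score

The paper-level statistic is built in three steps
(`fermentation_shift_scores()` runs them end to end):

1. One **joint ordination** of all donors × treatments at the analysis
   end point (24 h by default; the time point is a parameter, never
   hard-coded, because some designs sample at 20 h and lactate peaks
   mid-fermentation).
2. **Per-donor normalization** (`normalize_shifts()`): each donor's
   untreated coordinates are subtracted from all of that donor's samples,
   so every untreated control sits at the origin and each fiber leaves a
   2-D displacement vector per donor. Displacements are computed in the
   ordination plane, as the overlaid figures in this literature imply,
   not in raw profile space.
3. **Mean pairwise cosine similarity** (`mean_pairwise_cosine()`): for
   one fiber, the cosine similarity of every unordered donor pair's
   displacement, averaged. A score near 1 means all donors moved the same
   way — a glycan-driven, deterministic response; near 0 means donor
   idiosyncrasy dominates. Zero displacements (cosine undefined) are
   excluded from the average and counted, so the pair count is auditable.

`kmeans_trajectories()` additionally clusters the donor-averaged
displacement per treatment, reproducing the observation that
high-butyrate fibers travel together.

## The generative model

`simulate_study()` emulates the multi-donor design so that every stage
above can be tested against known truth. Defaults mirror the scale of the
study design the package targets: 20 donors, 100 taxa, 12 fibers in 5
phyloglycomic groups plus an untreated control, sampled at 0/6/10/24 h.

* **Fibers**: monosaccharide compositions are Dirichlet draws around
  per-group templates (glucan, galacto/glucomannan, (arabino)xylan,
  arabinan/pectin, galactan) with concentration 200 — tight enough that
  groups are recoverable, loose enough that fibers are distinct. Raw
  linkage areas are built as monosaccharide share × linkage split ×
  ionization bias (terminal linkages biased 1.6×), so the raw areas
  deliberately violate monosaccharide closure until normalized. Size-bin
  distributions are per-group Dirichlet draws over five kDa bins, with
  the galactan-like group carrying a large >1000 kDa tail.
* **Donors**: per-taxon Bernoulli presence (a prevalent core at 0.95, a
  variable tail at 0.35) with log-normal abundances among present taxa,
  closed to 1. This produces partially overlapping communities with
  donor-unique taxa, the sparsity phenomenon the multi-donor design has
  to cope with.
* **Response**: taxa carry guild-derived affinity vectors over
  monosaccharides (butyrate producers respond to glucan/xylan features,
  propionate producers to arabinan/pectin, bifidobacteria to
  galactose/fructose). For donor $d$ and fiber $f$ the response exponent
  of taxon $t$ is
  $\eta_t = \lambda\,(a_t \cdot f) + (1-\lambda)\,\varepsilon_{d,t}$, and
  the 24 h community is the baseline tilted multiplicatively,
  $x'_t \propto x_t e^{\eta_t}$, then re-closed. The tilt respects
  compositionality and guarantees absent taxa never bloom, which is what
  produces donor-specific responders. $\varepsilon$ is drawn once per
  (donor, taxon) and reused across treatments, and untreated controls
  have $\eta = 0$ exactly — together these make $\lambda$ the single
  interpretable knob: at $\lambda = 0$ every treatment displaces a donor
  the same idiosyncratic way (score ≈ 0 across donors), at $\lambda = 1$
  displacement is set by the fiber alone (score ≈ 1).
* **Metabolites**: baseline + yield matrix × guild-aggregated endpoint
  abundance, scaled by a per-metabolite time ramp (saturating for the
  SCFAs; lactate rises then falls, peaking mid-fermentation), plus
  Gaussian measurement noise truncated at 0. Yields are calibrated only
  to qualitative orderings (glucan-responsive guilds yield the most
  butyrate; reference-prebiotic-like substrates are bifidogenic); they
  are not fitted to any measured dataset. OD600 rises and pH falls
  monotonically with total production.

What the generator does *not* emulate: kinetic feedback (no ODEs, no pH
inhibition of growth), gas production, sequencing noise or compositional
count sampling, cross-feeding between guilds, and real phylogenetic
signal in guild membership (the tree is a random coalescent). Passing the
recovery tests therefore shows the *statistics* behave as designed under
the assumed response structure — it does not validate the biology of any
particular fermentation.

## Assay calibrations

qPCR absolute quantification fits `Cq = intercept + slope·log10(conc)` to
a serial dilution series (≥ 3 points spanning ≥ 2 decades), derives
amplification efficiency `10^(-1/slope) - 1` (flagged outside 90–110%),
and sets the limit of detection to the lowest dilution whose replicates
all amplified; estimates below the LOD are censored at it. The BCECF pH
readout treats 405/475 nm as an opaque ratio channel pair and
interpolates linearly between calibration points — within the buffered
fermentation range (pH 5.8–6.8) the dye is near-linear, and readings
outside the calibrated range are flagged as extrapolated.

## Numerical and design choices

* Relative abundances are stored as fractions (sum 1) everywhere;
  percentages are presentation only.
* Every stochastic function takes an explicit integer seed and is
  bit-reproducible given it.
* Tie-breaks resolve to the lowest input index (clustering, dominant size
  bin).
* The Benjamini-Hochberg family for Dunn's test is the set of
  vs-reference comparisons within one response variable, matching how
  per-panel "not different from reference" annotations are made; users
  who want a wider family can adjust across calls.
* Dunn's test defaults to donor-level observations as replicates; a
  caller can aggregate to donor means first if their design demands it.
* The problem sizes used in the validation suite (6-fiber, 20-donor
  simulations; 50-seed score replications; 1,000-run null calibrations)
  were chosen as the smallest sizes at which the Monte-Carlo noise is
  clearly below the effect being checked.

## Known limitations

* The NMDS embedding dimension for the shift analysis defaults to 2; the
  score is defined in whatever dimension is chosen, and sensitivity to
  `dims` is the user's to explore.
* `classify_novel_fiber` assumes the grouping's feature space is
  meaningful for the novel fiber; heavy off-support mass is flagged but
  not rejected.
* PERMANOVA is one-way only; donor cannot be modeled as a random effect
  (out of scope by design).
* The determinism score is reported descriptively, without a significance
  test, as is conventional for this statistic.
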