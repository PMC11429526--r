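---
title: "Methods: quantifying tumor endothelial cell heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying tumor endothelial cell heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tecatlas)
```

## Scope and data model

Endothelial cells (ECs) are rare in tumor biopsies, so their fine-grained
heterogeneity is usually studied on integrated single-cell atlases where
every cell already carries a subset label (e.g. an angiogenic `CXCR4`+
tip-cell subset, a proinflammatory `SELE`+ vein subset), a major
compartment (tip / vein / capillary / artery / lymphatic), a cancer type,
and a tumor-vs-adjacent-normal tissue label. `tecatlas` implements the
downstream statistics for such an atlas: per-cell gene-set activity,
compositional enrichment, cross-cancer marker screening, spatial
co-localization on imaging-based data, and clinical association. Upstream
steps (QC, integration, clustering, embedding) are deliberately out of
scope; the package consumes labeled cells.

The shared container is the `CellAtlas`: a sparse cells × genes count
matrix plus per-cell metadata, validated for the invariants every
operation relies on (unique cell ids, a strict tumor/normal vocabulary,
and a single (cancer type, tissue) pair per sample). All expression-level
operations work on a common normalization — counts per 10,000 followed by
`log1p` — the standard single-cell practice; the scale factor is a
parameter of `normalize_counts()` and `pseudobulk()`.

## Gene-set activity: the recovery-curve AUC

Per-cell activity of a gene set (angiogenesis, collagen formation,
leukocyte–endothelial adhesion, ...) is scored by ranking genes within
each cell by raw count and measuring how early the set's members are
recovered. With $k = \lceil f \cdot G \rceil$ top positions (default top
fraction $f = 0.05$), the score is

$$\mathrm{score} = \frac{\sum_{i=1}^{k} \#\{s \in S : r_s \le i\}}
                        {\sum_{i=1}^{k} \min(i, |S|)} \in [0, 1],$$

the area under the cumulative recovery curve normalized by its maximum
(all set genes at the very top). Because only within-cell ranks enter,
the score is invariant to any monotone transform of the counts, which
makes it robust to depth differences. Ties are broken by *average rank*
by default so results are deterministic; a seeded random tie-break mode
(`ties = "random"`) exists for parity with implementations that
randomize ties. With average ties a set gene at fractional rank $r$
contributes from position $\lceil r \rceil$ on.

For bulk expression (e.g. TCGA-style cohorts) the signature score is the
mean across set genes of per-gene z-scores across samples
(`bulk_signature_score()`), and the balance between two signatures — the
proinflammatory vein signature relative to the angiogenic tip signature —
is summarized per sample by `relative_score()`. The default is the
difference of z-scored signatures: a literal quotient of signed z-means
is numerically unstable whenever the denominator crosses zero, whereas
the z-difference is location/scale-free and monotone in both inputs. A
`"ratio"` mode (quotient after shifting both scores positive) is kept for
users who want a literal ratio; the choice of default is ours and is
documented rather than asserted as canonical.

## Compositional enrichment: Pearson residuals

Tissue enrichment of subsets uses the observed/expected ("Ro/e")
contingency analysis: with $E_{ij} = r_i c_j / N$ from the chi-square
independence model, the Pearson residual
$(O_{ij} - E_{ij})/\sqrt{E_{ij}}$ is positive exactly when subset $i$ is
over-represented in condition $j$. The default pools cells across samples
(`mode = "pooled"`), matching how a single tumor-tissue residual per
subset is usually reported. Because a few very large samples can dominate
a pooled table, a stratified variant computes, for every sample, the
residual of its subset counts against the atlas-wide subset frequencies
and averages these residuals within each condition, giving every sample
equal weight. Whether pooling or stratification is the "right" choice
depends on the sampling design, so both are exposed; pooled is the
default. Expected counts below 5 trigger a warning (the chi-square
approximation degrades) but never a failure.

Sample-level comparisons (compartment abundance between tissues,
responder versus non-responder frequencies, adjacent tumor stages) use
the two-sided unpaired Wilcoxon rank-sum test throughout, with
Benjamini–Hochberg adjustment applied within each analysis family (all
subsets of one comparison; all cancers of one Cox screen) — the scope of
every BH family is recorded in the output. Cancer types are clustered by
average-linkage on Euclidean distances between mean composition vectors;
an Aitchison (CLR) distance is available by flag for users who prefer a
compositional geometry, with a pseudo-frequency of half the smallest
nonzero frequency.

## Cross-cancer marker screening

Differential expression between cell groups is the two-sided Wilcoxon
rank-sum test on log-normalized expression with BH adjustment across
genes; log2 fold changes compare group means with a 1e-9 pseudocount.
Small tie-free groups use the exact null distribution; larger groups use
the tie-corrected normal approximation with continuity correction,
computed in one vectorized pass and agreeing with
`stats::wilcox.test(exact = FALSE)` to floating-point accuracy (this is
tested, and the null calibration of the whole pipeline is checked on a
no-effect negative-binomial atlas).

"Top-upregulated" lists keep genes with `log2fc >= 0.25` and
`p_adj <= 0.05`, ordered by adjusted p, then absolute fold change, then
symbol, capped at `n_top = 100`. Each listed gene receives a linear rank
score $(n_{top} - \mathrm{rank} + 1)/n_{top}$ — bounded, monotone, and 1
for the top gene; a `1/rank` alternative sits behind a flag. Conservation
across cancers counts, per gene, the cancers whose top list contains it
and averages the rank score over *all* analyzed cancers, contributing 0
(not missing) where a gene is absent, so a gene strong in one cancer
cannot outrank a gene moderately up everywhere. The conserved TEC
signature is the intersection of (i) genes upregulated in all four blood
vascular compartments (the all-categories pattern of the distinct-mode
intersection, in which every gene belongs to exactly one membership
pattern) and (ii) genes upregulated in at least a majority of cancers,
ordered by mean rank score. Signature quality is summarized by the
rank-based (Mann–Whitney) AUC of the mean signature expression as a
tumor-vs-normal EC discriminator, with ties counted ½.

The exact fold-change and adjusted-p thresholds behind published
"top-upregulated" lists are rarely stated; ours are the defaults above,
configurable, and documented rather than claimed to match any particular
study.

## Spatial co-localization

Imaging-based data enter as typed point patterns (one `SpatialSlice` per
section). Two complementary analyses mirror common practice:

* **Region sampling.** Square regions (default side 1000 units, in the
  slice's native units) are drawn uniformly from the admissible origin
  rectangle; counts use half-open squares so boundaries are unambiguous.
  Regions are grouped by their focal-cell count — "high" at ≥ 5 focal
  cells, "low" at 0 by default, both configurable since published
  groupings are rarely explicit — and companion-cell counts are compared
  between groups by rank-sum test.
* **Neighborhood residuals.** All non-focal cells within radius $r$ of
  any focal cell are pooled and their type composition is compared with
  the slice-wide composition via Pearson residuals. Neighbors are counted
  once per focal cell they neighbor (multiplicity reflects neighborhood
  *exposure*; a deduplicated variant is a flag — both are defensible and
  the choice is stated in the output). The neighborhood radius is not a
  quantity with a canonical value; the default is 50 units and every
  analysis is radius-parameterized. Distances are Euclidean with no edge
  correction: regions are sampled fully inside the window, and the
  permutation-null calibration below shows the residual test holds its
  level without one.

Two focal types are contrasted across slices by a paired two-sided t-test
on the target type's residual. Degenerate inputs are reported, not
silently tested: all-zero differences give $t = 0, p = 1$; a constant
nonzero difference (zero variance) is flagged as exact separation with
`p = NA`.

## Synthetic data with planted truth

Every analysis stage is validated on generated data whose ground truth is
known, via one seed-deterministic generator per data kind. The defaults
are fixed study conditions, not tuning knobs.

* **Atlas.** Negative-binomial counts (dispersion 0.5, the typical
  scRNA-seq overdispersion scale; library sizes log-normal around 2,000)
  with per-cell mean `libsize * softmax(base + planted effects)`. The
  subset catalog plants a tumor-enriched tip subset (30% vs 10%) and a
  tumor-depleted vein subset (10% vs 30%), i.e. 3:1 frequency ratios in
  either direction; each subset over-expresses a 10-gene marker block by
  2 on the log2 scale; two designated programs ("angio", "collagen")
  receive per-cell log-scale activity multipliers that are bivariate
  normal with correlation 0.6, reproducing a positive score–score
  coupling with a single parameter. Optional *tumor programs* plant gene
  blocks upregulated only in tumor cells of chosen compartments and
  cancers, which is what the conserved-signature validation uses.
  Because the softmax renormalizes relative expression, a planted log2
  effect of $e$ realizes a fold change visibly smaller than $2^e$ (about
  half, at these block sizes); validation scenarios therefore state
  planted effects on the realized scale they target — log2 effect 2
  (≈2× realized, the conventional marker-gene magnitude) for the
  moderate-noise recovery study, log2 effect 4 for the noiseless arm.
* **Spatial.** Companion types (epithelial cells, T cells) are Thomas
  cluster processes: Poisson niche centers with Gaussian-scattered
  offspring (σ = 150 units on a 3000-unit window). Focal tip-like cells
  are placed inside epithelial niches with probability
  $s/(1+s)$ (co-localization strength $s = 4$ → 80% niche placement) and
  uniformly otherwise; vein-like cells likewise inside T-cell niches.
  $s = 0$ recovers independent uniform placement, $s = \infty$ hard
  confinement. The generator's cluster primitive is checked against the
  analytic Thomas-process neighbor expectation
  $\lambda\pi r^2 + \mu(1 - e^{-r^2/4\sigma^2})$.
* **Clinical.** Survival is exponential with hazard
  $h_0 \exp(\beta\,\mathrm{score} + \text{covariate effects})$
  ($h_0 = 0.002$/day; age, gender and stage effects of 0.01, 0.2 and
  0.15 on the log-hazard), censored by an independent exponential clock
  calibrated to the configured censoring fraction (0.3). Stage is drawn
  from a latent Gaussian shifted by the score, planting a monotone
  score–stage trend. The therapy-response table draws one focal-subset
  proportion per cancer uniformly on [0.05, 0.5] and sets
  $\mathrm{ORR} = 10 + 80\,p + \varepsilon$, $\varepsilon \sim N(0,
  10.5^2)$, clipped to [0, 100] — parameters chosen so the population
  correlation is 0.70, a strong but noisy cross-cancer association.

What the generator does *not* emulate: real per-cancer expression
profiles, doublets, ambient RNA, batch effects, or informative censoring.
Passing the planted-truth studies therefore demonstrates that the
statistics recover known structure under their stated assumptions — not
that any particular biological dataset satisfies those assumptions.

## Clinical association

Per-cancer Cox models regress overall survival on the z-scored signature
with age, gender and stage corrected, with BH adjustment across cancers
and a pooled fit whose baseline hazard is stratified by cancer type.
Stage enters as an ordered numeric covariate by default (categorical
behind a flag): with four levels the numeric coding costs little and is
far more stable in small cancers. Kaplan–Meier comparisons split at the
median score (ties to the low group) and use the log-rank test; an
optimal-cutpoint split is deliberately not offered as a default because
cutpoint optimization inflates type-I error. The fitting engine is
`survival::coxph`/`survdiff`; the module's contribution is the pipeline
contract around it (z-scoring, per-cancer looping, the BH family, the
stratified pooled fit, degenerate-input handling).

## Numerical choices and degenerate inputs

* Rank ties: average rank everywhere (scores, DE, AUC with ties ½).
* DE p-values: exact enumeration only for small tie-free groups
  (matching `wilcox.test` semantics); otherwise tie-corrected normal
  approximation with continuity correction.
* All-zero cells keep library size 1 during normalization so they map to
  all-zero profiles instead of NaN.
* Zero-variance genes are excluded from z-score signatures with a
  warning; an all-constant set is an error, as are constant scores in a
  Cox fit or a median split with no spread.
* Hierarchical clustering sorts inputs by label before agglomeration so
  leaf order is reproducible across input orderings.
* Every generator draws through an isolated RNG scope keyed by
  `config$seed`, so identical configs give bit-identical outputs and the
  caller's RNG stream is untouched.

## Validation scale

The planted-truth studies run at deliberately desk-sized scales: 100
replicate seeds per scenario, atlases of a few thousand cells and a few
hundred genes, eight spatial slices of several hundred cells, clinical
cohorts of 300–500 samples, 500 label permutations for the spatial null.
These sizes give the Monte-Carlo error implied by each check's acceptance
band (binomial error on a rate estimated from 100 seeds is about ±5
points) while keeping the whole suite runnable on one CPU in minutes.
`scripts/acceptance.R` re-runs all of them from scratch under a single
command-line seed.

## Known limitations

* Enrichment residuals are descriptive effect sizes; no inferential
  correction for within-sample cell dependence is attempted.
* The rank-sum DE test inherits the usual pseudoreplication caveat of
  cell-level tests; a pseudobulk route is available via `pseudobulk()`
  but is not the default.
* The literal "ratio" mode of `relative_score()` depends on the shift
  constant near zero-spanning scores; prefer the z-difference.
* Spatial analysis assumes cell typing is given and correct; no edge
  correction is applied, so residuals very close to slice borders are
  mildly biased toward the slice composition.
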