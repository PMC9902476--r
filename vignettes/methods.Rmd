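---
title: "Quantifying intratumoral heterogeneity of Ki67 and tumor regression: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intratumoral heterogeneity of Ki67 and tumor regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ki67ith)
```

## The measurement problem

Tumor regression after neoadjuvant chemotherapy and the Ki67
proliferation index are usually reported as a single number per tumor.
Both are spatially heterogeneous: regression varies from block to block
of the same resection specimen, and Ki67 positivity varies from region
to region of the same section. This package implements a block-resolved
quantification: annotations (polygons delineating the former tumor bed,
the residual tumor, and Ki67 hotspot/coldspot counting regions, plus
classified cell marks) are turned into per-block metrics, case-level
aggregates, association statistics, and survival comparisons.

## Per-block metrics

* **TBR** `= 100 · A_residual / A_bed`, areas by the shoelace formula
  over the annotation polygons, converted to µm² with the pixel pitch
  (0.26 µm default, the scanner's pixel-to-pixel distance).
  Multi-part region sets are summed. Values marginally above 100 —
  possible because residual-tumor and bed outlines are drawn
  independently — are clipped to 100 with a warning.
* **Ki67 PI** `= 100 · red dots / all dots` inside a delineated
  polygon. A region is evaluable only with ≥ 100 counted cells;
  "not evaluable" is a distinct state from PI = 0. More than 500 dots
  warns (the manual counting cap) but all dots are used: the cap is an
  ergonomic constraint, not a statistical one.
* **KiH / KiL / KiD**: maximum and minimum evaluable region PI and
  their difference. With exactly one evaluable PI the value is KiH and
  KiL/KiD stay missing — so a block can contribute a hotspot PI (and a
  TBR) without contributing to the heterogeneity span, which mirrors
  the published block counts (more TBR than KiH than KiL blocks).
* **Inclusion**: ≥ 50 tumor cells on the screening cytokeratin slide.
* **Becker grade** as a total step function of residual tumor:
  1a only at exactly 0%, 1b on (0, 10), 2 on [10, 50], 3 on (50, 100].
  The published definitions ("<10%", "10% to 50%", ">50%") leave both
  boundaries ambiguous; we place 10 and 50 in grade 2, the coarser
  (more conservative) grade, and require literal completeness for 1a.

### Geometry conventions

Coordinates are 0-based pixel units. Containment uses the even–odd
ray-casting rule with boundary points counted **inside**: a dot placed
exactly on a drawn line belongs to the region, a deterministic
tie-break. Self-intersecting rings are rejected at parse time instead
of silently repaired; polygon holes are not supported (the annotation
tool drew simple outlines). Marks in overlapping counting regions are
counted in both, with a warning.

### Automatic hotspot/coldspot selection

For simulated slides (and annotation-free point patterns) the
pathologist's delineation is emulated by scanning circular windows
centered on marks, each holding the center's 500 nearest marks, and
keeping the windows with the extreme positive fractions. Ties break to
the lowest mark index; with many marks the candidate centers are
thinned deterministically (even index spacing). The window size of 500
mirrors the manual counting cap; nothing in the published method
defines the hotspot's spatial extent, so this is our choice and we keep
it fixed. The max/min over overlapping windows carries a small
selection bias (order +1–2 binomial standard deviations, i.e. a point
or two at 500 cells); the same bias is inherent in the manual method.

## Case aggregation and dichotomization

Case-wise parameters: `max KiH`, `min KiL`,
`case KiD = max KiH − min KiL`, and `mTBR` = median of the included
blocks' TBRs (even counts average the two central values). The
published study-design text says "KiD between the maximum KiH and
minimum KiH", but its cohort table labels the column
"KiD max KiH min KiL"; we follow the table. Cohort vectors are
dichotomized at their median with ties going to the `≥median`
(non-responder / high) group — the only convention that yields a
reproducible partition without randomization and matches the
`<median` / `≥median` column pairing. Responder status at an explicit
cutoff (10%, 20%) is strict: `mTBR < cutoff`. Quartile boundaries are
type-7 quantiles applied as half-open intervals (Q1 [0, q1],
Q2 (q1, q2], Q3 (q2, q3], Q4 (q3, 100]).

## The association battery

* **Exact tests.** Two-sided p is the point-probability ("sum of
  small p") definition: the total probability of all tables with the
  observed margins whose point probability is ≤ the observed one, with
  a `1 + 1e-7` guard against floating-point ordering artifacts. This is
  the convention of both SPSS (used for the published values) and R's
  `fisher.test`, and it reproduces the printed p-values exactly. The
  r×c (Freeman–Halton) version enumerates tables recursively with a
  feasibility bound and offers a seeded Monte-Carlo fallback.
* **Kendall tau-b** with tie corrections in the coefficient and the
  tie-adjusted variance of the concordance statistic S; two-sided p
  from the normal approximation (the SPSS convention), permutation
  inference available as an option. On the published Becker × min KiL
  table this gives 0.0136 vs the printed 0.012 — within the ±0.002
  that variance-estimator differences explain.
* **FDR.** Benjamini–Hochberg step-up per report column (one metric
  against all covariates). The published analysis does not state its
  family composition; per-column families are the most natural reading
  of the column-wise footnotes and are our fixed choice.

## Survival

Kaplan–Meier product-limit estimation with Greenwood variance and a
log-log transformed 95% band; median survival is the smallest event
time with S ≤ 0.5 and is reported as "not computed" when the curve
never reaches 0.5. Group comparison uses the Mantel–Cox log-rank
statistic (hypergeometric variance, chi-square with k−1 df). The
cut-off scan splits mTBR at the cohort median, 10%, 20%, and quartiles
for overall and tumor-specific survival; empty groups flag the row and
omit the p. Tumor-specific survival treats non-tumor deaths as
censoring at the time of death (the published analysis implies but
does not state this). Reproducing the published survival medians and
p-values is out of reach by construction — patient-level times were
never printed — so the survival module is validated against closed
forms, a permutation oracle, and the `survival` package instead.

## The synthetic cohort

The generator implements the subclonal-selection account of therapy
response, with every stochastic element behind one seed:

* A case carries 3–6 subclones, each with a pre-therapy positivity
  drawn from U(0.05, 0.85) and a survival probability
  `θ^(1 + 1.5 · positivity)`, where θ ~ Beta(1.1, 2.2) is the
  case-level resistance. The exponent makes rapidly proliferating
  subclones preferentially chemo-sensitive; the Beta prior puts the
  cohort's median mTBR near 12%, the published case-wise median. The
  positivity ceiling of 0.85 keeps `positivity + release boost ≤ 1`.
* A block is a blob-shaped tumor-bed polygon (radial noise 0.12 around
  a 90–130 px radius) partitioned into nearest-seed territories, with
  cells as a homogeneous Poisson process (≈10⁴ cells/block).
  **Regression contracts footprints**: the surviving fraction of a
  territory is the sub-region nearest its seed, at unchanged cell
  density — residual tumor persists as compact nests. (Independent
  cell thinning would leave the convex-hull annotation covering the
  whole territory no matter how strong the kill, making the annotated
  TBR uninformative; contraction reproduces the intended ground truth
  `TBR = Σ area_k · survival_k / A_bed`.)
* **Competitive release**: when a block's surviving fraction falls
  below 0.5, all surviving subclones gain +0.15 positivity — the
  release of resistant clones from competition. This is what raises
  KiL (and shrinks KiD) in responder blocks.
* Residual-tumor polygons are convex hulls of surviving territory
  cells — deliberate annotation slop motivating the ±5-point recovery
  tolerance. Hotspot/coldspot regions are selected automatically;
  blocks with 100–999 surviving cells yield a single whole-slide PI
  (reported as KiH), blocks under 100 cells none, and blocks under 50
  cells fail inclusion — the same missingness cascade as the published
  cohort.
* Covariates are drawn independently from the published marginals
  (gender 85/21, Laurén 53/23/21/9, …); survival is exponential with
  responder (true mTBR < 10%) median 32 months — the published
  responder median OS — hazard ratio 2.5 for non-responders, light
  censoring ~ Exp(0.004/month) truncated at 120 months, and
  tumor-related death probability 0.8 for the tumor-specific endpoint.
  Censoring is deliberately lighter than the published cohort's ~46%:
  the generator's documented power surface (log-rank at the 10% cutoff
  detecting HR 2 in ≥80% of 100-case cohorts) is arithmetically
  unreachable at published censoring levels, so the power requirement
  won.

### What a green test does and does not establish

The generator produces realistic *structure* (multi-block cases,
spatial territories, evaluability cascades, Table-1-like marginals,
responder-linked survival) but not realistic *histology*: covariates
are mutually independent, cell density is uniform, territories are
convex-ish, and the survival model is exponential. Green
ground-truth-recovery tests establish that the measurement pipeline is
faithful to the generative model within the stated tolerances — not
that the biological effect sizes are realistic. Conversely, the
published contingency tables are real data, and reproducing their
p-values validates the statistical layer against the published
analysis exactly.

## Numerical choices

* Areas/PIs are never rounded internally; percentages are rounded to
  1 decimal and p-values to 2–3 decimals only at output.
* Exact-test probability comparisons use the `1 + 1e-7` guard factor.
* The hotspot circle is stored as a 48-gon with radius inflated by
  `1/cos(π/48)` so the polygon circumscribes the true window disc.
* The case-level median test of the KM curve uses `S ≤ 0.5 + 1e-12`.
* Degenerate inputs: zero-margin 2×2 tables give p = 1; all-tied
  tau-b errors; bed area ≤ 0 errors; a cutoff that empties a survival
  group flags the row instead of testing.

## Known limitations

* The Freeman–Halton enumeration is exponential in table size; the
  feasibility guard (~5·10⁶ tables) covers the r×2 tables of this
  design comfortably but general large r×c tables need the Monte-Carlo
  fallback.
* The asymptotic tau-b p differs from SPSS in the third decimal for
  some tables (variance-estimator details); permutation mode is exact
  up to Monte-Carlo error but slower.
* The simulator's competitive-release effect on KiL is
  direction-stable but, at the default effect sizes, its per-seed
  one-sided significance at the block level has roughly 75–85% power
  in a 100-case cohort; the KiD effect is essentially always
  significant. The acceptance test asserts direction per seed plus
  pooled significance across seeds accordingly.
* Survival medians and published log-rank p-values cannot be
  reproduced without patient-level data and are not targets.
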