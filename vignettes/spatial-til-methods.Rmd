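---
title: "Methods: spatial TIL quantification from multiplexed IHC cell tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial TIL quantification from multiplexed IHC cell tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`tilspatial` analyzes segmented cell tables from multiplexed
immunohistochemistry (mIHC) of tumor sections.  The pipeline starts where
image analysis ends: one row per segmented cell with 2-D coordinates in
micrometres, binary positivity calls (optionally raw intensities) for a
six-plex panel — PANCK (pan-cytokeratin, the epithelial tumor marker),
CD4, CD8, LAG3, Ki67 and IFN-&gamma; — and a region label (`tumor`,
`stroma`, or `excluded` for necrosis/normal epithelium).  All coordinates
use a single convention (origin at the window's lower-left corner,
micrometres); all areas and densities are reported in mm^2 and cells/mm^2
(1 mm^2 = 10^6 um^2), which keeps the 10^6 scale factor in exactly one
place.

Pixel-level segmentation, spectral unmixing and proprietary export
formats are out of scope; cell tables are plain CSV and region masks are
GeoJSON polygons in the same micrometre frame.

# Phenotype calling

A phenotype is a named marker-logic predicate: all `require_positive`
markers positive, all `require_negative` negative, and optionally at
least one of an `any_of` set (needed for "LAG3+ T cell" = LAG3+ and
CD4+ or CD8+).  The default rule set is

* `TUMOR` = PANCK+
* `CD4_T` = CD4+ CD8- PANCK-, `CD8_T` = CD8+ CD4- PANCK-
* `LAG3_T` = LAG3+ PANCK-, with CD4 or CD8 positive
* refined phenotypes (`LAG3_CD4_T`, `KI67_CD8_T`, ...) add one marker to
  a base rule; `KI67_TUMOR` adds Ki67 to PANCK+.

CD4+CD8+ double positives are a genuine reporting gap in this field:
commercial software rarely documents their handling.  We exclude them
from both single-positive subsets (the subsets stay disjoint) but keep
them in `LAG3_T`; `default_phenotype_rules(double_positive = "include")`
drops the mutual exclusion.  Cells in excluded regions never match any
rule, so they are invisible to every downstream metric.  Intensity
thresholding uses a closed cutoff (`intensity >= cutoff` is positive) so
boundary behavior is deterministic.

# Region segmentation

Manual tumor/stroma annotation is not reproducible from a deposited cell
table, so the package reconstructs cancer nests algorithmically from the
PANCK+ pattern: single-linkage clustering at `nest_link_distance`
(default 30 um), groups of at least `min_nest_cells` (default 10) become
nests, and each nest's convex hull dilated by `boundary_buffer` (default
10 um) becomes a tumor polygon.  Every cell is then relabeled by
point-in-polygon (closed boundaries: a cell on the edge is inside), and
the areas satisfy tumor + stroma + exclusion = window by construction.
These defaults are calibration defaults, tuned once against the
synthetic generator (where they recover about 98% of ground-truth
labels) and exposed in `segmentation_params()`; they are not derived
from any published annotation protocol.  When manual masks exist,
`assign_regions_from_masks()` overrides the algorithm, with exclusion
taking precedence over tumor.

Hulls are convex by design: nests are compact, convex clipping is exact,
and the union area of convex rings can be computed by
inclusion-exclusion without a computational-geometry dependency.  For
non-convex manual masks the union area falls back to a deterministic
fine-grid approximation (midpoint rule, 1200^2 cells over the bounding
box); the partition identity is unaffected because stroma is defined as
the remainder.

# Spatial metrics

Per sample the package reports

* densities per (phenotype, region) in cells/mm^2,
* positivity percentages of a marker within a base phenotype,
* per-tumor-cell nearest-neighbor distances to each immune phenotype
  (plus their sample-level mean and median), and
* mean counts of immune cells within a pairing radius (default 50 um) of
  each tumor cell.

Distances cross region boundaries (a stromal T cell may be the nearest
neighbor of a tumor cell) and no edge correction is applied: the values
match what per-cell image-analysis software exports.  Analytic
validation therefore restricts itself to interior centers, where for a
homogeneous Poisson field of intensity &lambda; the mean 50 um neighbor
count is &lambda;&pi;r^2 and nearest distances follow
1 - exp(-&lambda;&pi;d^2); both laws are verified in the test suite.
Undefined quantities — a density over a zero-area region, a positivity
rate with an empty denominator, a nearest distance with no neighbor
cells — are carried as `NA` with a diagnostic, never as 0, and are
removed listwise from downstream correlations so artificial zeros cannot
deflate them.  The per-center median distance is computed and exported
alongside the mean but drives no downstream analysis.

The production distance code uses chunked vectorized brute force; the
tests require exact equality with an independent per-center brute-force
oracle, so any future spatial indexing must be drop-in exact.

# Statistics

* **Paired comparisons** use the Wilcoxon signed-rank test.  Zero
  differences are dropped (classic convention; Pratt is available).  For
  up to 25 non-zero pairs the two-sided p comes from the exact null
  distribution, built by dynamic programming over doubled midranks —
  equivalent to enumerating all 2^n sign assignments and valid under
  ties, which the textbook normal approximation is not.  Larger samples
  use the normal approximation with tie correction and a continuity
  correction.
* **Correlations** are Spearman's rank correlation: Pearson on midranks,
  p from the t approximation on n - 2 degrees of freedom.
* **Survival** uses the product-limit estimator and log-rank test from
  the `survival` package behind a thin interface.  The KM median is the
  smallest observed time with S(t) &le; 0.5; if the curve never reaches
  0.5 the median is "not reached" (`NA`).  Months are days/30.44 when
  clinical input arrives in days.
* **Dichotomization** follows the ROC/Youden recipe: every midpoint
  between adjacent unique feature values is a candidate cutoff and the
  one maximizing J = sensitivity + specificity - 1 wins, with ties
  broken toward balanced groups and then the smaller cutoff.  Two
  genuinely open choices are made explicit.  First, the binary outcome
  for the ROC is vital status at end of follow-up (a documented gap in
  the source protocol; a fixed-horizon status is a one-line change).
  Second, orientation: protective features (most TIL densities) need the
  `value <= cutoff` direction, so `direction = "auto"` picks the
  orientation whose best cutpoint attains the larger J, as ROC software
  does by forcing AUC &ge; 0.5.
* **Cutpoint optimism**: optimizing the cutpoint inflates the log-rank
  type-I error well above the nominal level.  The pipeline therefore
  also reports a permutation-calibrated p (feature labels permuted, the
  whole cutpoint + log-rank pipeline rerun; default 500-1000
  permutations).  Point estimates follow the classic recipe; honest
  inference comes from the permutation p.  No multiple-testing
  correction is applied by default; Benjamini-Hochberg can be applied to
  the result tables with `p.adjust`.

# The synthetic generator

No real cell-level dataset accompanies this pipeline, so the generator
is a first-class module that defines the study conditions and provides
ground truth for recovery tests.

A tissue is a hard-disc Neyman-Scott-style pattern: `n_nests` (default
5) non-overlapping discs with mean radius 150 um inside a 2 x 2 mm
window; PANCK+ cells uniform in each disc at 2000 cells/mm^2; CD4/CD8 T
cells as independent Poisson processes at 184 and 62 cells/mm^2 in
stroma versus 40 and 30 cells/mm^2 inside nests (the stroma-dominant
ordering reported for ESCC sections).  Marker positivity is Bernoulli
per (phenotype, marker): about 1% LAG3 and Ki67 and 3.4%/5.9%
IFN-&gamma; in CD4/CD8 T cells, 30% Ki67 in tumor cells (a typical
proliferative fraction for squamous carcinoma; the sources report tumor
Ki67 only as a dichotomized survival feature).  The LAG3 coupling adds
`coupling * z` to a T cell's LAG3 log-odds, where z is its standardized
50 um T-cell neighbor count; standardization is per sample, so the knob
shapes where LAG3+ cells sit within a section.

Cohorts add: (i) independent per-patient lognormal density multipliers
(sdlog 0.4, mean 1) per immune phenotype — the biological heterogeneity
that carries across-patient density-density correlations, as in real
cohorts; (ii) a paired on-treatment section with stromal densities
multiplied by 0.67 (CD4) and 0.69 (CD8) and IFN-&gamma; rates shifted by
+9.5 and +17 percentage points (the observed chemoradiation effect
sizes); and (iii) exponential proportional-hazards survival (baseline
hazard 0.03/month, i.e. a 23-month median; log-HR -0.5 per SD of the
log CD4 multiplier; administrative censoring at 76 months, the observed
maximum follow-up).  Exponential survival keeps medians analytic
(ln 2 / hazard), which gives closed-form recovery targets.  Every sample
draws from a stream seeded by (master seed, patient, timepoint), so
cohorts are bit-reproducible and insensitive to generation order.

One structural fact deserves emphasis: because LAG3+ T cells are a
thinned subset of the T population, the across-sample correlation
between LAG3+ T density and CD4 T density is not exactly zero even with
the coupling off — binomial thinning leaves a residual rho of roughly
sqrt(rate) (about 0.1 at the default 1% rates).  The calibration test
for the coupling-off case therefore uses homogeneous fixed-configuration
cohorts of 20 sections, where power against rho ~ 0.1 is near the
nominal level, and checks that the rejection rate stays within binomial
noise of nominal; the coupling-on check uses heterogeneous cohorts,
where the association is strong.  This mirrors the real situation: the
observable density-density correlation across patients is carried by
infiltration heterogeneity, with the spatial coupling acting within
sections.

What the generator does **not** emulate: cell morphology, staining
artifacts, irregular (non-disc) nest shapes, necrosis geometry, immune
phenotypes beyond CD4/CD8 T cells, and non-exponential survival.
Passing recovery tests therefore demonstrates that the pipeline computes
its estimands correctly under known structure — not that those estimands
are unbiased on arbitrary real tissue.

# Problem sizes and numerical choices

The test suite and analysis scripts run cohorts of 16-200 patients with
sections of roughly 300-1700 cells (windows 0.36-4 mm^2), chosen so each
Monte-Carlo check has clear resolution: e.g. 150 null cohorts for
Wilcoxon uniformity, 1000 replicates for log-rank type-I error, 100
seeds for segmentation recovery, 40 Poisson patterns (2400 interior
centers) for the spatial laws.  Discs are exported as 128-gons and all
areas are computed from the polygons themselves, so area identities hold
to machine precision rather than to a polygon-vs-circle approximation.
Nearest-neighbor ties are broken toward the smaller cell id (irrelevant
for distances, stable if neighbor identities are ever exported).
Degenerate inputs — constant features, single-class outcomes, all-zero
paired differences, empty regions — yield flagged results or `NA` with
diagnostics, never silent zeros.

# Known limitations

* Convex hulls overestimate concave nest boundaries; an alpha-shape
  would track them more closely at the cost of a tuning parameter.
* No edge correction means near-boundary centers are biased toward
  larger nearest distances and smaller neighbor counts; comparisons
  between samples of similar geometry are unaffected, absolute values
  near edges are.
* The ROC outcome (vital status at end of follow-up) conflates event
  and follow-up length for censored patients; with administrative
  censoring at a common horizon this is benign, with heavy early
  censoring it is not.
* The permutation p calibrates selection of the cutpoint, not selection
  among the many features examined.
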