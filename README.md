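# tilspatial

Spatial quantification of tumor-infiltrating lymphocytes (TILs) from
multiplexed immunohistochemistry (mIHC) cell tables, with paired
treatment comparisons and survival stratification.

## The problem

Six-plex mIHC of tumor biopsies (PANCK / CD4 / CD8 / LAG3 / Ki67 /
IFN-γ) yields, after image analysis, a table of segmented cells with
coordinates and marker calls. Turning that table into biology requires a
chain of quantitative steps that are usually buried in commercial
software: calling cell phenotypes from marker logic, separating cancer
nests (PANCK+ regions) from stroma, computing region-stratified
densities (cells/mm²) and positivity rates, measuring tumor–immune
spatial relationships (distance from each tumor cell to its nearest
CD4+/CD8+/LAG3+ T cell; mean number of immune cells within 50 µm of each
tumor cell), comparing paired baseline vs on-treatment biopsies
(Wilcoxon signed-rank, CCRT/BL density ratios), correlating readouts
(Spearman), and stratifying overall survival by ROC-optimal cutpoints
(Youden J) with Kaplan–Meier curves and log-rank tests.

`tilspatial` implements this chain as tested, reusable R functions, for
researchers analyzing checkpoint (LAG3) biology and chemoradiation
effects in the tumor microenvironment. Because cell-level mIHC data are
rarely deposited, the package includes a synthetic tissue/cohort
generator — clustered PANCK+ nests in a stromal field, region-specific
Poisson immune intensities, Bernoulli marker positivity with a
local-density LAG3 coupling, and exponential proportional-hazards
survival — that supplies ground truth for every stage, so each estimator
is validated by parameter recovery.

Key quantities, in the field's notation: density = N(phenotype, region)
/ area(region) in cells/mm²; positivity % = 100 · N(base ∧ marker+) /
N(base); for each tumor cell *i*, d_i = min over immune cells *j* of
‖x_i − x_j‖ and k_i = #{j : ‖x_i − x_j‖ ≤ r} with r = 50 µm; Youden
J = sensitivity + specificity − 1; KM median = smallest t with
Ŝ(t) ≤ 0.5 ("NR" if never reached).

## Worked example

```r
library(tilspatial)

# one synthetic section: 5 tumor nests in a 2x2 mm window
s <- generate_tissue(tissue_config(seed = 7))
s
#> <tissue_sample> patient P1, baseline: 1659 cells (750 tumor / 909 stroma / 0 excluded)
#>   window 2000 x 2000 um; areas (mm^2): tumor 0.3622, stroma 3.6378, excluded 0.0000

# re-derive tumor/stroma regions from the PANCK+ pattern alone
seg <- segment_regions(s)
mean(seg$cells$region == s$cells$region)   # recovery vs ground truth
#> [1] 0.994575

cell_density(s, "CD4_T", "stroma")         # cells per mm^2
#> [1] 188.024
positivity_rate(s, "CD8_T", "IFNG")        # % of CD8 T cells IFN-gamma+
#> [1] 6.382979
nearest_distances(s, "CD4_T")$mean         # tumor cell -> nearest CD4 T (um)
#> [1] 58.54936
neighbor_counts(s, "CD4_T", radius = 50)$mean
#> [1] 0.4946667
```

The numbers mean: CD4+ T cells infiltrate the stroma at ~188 cells/mm²
(versus ~44/mm² inside nests — the stroma-dominant ordering typical of
squamous carcinoma), 6.4% of CD8+ T cells express IFN-γ, and the average
tumor cell sits 59 µm from its nearest CD4+ T cell with ~0.5 CD4+ T
cells inside its 50 µm neighborhood.

The cohort-level workflow lives in `analysis/01...05` (simulate →
segment → spatial metrics → paired treatment effects → survival
stratification), each a thin driver over package functions that prints
what it found and writes tables under `results/`. For example
`analysis/04_paired_treatment_effects.R` reports the on-treatment
contraction of the stromal T-cell compartment (median CCRT/BL density
ratios 0.66 for CD4, 0.69 for CD8, Wilcoxon p < 1e-7) alongside the
IFN-γ elevation (3.2% → 13.3% in CD4+ T cells), and
`analysis/05_survival_stratification.R` prints per-feature cutpoints, KM
medians and both raw and permutation-calibrated log-rank p-values.

## Layout

```
R/                  package code (data model & IO, generator, phenotyping,
                    segmentation, spatial metrics, statistics, pipeline)
analysis/           numbered narrative drivers over the package
tests/testthat/     unit, property and acceptance tests (oracle-checked)
scripts/acceptance.R  end-to-end recomputation of headline numbers
vignettes/          methods vignette (model, assumptions, limitations)
```
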