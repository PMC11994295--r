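---
title: "Methods: inventory completeness and environmental bias of occurrence records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inventory completeness and environmental bias of occurrence records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sampcov)
```

`sampcov` asks a quantitative question about biodiversity data: when
occurrence records held in natural history collections are digitised and
added to an aggregator's holdings, how much does inventory completeness
improve, and how much of the spatial and environmental bias of the original
data is removed? This vignette documents the models and procedures each
stage implements, the parameters that matter, and the design choices made
where several readings were defensible.

## The analysis grid

The study area is tiled with square cells in geographic coordinates
(`build_grid()`), 0.83° by default — roughly 100 km at the equator — with a
lower-left origin and row-major ids. Cell membership uses half-open
intervals $[x_{\min}, x_{\max})$ on both axes, so a point on a shared edge
belongs to exactly one cell (the one to its east/north); the grid's outer
boundary closes onto the last cell. A cell is *land* if it intersects the
land-mask polygons. Regional labels are assigned by the cell's **centre
point** — for cells straddling a border, the centroid decides. A single
degree-based grid keeps the occurrence analysis and the aggregated climate
layers congruent; an equal-area projected grid would change cell areas with
latitude by only a few percent across a tropical study extent, at the cost
of a projection dependency, and is deliberately not the default.

## Record cleaning

Cleaning never silently drops data: each filter returns the kept rows and
the removed rows with exactly one primary reason code, so a preprocessing
report can always account for every input record.

- **Species level** (`filter_species_level()`): only binomials are kept;
  open-nomenclature names (`sp.`, `cf.`, `aff.`, ...) are removed;
  trinomials collapse to their binomial.
- **Coordinates** (`filter_coordinates()`): removes absent/unparseable
  coordinates, exact (0, 0), points off the land polygons, points within
  `tolerance_km` (default 5 km) of a listed country centroid or biodiversity
  institution, and points whose containing country polygon contradicts the
  declared country. A record with no declared country skips the mismatch
  test, which cannot be evaluated for it. The sea test is point-in-polygon
  at the resolution of the supplied land layer, with no coastal buffer by
  default.
- **Taxonomy** (`standardize_taxonomy()`): renames through a synonym map
  and removes names on a drop list (extralimital species, *incertae sedis*).
  The map is validated for consistency and idempotence at construction, so
  applying the standardisation twice is a no-op.

## Duplicate detection across datasets

When a collections-derived dataset is merged with an aggregator download,
some specimens appear in both, in different textual formats. Two records
are duplicates (`records_duplicate()`) iff **all** of:

1. same species;
2. same collection year;
3. compatible date precision: granularities beyond the year are compared at
   the finest level present in *both* records (`date_rule = "shared"`, the
   default). The stricter reading — a month or day present in only one
   record blocks the match — is available as `date_rule = "strict"`. The
   default was chosen because a one-sided precise date is most often a
   transcription difference, not evidence of distinct collecting events;
4. equal collector and locality labels after normalisation
   (`normalize_label()`): case-folding, accent stripping, removal of
   periods and apostrophes, remaining punctuation treated as separators,
   comparison as sorted token sets. Token-set equality tolerates
   reordering ("Smith, J." vs "J. Smith") without the false positives of
   edit-distance matching;
5. latitude *and* longitude each within 1.0° ("no more than one degree
   apart" read as $|\Delta| \le 1$ per axis independently).

`merge_datasets()` blocks candidate pairs on (species, year), applies the
full rule, and drops the revision copy of each matched pair by default —
retaining the already-mobilised record preserves its aggregator identifier;
`retain = "revision"` flips this. The count identity
$n_{combined} = n_{gbif} + n_{revision} - n_{removed}$ is asserted on every
merge.

## Inventory completeness

For each cell, the expected species accumulation curve is the mean
cumulative species count over random orderings of the cell's records
(`accumulation_curve()`). The effort unit is the database record (row), not
the specimen count, matching the "> 20 records" well-sampled criterion;
expanding rows by `individualCount` is possible upstream but off by
default. With ≤ 6 records the mean is exact over all $n!$ orderings;
otherwise 200 seeded permutations are used (the Monte-Carlo error of the
mean is far below the Clench fit's residual error at that size). The exact
expectation has a closed hypergeometric form, which the test suite uses as
an independent oracle.

The curve is fitted (`fit_clench()`) with the Clench (Michaelis–Menten)
model
$$S(n) = \frac{a\,n}{1 + b\,n}, \qquad \hat S_{total} = a/b,$$
by Levenberg–Marquardt nonlinear least squares, started from the linearised
regression of $n/S$ on $n$ (intercept $1/a$, slope $b/a$) and bounded below
at $10^{-12}$ so both parameters stay positive. Completeness is
$100 \cdot S_{obs} / (a/b)$, clamped to 100% when the asymptote falls below
the observed richness (the clamp is flagged, not hidden). A cell is
*computable* only when it has at least 3 effort levels and the fit
converged; `completeness_table()` reports non-computable cells rather than
dropping them. A cell is **well-sampled** iff records > 20, completeness
> 75% and records/species > 5 — all strict inequalities, so a cell sitting
exactly on a threshold is not well-sampled.

The Clench function is the standard saturating estimator in completeness
software; the rational-function and negative-exponential alternatives are
out of scope.

## Climate space and climate types

The climate layers are aggregated to the grid by the mean of pixel centres
per cell, ignoring no-data pixels; cells with no valid pixel are dropped
from the environmental matrix with a log message. PCA
(`run_pca()`) is computed on standardised columns (correlation PCA) because
bioclim variables mix °C, mm and dimensionless indices; component signs are
fixed by making each component's largest-magnitude loading positive, so
scores are reproducible across platforms.

`bin_climate_space()` partitions the observed PC1 and PC2 ranges into
`n_bins_per_axis` equal-width intervals each (half-open, the last closed),
giving equal-area bins of score space; each occupied bin is a *climate
type*. The default of 6 bins per axis (36 potential types) gives, on a
study area of order 10³ cells, tens of occupied types — enough resolution
to distinguish common from rare climates without emptying most bins; the
occupied count is an emergent, data-dependent quantity, not a target.
Binning is always computed once from the full study area; subsets (e.g. the
well-sampled cells) are looked up in that typing, never re-binned, so all
comparisons use the same description of climate frequency.

Rarity (`rarity_scores()`) is the min–max scaled inverse frequency:
$r_i = (f_{\max} - f_i)/(f_{\max} - f_{\min})$, 0 for the most common type,
1 for the rarest, all 0 when every occupied type is equally frequent.

## Bias statistics

**Schoener's D** (`schoener_d()`):
$D = 1 - \tfrac12 \sum_i |p_i - q_i|$ over the discrete climate-type
distributions; 0 = disjoint, 1 = identical. Inputs must sum to one —
the function refuses to renormalise silently.

**Resampling null** (`null_overlap_test()`): the observed statistic is the
overlap between the well-sampled cells' type distribution and the study
area's. Each of `n_iter` (default 1000) null draws samples as many
*occurrence records* as there are WS cells — sampling records, not cells,
mirrors the question "what if the same amount of collecting had landed at
random?" — without replacement within a draw, and computes the same
overlap. The one-sided p-value with add-one correction is
$p = (1 + \#\{D_{null} \ge D_{obs}\})/(1 + n_{iter})$, so $p \in
[1/(n_{iter}+1), 1]$: p near 1 means the WS cells cover climate space
*worse* than random placement, the typical outcome for biased data.
Whether to sample with replacement is exposed as a flag; without
replacement is the default because it mimics picking a set of real records.
A set with no WS cells is reported with $D = 0$ (it covers nothing) and an
undefined p.

**Kolmogorov–Smirnov** (`ks_two_sample()`): $D = \sup_x |F_a(x) - F_b(x)|$
with the asymptotic two-sample p-value, comparing WS-cell scores against
*all* land cells' scores on each PC axis and on rarity — the study area,
not just the sampled cells, is the reference distribution.

**Density profiles** (`kde_profile()`): Gaussian kernel, Silverman
rule-of-thumb bandwidth, evaluated on a shared grid for the WS subset and
all cells, exported as plain tables. A constant sample has no data-driven
bandwidth and raises an error suggesting an explicit one.

**Reporting** (`summarize_coverage()`): cell and climate-type percentages
are rounded half-up to two decimals, dataset contribution shares to one
decimal, with integer-rounded variants alongside; raw counts are always
retained so every percentage recomputes exactly.

## The synthetic study system

`synthetic_scenario()` fixes the world the tests and the acceptance script
run in. Its defaults are the study conditions, chosen once:

- a 10° × 10° extent with 1° cells (100 cells, all land) and four quadrant
  regions — large enough for regional contrast, small enough that the full
  pipeline runs in seconds;
- 19 climate layers at 0.25° driven by two smooth latent gradients
  (latitudinal and longitudinal) plus per-pixel noise (sd 0.05), so two PCA
  axes genuinely dominate, as they do for real bioclim stacks;
- a pool of 40 species with log-series abundances (shape 0.96) and Gaussian
  niches (sd 0.35 in latent units) — a saturating accumulation regime with
  realistic rarity structure. A species is truly present in a cell when
  abundance × niche match exceeds 0.01; sampling respects the same
  threshold, so observed richness can never exceed the truth;
- a sparse "gbif-like" set of 600 records with regional effort 8 : 1 : 0.5
  : 0.5 (one dominant region, as aggregator data typically show) and a
  dense "revision-like" set of 1500 records with uniform effort;
- 10% of gbif-like rows cloned into the revision-like set with
  rule-preserving perturbations (label reformatting, accent/punctuation
  changes, coordinate jitter ≤ 0.4° kept inside the study area); an
  optional near-miss mode adds clones violating exactly one rule (year + 1
  or a 1.6° longitude shift) for precision testing.

What the generator does *not* emulate: real coastline and country geometry,
temporal trends in collecting effort, spatially autocorrelated
identification error, and gazetteer-style locality ambiguity. Passing
tests therefore show the pipeline's statistical machinery is correct and
well-calibrated under known truth; they do not certify the cleaning
heuristics against the full messiness of real aggregator data.

## Numerical conventions and degenerate inputs

- Half-open intervals everywhere a value can sit on an edge (grid cells,
  climate bins), upper boundary closed on the outermost interval.
- Clench starting values from the linearised transform; convergence is
  reported honestly and non-converged cells are excluded from the
  computable set rather than patched.
- Completeness clamped to 100% with a flag when the asymptote is below
  $S_{obs}$.
- Degenerate climate axes (all scores equal) collapse to one bin; equal
  type frequencies give all-zero rarity; an empty land mask is a warning,
  not an error.
- Percentages round half-up (print-style), not banker's rounding.
- Every stochastic step (permutations, null draws, the generator) takes an
  explicit seed and restores the caller's RNG state afterwards.

## Problem sizes in the shipped tests

The test suite and acceptance script use deliberately desk-scale sizes: the
100-cell synthetic scenario above; 500 null-calibration replicates at 200
iterations; 1000 KS instances (≤ 50 points) against a brute-force ECDF
oracle and 1000 same-distribution pairs (n = 100) for empirical size; 100
synthetic cells for Clench asymptote recovery (median relative error is
checked against a 25% band — accumulation estimators are biased low at
finite effort, so tighter bands would test the data, not the code). Realm-
scale quantities from any particular empirical study (thousands of cells,
dozens of climate types) require that study's occurrence data and global
climate rasters; fed through the same file-based interface, the pipeline
emits the identical report schema for direct comparison.

## Known limitations

- Point-in-polygon land/country tests have no coastal buffer by default, so
  shoreline records can be flagged as at sea with coarse masks
  (`coast_buffer` handling is left to the mask supplier).
- Duplicate detection is rule-based, not probabilistic; records differing
  by a misspelt collector token are not matched (by design — precision over
  recall).
- The Clench asymptote underestimates richness at low effort; completeness
  percentages for barely computable cells (few records, few species) are
  optimistic. The well-sampled thresholds exist precisely to gate
  downstream inference on cells where the fit is trustworthy.
- Climate typing depends on the bin count; conclusions about *which* types
  are rare are scale-dependent even though the min–max scoring is not.
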