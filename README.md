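# sampcov

Quantifying what the mobilisation of natural-history-collection records adds
to our knowledge of species distributions — and what biases remain.

Aggregators such as GBIF hold millions of occurrence records, but for many
insect groups, especially in the tropics, those records are too sparse and
too unevenly placed to support distribution modelling. `sampcov` implements
an analysis pipeline that makes that statement measurable. Given two
occurrence datasets — an already-mobilised set and a set newly extracted
from collections or taxonomic literature — it:

1. cleans both sets (species-level filter; coordinate checks against land,
   country, country-centroid and institution locations; taxonomic
   standardisation through a synonym/drop map);
2. merges them, removing cross-dataset duplicates by a rule-based matcher
   (same species and year, compatible date precision, same collector and
   locality after token normalisation, coordinates ≤ 1° apart per axis);
3. estimates per-grid-cell **inventory completeness**: the expected species
   accumulation curve over record-order permutations is fitted with the
   Clench model

   S(n) = a·n / (1 + b·n),

   whose asymptote a/b predicts the cell's total richness, so completeness
   = 100 · S_obs / (a/b). Cells with > 20 records, completeness > 75% and a
   records-to-species ratio > 5 are classified **well-sampled (WS)**;
4. types the study area's climate by binning the first two principal
   components of a 19-layer bioclimatic stack into equal-area bins
   ("climate types"), each scored for min–max rarity in [0, 1];
5. measures environmental bias per set: Schoener's overlap
   D = 1 − ½ Σᵢ |pᵢ − qᵢ| between the WS cells' climate-type distribution
   and the study area's, tested against a null of 1000 random occurrence
   draws; two-sample Kolmogorov–Smirnov tests per PC axis; kernel density
   profiles of scores and rarity.

A seeded synthetic-data module generates the whole study system with known
truth (climate landscape with two latent gradients, log-series species pool
with Gaussian niches, biased vs uniform sampling, injected format-perturbed
duplicates), so every stage is testable end-to-end.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
synthetic study system (seed 42), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess_merge.R
Rscript analysis/03_completeness.R
Rscript analysis/04_climate.R
Rscript analysis/05_coverage_stats.R
```

which prints, among other things:

```
merge: 600 + 1560 records, 60 duplicates removed -> 2100 combined
dedup recall against injected truth: 100% (60/60)
gbif set: 83 occupied cells, 36 computable, 1 well-sampled (SE 1)
combined set: 100 occupied cells, 99 computable, 11 well-sampled (NE 4, NW 1, SE 6)
PC1 + PC2 explain 99.8% of climate variance
36 occupied climate types across 100 cells; rarity spans [0.00, 1.00]
gbif set: D = 0.040 (p = 0.709) over 1 WS cells in 1 climate types
combined set: D = 0.210 (p = 0.987) over 11 WS cells in 7 climate types
```

Read: the sparse, regionally biased "gbif-like" set yields completeness
estimates in 36 of 100 cells and a single well-sampled cell, confined to
one region and one climate type. Adding the dense "revision-like" set
nearly triples computable coverage (99 cells), spreads 11 WS cells over
three regions and 7 climate types, and raises the niche overlap with the
study area from D = 0.04 to D = 0.21. The p-values near 1 say that even
the improved WS cells cover climate space *worse* than the same number of
randomly drawn records would — well-sampled cells sit in common climates.
The same in-memory workflow is available as one call: `run_pipeline()` on
a `pipeline_config()`.

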