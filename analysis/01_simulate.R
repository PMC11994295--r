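#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study system: a climate landscape with two
# latent gradients, a species pool with climate-linked ranges, and two
# occurrence datasets (a sparse regionally biased "gbif" set and a dense
# near-uniform "revision" set) sharing injected format-perturbed duplicates.
source("analysis/00_config.R")

dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_occurrences(scenario)
polys <- make_synthetic_polygons(scenario)
stack <- make_synthetic_bioclim(scenario)

write_table(sim$gbif, file.path(DATA_DIR, "occurrences_gbif.csv"))
write_table(sim$revision, file.path(DATA_DIR, "occurrences_revision.csv"))
write_stack(stack, file.path(DATA_DIR, "bioclim"))
write_polygons(polys$land, file.path(DATA_DIR, "land.geojson"))
write_polygons(polys$regions, file.path(DATA_DIR, "regions.geojson"))
jsonlite::write_json(
  list(duplicate_pairs = sim$truth$duplicate_pairs,
       cell_truth = sim$truth$cell_truth),
  file.path(DATA_DIR, "truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf(
  "simulated %d gbif-like and %d revision-like records (%d injected duplicates)\n",
  nrow(sim$gbif), nrow(sim$revision), nrow(sim$truth$duplicate_pairs)))
cat(sprintf("climate stack: %d layers at %g deg over extent [%s]\n",
            length(stack$layers), stack$cellsize,
            paste(scenario$extent, collapse = ", ")))
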