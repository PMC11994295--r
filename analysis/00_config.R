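# Shared configuration for the numbered analysis scripts. Source-d by each
# script; edit here to change the study conditions once for the whole run.

library(sampcov)

SEED <- 42L
DATA_DIR <- "results/data"
OUT_DIR <- "results"

scenario <- synthetic_scenario(seed = SEED)

grid_with_regions <- function() {
  land <- read_polygons(file.path(DATA_DIR, "land.geojson"))
  regions <- read_polygons(file.path(DATA_DIR, "regions.geojson"))
  g <- build_grid(scenario$extent, scenario$cell_size, land_mask = land)
  assign_regions(g, regions)
}
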