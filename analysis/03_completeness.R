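#!/usr/bin/env Rscript
# Stage 3 — per-cell inventory completeness for each set: species
# accumulation curves (permutation means), Clench asymptote fits, and the
# well-sampled classification (> 20 records, completeness > 75%,
# records/species ratio > 5).
source("analysis/00_config.R")

grid <- grid_with_regions()

for (set in c("gbif", "combined")) {
  recs <- read_table(file.path(OUT_DIR, paste0("set_", set, ".csv")))
  recs <- assign_cells(recs, grid)
  comp <- completeness_table(recs, n_perm = 200L, seed = SEED)
  write_table(comp, file.path(OUT_DIR, paste0("completeness_", set, ".csv")))
  ws <- comp[comp$well_sampled, ]
  if (nrow(ws)) {
    write_cells_geojson(ws, grid,
                        file.path(OUT_DIR, paste0("ws_cells_", set, ".geojson")))
  }
  reg <- grid$cells$region[match(ws$cell_id, grid$cells$id)]
  cat(sprintf(
    "%s set: %d occupied cells, %d computable, %d well-sampled (%s)\n",
    set, nrow(comp), sum(comp$computable), nrow(ws),
    if (nrow(ws)) paste(names(table(reg)), table(reg), collapse = ", ")
    else "none"))
}
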