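#!/usr/bin/env Rscript
# Stage 5 — environmental-bias statistics per set: Schoener's D between the
# well-sampled cells' climate-type distribution and the study area's, tested
# against a 1000-draw resampling null; two-sample KS tests on each PC axis
# and on rarity; kernel density profiles; and the side-by-side coverage
# summary.
source("analysis/00_config.R")

grid <- grid_with_regions()
cell_types <- read_table(file.path(OUT_DIR, "climate_typing.csv"))
type_table <- read_table(file.path(OUT_DIR, "climate_types.csv"))
typing <- structure(list(cell_types = cell_types, type_table = type_table),
                    class = "climate_typing")
n_land <- sum(grid$cells$is_land)

summary_rows <- list()
for (set in c("gbif", "combined")) {
  recs <- assign_cells(read_table(file.path(OUT_DIR, paste0("set_", set, ".csv"))),
                       grid)
  comp <- read_table(file.path(OUT_DIR, paste0("completeness_", set, ".csv")))
  ws_ids <- comp$cell_id[comp$well_sampled]
  ws <- cell_types[cell_types$cell_id %in% ws_ids, ]

  ot <- null_overlap_test(recs$cell_id, ws_ids, typing,
                          n_draw = length(ws_ids), n_iter = 1000L,
                          seed = SEED)
  cat(sprintf("%s set: D = %.3f (p = %.3g) over %d WS cells in %d climate types\n",
              set, ot$D_obs, ot$p_value, length(ws_ids),
              length(unique(ws$type_id))))
  for (ax in c("pc1", "pc2", "rarity")) {
    if (nrow(ws) < 2L) {
      cat(sprintf("  KS %-6s skipped: fewer than 2 WS cells\n", ax))
      next
    }
    ks <- ks_two_sample(ws[[ax]], cell_types[[ax]])
    cat(sprintf("  KS %-6s D = %.2f, p = %.3g\n", ax, ks$D_stat, ks$p_value))
    rng <- range(cell_types[[ax]])
    gridx <- seq(rng[1], rng[2], length.out = 128)
    dens <- data.frame(x = gridx,
                       density_ws = kde_profile(ws[[ax]], gridx)$density,
                       density_all = kde_profile(cell_types[[ax]], gridx)$density)
    write_table(dens, file.path(OUT_DIR, sprintf("density_%s_%s.csv", ax, set)))
  }
  cov <- summarize_coverage(list(
    computable_cells = sum(comp$computable), ws_cells = length(ws_ids),
    total_cells = n_land,
    occupied_types = length(unique(ws$type_id)),
    possible_types = nrow(type_table)))
  summary_rows[[set]] <- data.frame(
    set = set, computable = cov$computable_cells,
    computable_pct = cov$computable_cells_pct,
    ws = cov$ws_cells, ws_pct = cov$ws_cells_pct,
    types = cov$occupied_types, types_pct = cov$occupied_types_pct,
    D = ot$D_obs, D_p = ot$p_value)
}

summary <- do.call(rbind, summary_rows)
write_table(summary, file.path(OUT_DIR, "coverage_summary.csv"))
cat("\nside-by-side coverage summary:\n")
print(summary, row.names = FALSE)
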