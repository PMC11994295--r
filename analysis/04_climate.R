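#!/usr/bin/env Rscript
# Stage 4 — climate space of the study area: aggregate the layer stack to
# the grid, reduce to two principal components, bin the score space into
# equal-area climate types, and score each type's min-max rarity.
source("analysis/00_config.R")

grid <- grid_with_regions()
stack <- read_stack(file.path(DATA_DIR, "bioclim"))

env <- aggregate_bioclim(stack, grid)
pca <- run_pca(env, n_components = 2L)
typing <- rarity_scores(bin_climate_space(pca, n_bins_per_axis = 6L))

cat(sprintf("PC1 + PC2 explain %.1f%% of climate variance\n",
            100 * sum(pca$var_explained[1:2])))
cat(sprintf("%d occupied climate types across %d cells; rarity spans [%.2f, %.2f]\n",
            nrow(typing$type_table), nrow(typing$cell_types),
            min(typing$type_table$rarity), max(typing$type_table$rarity)))

write_table(typing$cell_types, file.path(OUT_DIR, "climate_typing.csv"))
write_table(typing$type_table, file.path(OUT_DIR, "climate_types.csv"))
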