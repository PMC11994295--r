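#!/usr/bin/env Rscript
# Stage 2 — quality-filter both occurrence sets and merge them, removing
# cross-dataset duplicates by the rule-based matcher (same species and year,
# compatible date precision, same collector/locality after normalisation,
# coordinates within one degree).
source("analysis/00_config.R")

gbif <- read_occurrences(file.path(DATA_DIR, "occurrences_gbif.csv"),
                         source = "gbif")
revision <- read_occurrences(file.path(DATA_DIR, "occurrences_revision.csv"),
                             source = "revision")
land <- read_polygons(file.path(DATA_DIR, "land.geojson"))

clean <- function(recs, tag) {
  st <- filter_species_level(recs)
  n_sp <- nrow(st$removed)
  st <- filter_coordinates(st$kept, land_polygons = land)
  cat(sprintf("%s: %d records; removed %d non-species-level, %d bad-coordinate\n",
              tag, nrow(recs), n_sp, nrow(st$removed)))
  st$kept
}
gbif_clean <- clean(gbif, "gbif")
revision_clean <- clean(revision, "revision")

m <- merge_datasets(gbif_clean, revision_clean)
cat(sprintf("merge: %d + %d records, %d duplicates removed -> %d combined\n",
            m$report$n_gbif, m$report$n_revision,
            m$report$n_duplicates_removed, m$report$n_combined))

truth <- jsonlite::read_json(file.path(DATA_DIR, "truth.json"),
                             simplifyVector = TRUE)
found <- paste(m$report$duplicate_pairs$gbif_row,
               m$report$duplicate_pairs$revision_row)
known <- paste(truth$duplicate_pairs$gbif_row,
               truth$duplicate_pairs$revision_row)
cat(sprintf("dedup recall against injected truth: %.0f%% (%d/%d)\n",
            100 * mean(known %in% found), sum(known %in% found),
            length(known)))

write_table(gbif_clean, file.path(OUT_DIR, "set_gbif.csv"))
write_table(m$combined, file.path(OUT_DIR, "set_combined.csv"))
write_table(m$report$duplicate_pairs, file.path(OUT_DIR, "duplicate_pairs.csv"))
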