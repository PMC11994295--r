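#' Pipeline configuration
#'
#' Collects all inputs and settings for [run_pipeline()]. Data inputs may be
#' given as file paths (occurrence CSVs, an `.asc` raster directory, GeoJSON
#' polygon files, a taxonomy CSV) or as ready-made in-memory objects; paths
#' are checked up front so a broken configuration aborts before any
#' computation.
#'
#' @param gbif,revision occurrence tables (paths or data.frames)
#' @param rasters climate stack (a directory of `.asc` layers or a
#'   [bioclim_stack()])
#' @param land,regions,countries polygon sets (paths or [polyset()]s);
#'   `countries` may be `NULL` to skip the country-mismatch filter
#' @param taxonomy a [taxonomy_map()], a taxonomy CSV path, or `NULL`
#' @param centroid_table centroid/institution table (path or data.frame) or
#'   `NULL`
#' @param extent,cell_size analysis grid definition
#' @param thresholds well-sampled thresholds, see [classify_well_sampled()]
#' @param n_bins_per_axis climate-space bins per PC axis
#' @param n_perm accumulation-curve permutations
#' @param null_iter null-model iterations
#' @param tolerance_km centroid/institution proximity radius
#' @param seed master seed, recorded in every output
#' @param out_dir output directory, or `NULL` for in-memory results only
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(gbif, revision, rasters, land, regions,
                            countries = NULL, taxonomy = NULL,
                            centroid_table = NULL,
                            extent, cell_size = 0.83,
                            thresholds = list(records = 20, pct = 75, ratio = 5),
                            n_bins_per_axis = 6L, n_perm = 200L,
                            null_iter = 1000L, tolerance_km = 5,
                            seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  for (nm in c("gbif", "revision", "rasters", "land", "regions",
               "countries", "taxonomy", "centroid_table")) {
    x <- cfg[[nm]]
    if (is.character(x) && length(x) == 1L && !file.exists(x)) {
      stop("configured path for '", nm, "' does not exist: ", x)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

load_input <- function(x, loader) if (is.character(x)) loader(x) else x

preprocess_set <- function(records, cfg, land, countries, taxonomy) {
  removed <- list()
  st <- filter_species_level(records)
  removed$species_level <- st$removed
  st <- filter_coordinates(st$kept, land_polygons = land,
                           country_polygons = countries,
                           centroid_table = cfg$centroid_table,
                           tolerance_km = cfg$tolerance_km)
  removed$coordinates <- st$removed
  if (!is.null(taxonomy)) {
    st <- standardize_taxonomy(st$kept, taxonomy)
    removed$taxonomy <- st$removed
  }
  list(kept = st$kept, removed = removed)
}

set_statistics <- function(records, typing, comp, grid, cfg, seed) {
  ws_ids <- comp$cell_id[comp$well_sampled]
  land_scores <- typing$cell_types
  ws_scores <- land_scores[land_scores$cell_id %in% ws_ids, ]
  realm <- type_distribution(typing)
  stats <- list(
    n_records = nrow(records),
    n_specimens = sum(records$count),
    n_species = length(unique(records$species)),
    n_computable = sum(comp$computable),
    n_ws = length(ws_ids),
    ws_cell_ids = ws_ids,
    occupied_types_ws = length(unique(ws_scores$type_id)))
  if (length(ws_ids) >= 1L) {
    stats$D_obs <- schoener_d(type_distribution(typing, ws_ids), realm)
    ot <- null_overlap_test(records$cell_id, ws_ids, typing,
                            n_draw = length(ws_ids),
                            n_iter = cfg$null_iter, seed = seed)
    stats$D_p_value <- ot$p_value
  } else {
    # no WS cells: the set covers none of climate space
    stats$D_obs <- 0
    stats$D_p_value <- NA_real_
  }
  for (ax in c("pc1", "pc2", "rarity")) {
    if (nrow(ws_scores) >= 2L) {
      ks <- ks_two_sample(ws_scores[[ax]], land_scores[[ax]])
      stats[[paste0("ks_", ax, "_D")]] <- ks$D_stat
      stats[[paste0("ks_", ax, "_p")]] <- ks$p_value
    } else {
      stats[[paste0("ks_", ax, "_D")]] <- NA_real_
      stats[[paste0("ks_", ax, "_p")]] <- NA_real_
    }
  }
  # per-region breakdown of computable and WS cells
  reg <- grid$cells$region[match(comp$cell_id, grid$cells$id)]
  stats$computable_by_region <- table(reg[comp$computable], useNA = "no")
  stats$ws_by_region <- table(reg[comp$well_sampled], useNA = "no")
  stats
}

kde_table <- function(ws_values, all_values, n_grid = 128L) {
  if (length(unique(all_values)) < 2L) return(NULL)
  rng <- range(c(ws_values, all_values))
  pad <- diff(rng) * 0.1
  grid <- seq(rng[1L] - pad, rng[2L] + pad, length.out = n_grid)
  all_d <- kde_profile(all_values, grid)
  out <- data.frame(x = grid, density_all = all_d$density,
                    density_ws = NA_real_)
  if (length(unique(ws_values)) >= 2L) {
    out$density_ws <- kde_profile(ws_values, grid)$density
  }
  out
}

#' Run the full coverage analysis for both occurrence sets
#'
#' Stages: preprocessing of both datasets (species-level, coordinate and
#' taxonomic filters), cross-dataset merge with duplicate removal, per-cell
#' inventory completeness and well-sampled classification for the gbif-only
#' set and the combined set, climate-space typing of the whole study area
#' (computed once and shared, so the two sets differ only in occurrences),
#' and the bias statistics per set (Schoener's D with a resampling null,
#' KS tests on PC1/PC2/rarity, kernel density profiles, coverage summary).
#' Fully deterministic given `cfg$seed`. When `cfg$out_dir` is set, per-cell
#' tables, WS-cell GeoJSON, density curves, and a stats JSON are written
#' there.
#'
#' @param cfg a [pipeline_config()]
#' @return list of class `pipeline_report` with elements `grid`, `typing`,
#'   `pca`, `dedup_report`, per-set `sets$gbif` / `sets$combined`
#'   (preprocessed records, completeness table, statistics, density
#'   curves), and `summary` (side-by-side coverage summary)
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  gbif_raw <- stage("load", load_input(cfg$gbif, function(p)
    read_occurrences(p, source = "gbif")))
  revision_raw <- stage("load", load_input(cfg$revision, function(p)
    read_occurrences(p, source = "revision")))
  stack <- stage("load", load_input(cfg$rasters, read_stack))
  land <- stage("load", load_input(cfg$land, read_polygons))
  regions <- stage("load", load_input(cfg$regions, read_polygons))
  countries <- stage("load", load_input(cfg$countries, read_polygons))
  taxonomy <- stage("load", load_input(cfg$taxonomy, read_taxonomy))
  cfg$centroid_table <- stage("load", load_input(cfg$centroid_table, read_table))

  pre_g <- stage("preprocess", preprocess_set(gbif_raw, cfg, land, countries, taxonomy))
  pre_r <- stage("preprocess", preprocess_set(revision_raw, cfg, land, countries, taxonomy))
  merged <- stage("merge", merge_datasets(pre_g$kept, pre_r$kept))

  grid <- stage("grid", {
    g <- build_grid(cfg$extent, cfg$cell_size, land_mask = land)
    assign_regions(g, regions)
  })
  gbif_set <- stage("grid", assign_cells(pre_g$kept, grid))
  combined_set <- stage("grid", assign_cells(merged$combined, grid))

  env <- stage("climate", aggregate_bioclim(stack, grid))
  pca <- stage("climate", run_pca(env, n_components = 2L))
  typing <- stage("climate",
                  rarity_scores(bin_climate_space(pca, cfg$n_bins_per_axis)))

  sets <- list()
  seeds <- c(gbif = cfg$seed, combined = cfg$seed + 1000L)
  inputs <- list(gbif = gbif_set, combined = combined_set)
  for (nm in names(inputs)) {
    recs <- inputs[[nm]]
    comp <- stage("completeness",
                  completeness_table(recs, n_perm = cfg$n_perm,
                                     seed = seeds[[nm]],
                                     thresholds = cfg$thresholds))
    st <- stage("stats", set_statistics(recs, typing, comp, grid, cfg,
                                        seed = seeds[[nm]]))
    ws_scores <- typing$cell_types[typing$cell_types$cell_id %in%
                                     st$ws_cell_ids, ]
    dens <- lapply(c(pc1 = "pc1", pc2 = "pc2", rarity = "rarity"),
                   function(ax) kde_table(ws_scores[[ax]],
                                          typing$cell_types[[ax]]))
    sets[[nm]] <- list(records = recs, completeness = comp, stats = st,
                       density = dens)
  }

  n_land <- sum(grid$cells$is_land)
  summary <- lapply(names(sets), function(nm) {
    st <- sets[[nm]]$stats
    summarize_coverage(list(
      set = nm,
      computable_cells = st$n_computable,
      ws_cells = st$n_ws,
      total_cells = n_land,
      occupied_types = st$occupied_types_ws,
      possible_types = nrow(typing$type_table),
      D_obs = st$D_obs, D_p_value = st$D_p_value))
  })
  names(summary) <- names(sets)

  report <- structure(list(grid = grid, typing = typing, pca = pca,
                           dedup_report = merged$report,
                           preprocessing = list(gbif = pre_g$removed,
                                                revision = pre_r$removed),
                           sets = sets, summary = summary, seed = cfg$seed),
                      class = "pipeline_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (nm in names(x$sets)) {
    st <- x$sets[[nm]]$stats
    cat(sprintf("  %-9s records=%d computable=%d WS=%d types=%d D=%.3f (p=%.3g)\n",
                nm, st$n_records, st$n_computable, st$n_ws,
                st$occupied_types_ws, st$D_obs, st$D_p_value))
  }
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' Emits, under `dir`: per-set completeness CSVs, well-sampled cell GeoJSON,
#' density-curve CSVs, the per-cell climate typing CSV, and `stats.json`
#' with the dedup report, per-set statistics and the side-by-side summary.
#'
#' @param report a [run_pipeline()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(report$typing$cell_types, file.path(dir, "climate_typing.csv"))
  stats_out <- list(seed = report$seed,
                    dedup = report$dedup_report[c("n_gbif", "n_revision",
                                                  "n_duplicates_removed",
                                                  "n_combined")],
                    sets = list(), summary = report$summary)
  for (nm in names(report$sets)) {
    s <- report$sets[[nm]]
    write_table(s$completeness, file.path(dir, paste0("completeness_", nm, ".csv")))
    ws <- s$completeness[s$completeness$well_sampled, , drop = FALSE]
    if (nrow(ws)) {
      write_cells_geojson(ws, report$grid,
                          file.path(dir, paste0("ws_cells_", nm, ".geojson")))
    }
    for (ax in names(s$density)) {
      if (!is.null(s$density[[ax]])) {
        write_table(s$density[[ax]],
                    file.path(dir, paste0("density_", ax, "_", nm, ".csv")))
      }
    }
    st <- s$stats
    st$computable_by_region <- as.list(st$computable_by_region)
    st$ws_by_region <- as.list(st$ws_by_region)
    stats_out$sets[[nm]] <- st
  }
  stats_out$summary <- lapply(stats_out$summary, unclass)
  jsonlite::write_json(stats_out, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
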