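#' Build the analysis grid
#'
#' Lays a regular lon/lat grid of square cells over `extent`, lower-left
#' origin, row-major cell ids (west to east, then south to north). When the
#' extent width or height is not a multiple of `cell_size`, the grid is
#' extended so that whole cells cover the extent (edge cells may overhang).
#' Cells are geographic degrees by default (0.83 degrees is roughly 100 km at
#' the equator), which keeps the occurrence grid congruent with aggregated
#' climate layers.
#'
#' @param extent numeric `c(lon_min, lat_min, lon_max, lat_max)`
#' @param cell_size cell edge in degrees
#' @param land_mask optional [polyset()]; a cell is land iff it intersects
#'   the mask. `NULL` marks every cell as land; an empty mask marks none and
#'   warns.
#' @return an object of class `sampcov_grid`: list with `origin`,
#'   `cell_size`, `n_cols`, `n_rows`, and `cells` (data.frame: `id`,
#'   `lon_min`, `lat_min`, `lon_max`, `lat_max`, `centroid_lon`,
#'   `centroid_lat`, `region`, `is_land`)
#' @export
build_grid <- function(extent, cell_size = 0.83, land_mask = NULL) {
  stopifnot(length(extent) == 4L, cell_size > 0)
  if (extent[3] <= extent[1] || extent[4] <= extent[2]) {
    stop("degenerate extent: max must exceed min on both axes")
  }
  n_cols <- ceiling((extent[3] - extent[1]) / cell_size - 1e-9)
  n_rows <- ceiling((extent[4] - extent[2]) / cell_size - 1e-9)
  col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  lon_min <- extent[1] + col * cell_size
  lat_min <- extent[2] + row * cell_size
  cells <- data.frame(
    id = seq_len(n_cols * n_rows),
    lon_min = lon_min, lat_min = lat_min,
    lon_max = lon_min + cell_size, lat_max = lat_min + cell_size,
    centroid_lon = lon_min + cell_size / 2,
    centroid_lat = lat_min + cell_size / 2,
    region = NA_character_,
    is_land = TRUE)
  if (!is.null(land_mask)) {
    stopifnot(inherits(land_mask, "polyset"))
    if (length(land_mask) == 0L) {
      warning("empty land mask: no cell marked as land")
      cells$is_land <- FALSE
    } else {
      cells$is_land <- vapply(seq_len(nrow(cells)), function(i) {
        rect_intersects(as.numeric(cells[i, c("lon_min", "lat_min",
                                              "lon_max", "lat_max")]),
                        land_mask)
      }, logical(1L))
    }
  }
  structure(list(origin = c(extent[1], extent[2]), cell_size = cell_size,
                 n_cols = n_cols, n_rows = n_rows, cells = cells),
            class = "sampcov_grid")
}

#' @export
print.sampcov_grid <- function(x, ...) {
  cat(sprintf("<grid: %d x %d cells of %g deg, %d land>\n",
              x$n_cols, x$n_rows, x$cell_size, sum(x$cells$is_land)))
  invisible(x)
}

#' Assign occurrence records to grid cells
#'
#' Cells are half-open intervals `[lon_min, lon_max) x [lat_min, lat_max)`,
#' so a point on a shared edge belongs to the cell to its east/north; points
#' on the grid's outer east/north boundary fall in the last cell. Records
#' outside the grid or with invalid coordinates get `cell_id = NA` and
#' `unassigned = TRUE` — they are flagged, never dropped.
#'
#' @param records data.frame with `lon`, `lat` columns
#' @param grid a [build_grid()] result
#' @return `records` with `cell_id` and `unassigned` columns added
#' @export
assign_cells <- function(records, grid) {
  stopifnot(inherits(grid, "sampcov_grid"),
            all(c("lon", "lat") %in% names(records)))
  cs <- grid$cell_size
  col <- floor((records$lon - grid$origin[1]) / cs)
  row <- floor((records$lat - grid$origin[2]) / cs)
  # outer max boundary closes onto the last cell
  col[records$lon == grid$origin[1] + grid$n_cols * cs] <- grid$n_cols - 1L
  row[records$lat == grid$origin[2] + grid$n_rows * cs] <- grid$n_rows - 1L
  ok <- !is.na(col) & !is.na(row) &
    col >= 0 & col < grid$n_cols & row >= 0 & row < grid$n_rows
  cell_id <- rep(NA_integer_, nrow(records))
  cell_id[ok] <- as.integer(row[ok] * grid$n_cols + col[ok] + 1L)
  records$cell_id <- cell_id
  records$unassigned <- !ok
  records
}

#' Assign region labels to grid cells
#'
#' A land cell's region is the label of the polygon containing the cell's
#' centre point — for cells straddling a regional border, the centre point is
#' the decider. Centroids contained in no polygon keep `region = NA`.
#' Overlapping regions that both contain a centroid are an error.
#'
#' @param grid a [build_grid()] result
#' @param region_polygons a [polyset()] with unique labels
#' @return `grid` with `cells$region` filled in
#' @export
assign_regions <- function(grid, region_polygons) {
  stopifnot(inherits(grid, "sampcov_grid"), inherits(region_polygons, "polyset"))
  if (anyDuplicated(region_polygons$labels)) {
    stop("region polygon labels must be unique")
  }
  land <- which(grid$cells$is_land)
  hits <- locate_points(grid$cells$centroid_lon[land],
                        grid$cells$centroid_lat[land],
                        region_polygons, all_matches = TRUE)
  n_hits <- lengths(hits)
  if (any(n_hits > 1L)) {
    bad <- grid$cells$id[land[n_hits > 1L]]
    stop("overlapping region polygons contain the centroid of cell(s): ",
         paste(bad, collapse = ", "))
  }
  region <- rep(NA_character_, length(land))
  has <- n_hits == 1L
  region[has] <- region_polygons$labels[unlist(hits[has])]
  grid$cells$region[land] <- region
  grid
}

#' Export per-cell values as GeoJSON polygons
#'
#' Writes one square polygon feature per row of `cell_table`, carrying every
#' non-geometry column as a feature property. Round-trips through
#' [read_polygons()] for geometry and label.
#'
#' @param cell_table data.frame containing a `cell_id` column
#' @param grid the grid the ids refer to
#' @param path output GeoJSON file
#' @return `path`, invisibly
#' @export
write_cells_geojson <- function(cell_table, grid, path) {
  stopifnot("cell_id" %in% names(cell_table))
  cells <- grid$cells[match(cell_table$cell_id, grid$cells$id), ]
  feats <- lapply(seq_len(nrow(cell_table)), function(i) {
    b <- cells[i, ]
    ring <- list(c(b$lon_min, b$lat_min), c(b$lon_max, b$lat_min),
                 c(b$lon_max, b$lat_max), c(b$lon_min, b$lat_max),
                 c(b$lon_min, b$lat_min))
    props <- as.list(cell_table[i, , drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
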