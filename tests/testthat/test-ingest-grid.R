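test_that("read_occurrences maps Darwin-Core headers and preserves rows", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "scientificName,decimalLatitude,decimalLongitude,recordedBy,individualCount,year",
    "Synthogenus speca,1.5,2.5,\"Smith, J.\",12,1999",
    ",3.0,4.0,A. Dupont,,2001",
    "Synthogenus specb,bad,5.0,K. Okafor,3,"), csv)
  recs <- read_occurrences(csv, source = "gbif")
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$collector, c("Smith, J.", "A. Dupont", "K. Okafor"))
  expect_true(is.na(recs$species[2]))
  expect_equal(recs$count, c(12L, 1L, 3L))       # missing count defaults to 1
  expect_equal(recs$valid_coords, c(TRUE, TRUE, FALSE))  # flagged, not dropped
  expect_equal(recs$source, rep("gbif", 3L))
})

test_that("read_occurrences errors on missing mandatory columns, naming them", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("scientificName,recordedBy", "X y,Someone"), csv)
  expect_error(read_occurrences(csv), "decimalLatitude|lat")
  expect_error(read_occurrences(tempfile()), "not found")
})

test_that("read_occurrences fills year from an event date when absent", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("species,lat,lon,event_date",
               "Synthogenus speca,1,1,1987-05-12"), csv)
  expect_equal(read_occurrences(csv)$year, 1987L)
})

test_that("build_grid tiles the extent with row-major ids and a land mask", {
  mask <- polyset(list(rect_feature(0, 0, 2, 2, "land")))
  g <- build_grid(c(0, 0, 2, 2), cell_size = 1, land_mask = mask)
  expect_equal(nrow(g$cells), 4L)
  expect_true(all(g$cells$is_land))
  expect_equal(g$cells$id, 1:4)
  expect_equal(g$cells$centroid_lon, c(0.5, 1.5, 0.5, 1.5))

  west <- polyset(list(rect_feature(0, 0, 0.99, 2, "w")))
  g2 <- build_grid(c(0, 0, 2, 2), cell_size = 1, land_mask = west)
  expect_equal(sum(g2$cells$is_land), 2L)
  expect_equal(g2$cells$id[g2$cells$is_land], c(1L, 3L))

  expect_warning(g3 <- build_grid(c(0, 0, 2, 2), 1, polyset(list())),
                 "empty")
  expect_false(any(g3$cells$is_land))
})

test_that("grid extends to cover extents not divisible by the cell size", {
  g <- build_grid(c(0, 0, 2.5, 1), cell_size = 1)
  expect_equal(g$n_cols, 3L)   # last column overhangs the extent
  expect_equal(max(g$cells$lon_max), 3)
  expect_error(build_grid(c(0, 0, 0, 1), 1), "degenerate")
})

test_that("assign_cells uses half-open intervals and flags outsiders", {
  g <- build_grid(c(0, 0, 2, 2), cell_size = 1)
  pts <- data.frame(lon = c(0.5, 1.0, 2.5, 1.999),
                    lat = c(0.5, 0.5, 0.5, 1.999))
  out <- assign_cells(pts, g)
  expect_equal(out$cell_id[1], 1L)     # centroid
  expect_equal(out$cell_id[2], 2L)     # shared vertical edge -> east cell
  expect_true(is.na(out$cell_id[3]) && out$unassigned[3])
  expect_equal(out$cell_id[4], 4L)
})

test_that("every in-extent point maps to exactly one cell", {
  g <- build_grid(c(-3, 10, 4, 17), cell_size = 0.83)
  set.seed(11)
  pts <- data.frame(lon = runif(500, -3, 4), lat = runif(500, 10, 17))
  out <- assign_cells(pts, g)
  expect_false(any(out$unassigned))
  b <- g$cells[out$cell_id, ]
  expect_true(all(pts$lon >= b$lon_min & pts$lon < b$lon_max))
  expect_true(all(pts$lat >= b$lat_min & pts$lat < b$lat_max))
})

test_that("assign_regions decides by cell centre point", {
  g <- build_grid(c(0, 0, 2, 1), cell_size = 1)
  # boundary at lon = 0.6: cell 1 straddles both, centroid (0.5) in the west
  regions <- polyset(list(rect_feature(0, 0, 0.6, 1, "Western"),
                          rect_feature(0.6, 0, 2, 1, "Eastern")))
  g <- assign_regions(g, regions)
  expect_equal(g$cells$region, c("Western", "Eastern"))

  # centroid in a gap between polygons stays unassigned
  gap <- polyset(list(rect_feature(0, 0, 0.2, 1, "A"),
                      rect_feature(1.8, 0, 2, 1, "B")))
  g2 <- assign_regions(build_grid(c(0, 0, 2, 1), 1), gap)
  expect_true(all(is.na(g2$cells$region)))

  overlapping <- polyset(list(rect_feature(0, 0, 2, 1, "A"),
                              rect_feature(0, 0, 1, 1, "B")))
  expect_error(assign_regions(build_grid(c(0, 0, 2, 1), 1), overlapping),
               "overlapping")
  dup <- polyset(list(rect_feature(0, 0, 1, 1, "A"),
                      rect_feature(1, 0, 2, 1, "A")))
  expect_error(assign_regions(build_grid(c(0, 0, 2, 1), 1), dup), "unique")
})

test_that("occurrence tables round-trip through CSV losslessly", {
  recs <- make_records(
    make_record(species = "Synthogenus speca", collector = "Côte, J."),
    make_record(species = "Synthogenus specb", lat = -5.25, year = 1993L),
    make_record(locality = NA_character_),
    make_record(event_date = "1999-04-01"),
    make_record(count = 7L, country = "SE"))
  path <- tempfile(fileext = ".csv")
  write_table(recs, path)
  back <- read_table(path)
  for (col in c("species", "lat", "lon", "year", "count", "country")) {
    expect_equal(back[[col]], recs[[col]], info = col)
  }
  # empty table: header-only file, no error
  path2 <- tempfile(fileext = ".csv")
  write_table(recs[0, ], path2)
  expect_equal(nrow(read_table(path2)), 0L)
  expect_equal(names(read_table(path2)), names(recs))
})

test_that("polygon sets and cell exports round-trip through GeoJSON", {
  polys <- polyset(list(rect_feature(0, 0, 1, 2, "Western Africa"),
                        rect_feature(1, 0, 3, 2, "Eastern Africa")))
  path <- tempfile(fileext = ".geojson")
  write_polygons(polys, path)
  back <- read_polygons(path)
  expect_equal(back$labels, polys$labels)
  expect_equal(back$features[[1]]$rings[[1]], polys$features[[1]]$rings[[1]],
               ignore_attr = TRUE)

  g <- build_grid(c(0, 0, 2, 2), 1)
  tab <- data.frame(cell_id = c(1L, 4L), completeness_pct = c(80.5, 91.2))
  gj <- tempfile(fileext = ".geojson")
  write_cells_geojson(tab, g, gj)
  feats <- jsonlite::read_json(gj)$features
  expect_length(feats, 2L)
  expect_equal(feats[[2]]$properties$completeness_pct, 91.2)
})
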