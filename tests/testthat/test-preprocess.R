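test_that("species-level filter keeps binomials and collapses trinomials", {
  recs <- make_records(
    make_record(species = "Synthogenus sp."),
    make_record(species = "Synthogenus speca"),
    make_record(species = "Synthogenus speca minor"),
    make_record(species = "Synthogenus cf. specb"),
    make_record(species = NA_character_))
  out <- filter_species_level(recs)
  expect_equal(nrow(out$kept) + nrow(out$removed), nrow(recs))
  expect_equal(out$kept$species,
               c("Synthogenus speca", "Synthogenus speca"))
  expect_true(all(out$removed$reason == "not_species_level"))
})

test_that("coordinate filter assigns one primary reason per removal", {
  land <- polyset(list(rect_feature(0, 0, 10, 10, "land")))
  countries <- polyset(list(rect_feature(0, 0, 5, 10, "KE"),
                            rect_feature(5, 0, 10, 10, "TZ")))
  centroids <- data.frame(kind = c("centroid", "institution"),
                          lon = c(2, 8), lat = c(2, 8))
  recs <- make_records(
    make_record(lon = 0, lat = 0),                          # zero coord
    make_record(lon = 2.004, lat = 2.0),                    # ~0.5 km off centroid
    make_record(lon = 8.0, lat = 8.01),                     # near institution
    make_record(lon = 6, lat = 3, country = "KE"),          # in TZ polygon
    make_record(lon = 12, lat = 3),                         # off the land mask
    make_record(lon = NA_real_, lat = 3, valid_coords = FALSE),
    make_record(lon = 3, lat = 3, country = "KE"),          # clean
    make_record(lon = 6, lat = 3, country = NA_character_)) # no declared country
  out <- filter_coordinates(recs, land, countries, centroids, tolerance_km = 5)
  expect_equal(out$removed$reason,
               c("zero_coordinate", "centroid", "institution",
                 "country_mismatch", "sea", "missing_coordinate"))
  expect_equal(nrow(out$kept), 2L)
  expect_equal(nrow(out$kept) + nrow(out$removed), nrow(recs))
})

test_that("taxonomy standardisation renames, drops, and is idempotent", {
  tax <- taxonomy_map(c("Synthogenus olda" = "Synthogenus newa"),
                      drop_list = c("Synthogenus incertae"))
  recs <- make_records(
    make_record(species = "Synthogenus olda"),
    make_record(species = "Synthogenus incertae"),
    make_record(species = "Synthogenus specb"))
  out <- standardize_taxonomy(recs, tax)
  expect_equal(out$kept$species,
               c("Synthogenus newa", "Synthogenus specb"))
  expect_equal(out$removed$reason, "dropped_name")
  twice <- standardize_taxonomy(out$kept, tax)
  expect_identical(twice$kept, out$kept)
  expect_error(taxonomy_map(c(A = "B"), drop_list = "A"), "both")
  expect_error(taxonomy_map(c(A = "B"), drop_list = "B"), "drop_list")
})

test_that("label normalisation ignores format, case, accents, punctuation", {
  expect_equal(normalize_label("Smith, J."), c("j", "smith"))
  expect_identical(normalize_label("Smith, J."), normalize_label("J. Smith"))
  expect_identical(normalize_label("Côte d'Ivoire"),
                   normalize_label("cote divoire"))
  expect_identical(normalize_label(NA_character_), character())
  expect_identical(normalize_label(""), character())
})

test_that("duplicate rule requires all criteria jointly", {
  a <- make_record(collector = "Smith, J.", locality = "Nairobi; Kenya",
                   year = 1993L, lon = 36.8, lat = -1.3)
  same <- make_record(collector = "J. Smith", locality = "NAIROBI KENYA",
                      year = 1993L, lon = 37.5, lat = -0.9)
  expect_true(records_duplicate(a, same)$duplicate)
  expect_true(records_duplicate(same, a)$duplicate)  # symmetric

  wrong_year <- same; wrong_year$year <- 1994L
  r <- records_duplicate(a, wrong_year)
  expect_false(r$duplicate)
  expect_false(r$trace[["year"]])

  too_far <- same; too_far$lon <- a$lon + 1.5
  r <- records_duplicate(a, too_far)
  expect_false(r$duplicate)
  expect_false(r$trace[["distance"]])
  # exactly one degree apart still matches ("no more than one degree")
  edge <- same; edge$lon <- a$lon + 1.0
  expect_true(records_duplicate(a, edge)$duplicate)
})

test_that("date precision is compared at shared granularity by default", {
  a <- make_record(event_date = "1993-05", year = 1993L)
  month_only_other <- make_record(event_date = "1993", year = 1993L)
  both_months <- make_record(event_date = "1993-05-12", year = 1993L)
  other_month <- make_record(event_date = "1993-06", year = 1993L)
  expect_true(records_duplicate(a, month_only_other)$duplicate)
  expect_true(records_duplicate(a, both_months)$duplicate)
  expect_false(records_duplicate(a, other_month)$duplicate)
  # strict reading: a one-sided precise date blocks the match
  expect_false(records_duplicate(a, month_only_other,
                                 date_rule = "strict")$duplicate)
  expect_false(records_duplicate(a, both_months,
                                 date_rule = "strict")$duplicate)
})

test_that("merge removes injected duplicates and keeps the count identity", {
  set.seed(5)
  gbif <- do.call(rbind, lapply(1:10, function(i)
    make_record(species = paste("Synthogenus", c("speca", "specb")[i %% 2 + 1]),
                year = 1990L + i, lon = i, lat = i,
                locality = paste("Site", i))))
  revision <- do.call(rbind, lapply(11:27, function(i)
    make_record(species = "Synthogenus specc", year = 1950L + i,
                lon = i / 10, lat = i / 10, locality = paste("Camp", i),
                source = "revision")))
  # 17 independent revision rows + 3 perturbed copies of gbif rows 2, 5, 8
  # = 20 revision rows, 3 of them duplicates
  dups <- gbif[c(2, 5, 8), ]
  dups$collector <- "SMITH, J"
  dups$locality <- toupper(dups$locality)
  dups$lon <- dups$lon + 0.7
  dups$source <- "revision"
  revision <- rbind(revision, dups)

  m <- merge_datasets(gbif, revision)
  expect_equal(m$report$n_duplicates_removed, 3L)
  expect_equal(m$report$n_combined, 27L)
  expect_equal(m$report$n_combined,
               m$report$n_gbif + m$report$n_revision -
                 m$report$n_duplicates_removed)
  expect_setequal(m$report$duplicate_pairs$gbif_row, c(2L, 5L, 8L))
  # retained copies are the gbif ones
  expect_true(all(m$combined$source[m$combined$locality %in%
                                      c("Site 2", "Site 5", "Site 8")] == "gbif"))

  # merging again removes nothing further
  m2 <- merge_datasets(m$combined[m$combined$source == "gbif", ],
                       m$combined[m$combined$source == "revision", ])
  expect_equal(m2$report$n_duplicates_removed, 0L)

  # zero overlap: plain concatenation
  m3 <- merge_datasets(gbif, revision[1:17, ])
  expect_equal(m3$report$n_combined, 27L)
})

test_that("retain side is configurable", {
  gbif <- make_record(year = 1990L)
  revision <- make_record(year = 1990L, lat = 1.6, source = "revision")
  m <- merge_datasets(gbif, revision, retain = "revision")
  expect_equal(m$report$n_combined, 1L)
  expect_equal(m$combined$source, "revision")
})
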