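#' Canonical occurrence columns and the default Darwin-Core column map
#'
#' Occurrence tables are plain data.frames with the canonical columns
#' `species`, `lat`, `lon`, `year`, `event_date`, `collector`, `locality`,
#' `count`, `country`, `source`, plus a `valid_coords` flag set at read time.
#' `darwin_core_map()` returns the default mapping from Darwin-Core-style
#' file headers to these fields; pass a modified copy to [read_occurrences()]
#' for other schemas.
#'
#' @return named character vector: file column -> canonical field
#' @export
darwin_core_map <- function() {
  c(scientificName = "species",
    species = "species",
    decimalLatitude = "lat",
    latitude = "lat",
    lat = "lat",
    decimalLongitude = "lon",
    longitude = "lon",
    lon = "lon",
    year = "year",
    eventDate = "event_date",
    event_date = "event_date",
    recordedBy = "collector",
    collector = "collector",
    locality = "locality",
    individualCount = "count",
    count = "count",
    countryCode = "country",
    country = "country",
    source = "source")
}

occurrence_fields <- function() {
  c("species", "lat", "lon", "year", "event_date", "collector",
    "locality", "count", "country", "source")
}

#' Read an occurrence CSV into the canonical schema
#'
#' Row order is preserved and nothing is dropped: rows with unparseable or
#' missing coordinates are kept with `valid_coords = FALSE` so downstream
#' filters can count them. Missing optional fields become `NA`; a missing or
#' unparseable specimen count defaults to 1. If a record's `event_date`
#' carries a year but `year` is absent, the year is filled from the date.
#'
#' @param path CSV file with a header row
#' @param source tag recorded in the `source` column (e.g. `"gbif"`,
#'   `"revision"`); an existing `source` column in the file wins
#' @param column_map named character vector mapping file columns to canonical
#'   fields; default [darwin_core_map()]
#' @return data.frame of occurrence records
#' @export
read_occurrences <- function(path, source = NA_character_,
                             column_map = darwin_core_map()) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  mapped <- column_map[names(raw)]
  keep <- !is.na(mapped)
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (i in which(keep)) out[[mapped[[i]]]] <- raw[[i]]
  missing_mandatory <- setdiff(c("species", "lat", "lon"), names(out))
  if (length(missing_mandatory)) {
    stop("mandatory column(s) missing after mapping: ",
         paste(missing_mandatory, collapse = ", "))
  }
  for (f in occurrence_fields()) if (is.null(out[[f]])) out[[f]] <- NA_character_
  out <- out[occurrence_fields()]

  blank_to_na <- function(x) { x[!nzchar(trimws(x))] <- NA_character_; x }
  out[] <- lapply(out, blank_to_na)

  lat <- suppressWarnings(as.numeric(out$lat))
  lon <- suppressWarnings(as.numeric(out$lon))
  out$valid_coords <- !is.na(lat) & !is.na(lon) &
    lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180
  out$lat <- lat
  out$lon <- lon

  out$year <- suppressWarnings(as.integer(out$year))
  date_year <- suppressWarnings(as.integer(substr(out$event_date, 1L, 4L)))
  out$year[is.na(out$year)] <- date_year[is.na(out$year)]

  cnt <- suppressWarnings(as.integer(out$count))
  cnt[is.na(cnt) | cnt < 1L] <- 1L
  out$count <- cnt

  if (all(is.na(out$source))) out$source <- source
  rownames(out) <- NULL
  out
}

#' Write and re-read tabular results
#'
#' CSV writer whose output round-trips through [read_table()] with identical
#' column names and values. Empty tables write a header-only file.
#'
#' @param table data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_table <- function(table, path) {
  stopifnot(is.data.frame(table), ncol(table) >= 1L)
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
}
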