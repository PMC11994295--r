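#' Taxonomic standardisation map
#'
#' Holds a synonym map (old name -> accepted name) and a drop list (names to
#' remove outright, e.g. extralimital species or names placed in *incertae
#' sedis*). The map must be consistent: accepted names may not appear in the
#' drop list, no name may be both renamed and dropped, and the map must be
#' idempotent (accepted names map to themselves or not at all).
#'
#' @param synonym_map named character vector, `names()` = old names
#' @param drop_list character vector of names to remove
#' @return object of class `taxonomy_map`
#' @export
taxonomy_map <- function(synonym_map = character(), drop_list = character()) {
  synonym_map <- unlist(synonym_map)
  if (length(synonym_map) && is.null(names(synonym_map))) {
    stop("synonym_map must be named (old name -> accepted name)")
  }
  clash <- intersect(names(synonym_map), drop_list)
  if (length(clash)) {
    stop("name(s) in both synonym_map and drop_list: ",
         paste(clash, collapse = ", "))
  }
  if (length(intersect(unname(synonym_map), drop_list))) {
    stop("accepted name(s) appear in drop_list")
  }
  chained <- synonym_map[unname(synonym_map) %in% names(synonym_map) &
                           unname(synonym_map) != names(synonym_map)]
  chained <- chained[synonym_map[chained] != chained]
  if (length(chained)) {
    stop("synonym_map is not idempotent for: ",
         paste(unique(chained), collapse = ", "))
  }
  structure(list(synonym_map = synonym_map, drop_list = drop_list),
            class = "taxonomy_map")
}

#' @rdname taxonomy_map
#' @param path CSV with columns `name`, `action` (`rename` or `drop`) and
#'   `accepted_name` (for renames)
#' @export
read_taxonomy <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "action")
  if (!all(need %in% names(tab))) {
    stop("taxonomy CSV needs columns: ", paste(need, collapse = ", "))
  }
  ren <- tab[tab$action == "rename", ]
  syn <- stats::setNames(ren$accepted_name, ren$name)
  taxonomy_map(syn, tab$name[tab$action == "drop"])
}

species_level_tokens <- c("sp", "spp", "cf", "aff", "indet", "nr", "gen")

#' Keep only species-level identifications
#'
#' A record is species-level when its name is a binomial: a capitalised genus
#' followed by a lowercase epithet that is not an open-nomenclature
#' qualifier (`sp.`, `cf.`, `aff.`, ...). Trinomials are collapsed to their
#' binomial.
#'
#' @param records occurrence data.frame
#' @return list with `kept` and `removed` (the latter with a `reason`
#'   column); `nrow(kept) + nrow(removed) == nrow(records)`
#' @export
filter_species_level <- function(records) {
  name <- trimws(ifelse(is.na(records$species), "", records$species))
  toks <- strsplit(name, "\\s+")
  ok <- vapply(toks, function(tk) {
    if (length(tk) < 2L) return(FALSE)
    epithet <- sub("\\.$", "", tk[2L])
    grepl("^[A-Z][a-z-]+$", tk[1L]) &&
      grepl("^[a-z-]+$", epithet) &&
      !(epithet %in% species_level_tokens)
  }, logical(1L))
  collapsed <- vapply(toks, function(tk) {
    if (length(tk) >= 2L) paste(tk[1:2], collapse = " ") else NA_character_
  }, "")
  kept <- records[ok, , drop = FALSE]
  kept$species <- collapsed[ok]
  removed <- records[!ok, , drop = FALSE]
  if (nrow(removed)) removed$reason <- "not_species_level"
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Coordinate quality filtering
#'
#' Removes, with one primary reason code each (first failing test in the
#' order below), records that are:
#' \itemize{
#'   \item `missing_coordinate` — absent or unparseable coordinates;
#'   \item `zero_coordinate` — exactly (0, 0);
#'   \item `sea` — not on the land polygons;
#'   \item `centroid` — within `tolerance_km` of a listed country centroid;
#'   \item `institution` — within `tolerance_km` of a listed institution;
#'   \item `country_mismatch` — the containing country polygon's label
#'     differs from the record's declared country (records with no declared
#'     country skip this test).
#' }
#'
#' @param records occurrence data.frame (from [read_occurrences()])
#' @param land_polygons [polyset()] land mask, or `NULL` to skip the sea test
#' @param country_polygons [polyset()] labelled with ISO-2 codes, or `NULL`
#' @param centroid_table data.frame with columns `kind`
#'   (`"centroid"`/`"institution"`), `lon`, `lat`, or `NULL`
#' @param tolerance_km proximity radius for centroid/institution removal
#' @return list with `kept` and `removed` (reason-coded)
#' @export
filter_coordinates <- function(records, land_polygons = NULL,
                               country_polygons = NULL,
                               centroid_table = NULL, tolerance_km = 5) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  valid <- if ("valid_coords" %in% names(records)) records$valid_coords else
    !is.na(records$lon) & !is.na(records$lat)
  reason[!valid] <- "missing_coordinate"
  zero <- valid & records$lon == 0 & records$lat == 0
  reason[is.na(reason) & zero] <- "zero_coordinate"

  todo <- which(is.na(reason))
  if (!is.null(land_polygons) && length(todo)) {
    at_sea <- is.na(locate_points(records$lon[todo], records$lat[todo],
                                  land_polygons))
    reason[todo[at_sea]] <- "sea"
  }
  near_any <- function(idx, pts) {
    if (!length(idx) || !nrow(pts)) return(logical(length(idx)))
    d <- geosphere::distHaversine(
      cbind(records$lon[idx], records$lat[idx])[rep(seq_along(idx), each = nrow(pts)), , drop = FALSE],
      cbind(pts$lon, pts$lat)[rep(seq_len(nrow(pts)), times = length(idx)), , drop = FALSE])
    apply(matrix(d, nrow = nrow(pts)), 2L, min) <= tolerance_km * 1000
  }
  if (!is.null(centroid_table)) {
    todo <- which(is.na(reason))
    cen <- centroid_table[centroid_table$kind == "centroid", , drop = FALSE]
    reason[todo[near_any(todo, cen)]] <- "centroid"
    todo <- which(is.na(reason))
    inst <- centroid_table[centroid_table$kind == "institution", , drop = FALSE]
    reason[todo[near_any(todo, inst)]] <- "institution"
  }
  if (!is.null(country_polygons)) {
    todo <- which(is.na(reason) & !is.na(records$country))
    if (length(todo)) {
      at <- locate_points(records$lon[todo], records$lat[todo], country_polygons)
      found <- country_polygons$labels[at]
      mismatch <- !is.na(found) & found != records$country[todo]
      reason[todo[mismatch]] <- "country_mismatch"
    }
  }
  kept <- records[is.na(reason), , drop = FALSE]
  removed <- records[!is.na(reason), , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Apply a taxonomy map to records
#'
#' Renames species through the synonym map, then removes records whose
#' (renamed) species is on the drop list. Idempotent by construction of
#' [taxonomy_map()].
#'
#' @param records occurrence data.frame
#' @param taxonomy a [taxonomy_map()]
#' @return list with `kept` and `removed` (reason `dropped_name`)
#' @export
standardize_taxonomy <- function(records, taxonomy) {
  stopifnot(inherits(taxonomy, "taxonomy_map"))
  sp <- records$species
  hit <- match(sp, names(taxonomy$synonym_map))
  sp[!is.na(hit)] <- unname(taxonomy$synonym_map[hit[!is.na(hit)]])
  records$species <- sp
  drop <- sp %in% taxonomy$drop_list
  removed <- records[drop, , drop = FALSE]
  if (nrow(removed)) removed$reason <- "dropped_name"
  kept <- records[!drop, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Normalise a collector/locality label to a token set
#'
#' Case-folds, strips accents, removes periods and apostrophes (so
#' "d'Ivoire" and "Divoire" agree and initials lose their period), turns
#' remaining punctuation into separators, and returns the sorted set of
#' unique tokens. Two labels written in different formats compare equal iff
#' their token sets are equal.
#'
#' @param text character scalar (or `NA`)
#' @return character vector of sorted unique tokens (empty for `NA`/empty)
#' @export
normalize_label <- function(text) {
  if (length(text) != 1L) stop("normalize_label() takes one label at a time")
  if (is.na(text)) return(character())
  x <- tolower(text)
  x <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  if (is.na(x)) x <- tolower(text)
  x <- gsub("[.'’`\"^~]", "", x)
  x <- gsub("[^a-z0-9]+", " ", x)
  toks <- strsplit(trimws(x), " ")[[1L]]
  sort(unique(toks[nzchar(toks)]))
}

labels_equal <- function(a, b) {
  identical(normalize_label(a), normalize_label(b))
}

parse_date_parts <- function(event_date) {
  if (is.na(event_date)) return(c(NA_integer_, NA_integer_, NA_integer_))
  p <- strsplit(as.character(event_date), "[-/]")[[1L]]
  out <- suppressWarnings(as.integer(p[1:3]))
  out
}

#' Rule-based duplicate test for a pair of records
#'
#' Two records are duplicates iff all of the following hold: same species;
#' same collection year; if a more precise date (month/day) is present, it
#' agrees (under `date_rule = "shared"`, agreement is required at the finest
#' granularity present in *both* records; under `"strict"`, a month or day
#' present in only one record blocks the match); collector and locality
#' labels are equal as normalised token sets; and the coordinates differ by
#' no more than one geographic degree on each axis independently.
#'
#' @param a,b single-row occurrence data.frames (or lists) with the
#'   canonical fields
#' @param date_rule `"shared"` (default) or `"strict"`
#' @param max_deg coordinate tolerance in degrees per axis
#' @return list with `duplicate` (logical) and `trace` (named logical vector
#'   giving the outcome of every rule)
#' @export
records_duplicate <- function(a, b, date_rule = c("shared", "strict"),
                              max_deg = 1.0) {
  date_rule <- match.arg(date_rule)
  same_or_both_na <- function(x, y) (is.na(x) && is.na(y)) ||
    (!is.na(x) && !is.na(y) && x == y)
  trace <- c(species = FALSE, year = FALSE, date = FALSE,
             collector = FALSE, locality = FALSE, distance = FALSE)
  trace["species"] <- !is.na(a$species) && !is.na(b$species) &&
    a$species == b$species
  trace["year"] <- same_or_both_na(a$year, b$year)

  da <- parse_date_parts(a$event_date)
  db <- parse_date_parts(b$event_date)
  ga <- sum(!is.na(da))   # granularity: 0 none, 1 year, 2 month, 3 day
  gb <- sum(!is.na(db))
  if (date_rule == "shared") {
    g <- min(ga, gb)
    trace["date"] <- g < 2L || all(da[2:g] == db[2:g])
  } else {
    trace["date"] <- ga == gb && (ga < 2L || all(da[2:ga] == db[2:ga]))
  }
  trace["collector"] <- labels_equal(a$collector, b$collector)
  trace["locality"] <- labels_equal(a$locality, b$locality)
  trace["distance"] <- !is.na(a$lat) && !is.na(b$lat) &&
    abs(a$lat - b$lat) <= max_deg && abs(a$lon - b$lon) <= max_deg
  list(duplicate = all(trace), trace = trace)
}

#' Merge two occurrence datasets, removing cross-dataset duplicates
#'
#' Every revision record that matches at least one GBIF record under
#' [records_duplicate()] is treated as a duplicate; by default the GBIF copy
#' (the already-mobilised record) is retained and the revision copy dropped
#' (`retain = "revision"` flips this). Candidate pairs are blocked on
#' (species, year) before the full rule test, so only same-species/year
#' pairs are compared.
#'
#' @param gbif_table,revision_table preprocessed occurrence data.frames
#' @param retain which copy of a duplicate to keep
#' @param date_rule passed to [records_duplicate()]
#' @param max_deg passed to [records_duplicate()]
#' @return list with `combined` (data.frame) and `report`: list with
#'   `n_gbif`, `n_revision`, `n_duplicates_removed`, `n_combined`, and
#'   `duplicate_pairs` (data.frame: `gbif_row`, `revision_row`, `trace`)
#' @export
merge_datasets <- function(gbif_table, revision_table,
                           retain = c("gbif", "revision"),
                           date_rule = "shared", max_deg = 1.0) {
  retain <- match.arg(retain)
  key <- function(t) paste(t$species, t$year, sep = "\r")
  gkey <- key(gbif_table)
  rkey <- key(revision_table)
  pairs_g <- integer(); pairs_r <- integer(); traces <- character()
  dup_rev <- logical(nrow(revision_table))
  for (i in seq_len(nrow(revision_table))) {
    cand <- which(gkey == rkey[i])
    for (j in cand) {
      res <- records_duplicate(gbif_table[j, ], revision_table[i, ],
                               date_rule = date_rule, max_deg = max_deg)
      if (res$duplicate) {
        dup_rev[i] <- TRUE
        pairs_g <- c(pairs_g, j); pairs_r <- c(pairs_r, i)
        traces <- c(traces, paste(names(res$trace)[res$trace], collapse = "+"))
      }
    }
  }
  if (retain == "gbif") {
    combined <- rbind(gbif_table, revision_table[!dup_rev, , drop = FALSE])
    n_removed <- sum(dup_rev)
  } else {
    dup_gbif <- seq_len(nrow(gbif_table)) %in% pairs_g
    combined <- rbind(gbif_table[!dup_gbif, , drop = FALSE], revision_table)
    n_removed <- sum(dup_gbif)
  }
  rownames(combined) <- NULL
  report <- list(
    n_gbif = nrow(gbif_table),
    n_revision = nrow(revision_table),
    n_duplicates_removed = n_removed,
    n_combined = nrow(combined),
    duplicate_pairs = data.frame(gbif_row = pairs_g, revision_row = pairs_r,
                                 trace = traces))
  stopifnot(report$n_combined ==
              report$n_gbif + report$n_revision - report$n_duplicates_removed)
  list(combined = combined, report = report)
}
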