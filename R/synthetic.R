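#' Synthetic study scenario
#'
#' Bundles every knob of the synthetic world: a rectangular study area
#' carved into four quadrant regions, a stack of climate layers driven by
#' two smooth latent factors (a latitudinal and a longitudinal gradient), a
#' log-series species pool with Gaussian climate niches, and two occurrence
#' datasets — a sparse, regionally biased "gbif-like" set and a denser,
#' near-uniform "revision-like" set sharing a fraction of format-perturbed
#' duplicate records. Every output downstream is a pure function of `seed`.
#'
#' @param seed integer master seed
#' @param extent study rectangle `c(lon_min, lat_min, lon_max, lat_max)`
#' @param cell_size analysis cell edge (degrees)
#' @param raster_res climate pixel edge (degrees)
#' @param n_layers number of climate layers (19 = the bioclim convention)
#' @param n_species species-pool size
#' @param sad_x log-series shape (relative abundance of rank k is
#'   proportional to `sad_x^k / k`)
#' @param niche_breadth Gaussian niche sd in latent-factor units (latent
#'   factors span [0, 1])
#' @param occ_threshold occupancy below which a species is absent from a
#'   cell (defines true richness; sampling respects it)
#' @param noise_sd per-pixel noise sd added to the mixed climate layers
#' @param n_gbif,n_revision records per dataset
#' @param gbif_effort,revision_effort per-region effort multipliers (order
#'   SW, SE, NW, NE)
#' @param duplicate_fraction fraction of gbif-like rows cloned into the
#'   revision-like set with rule-preserving format perturbations
#' @param n_near_miss rule-violating near-duplicates (year shifted or
#'   coordinates offset beyond one degree) added for precision testing
#' @return list of class `synthetic_scenario`
#' @export
synthetic_scenario <- function(seed = 42L,
                               extent = c(0, 0, 10, 10),
                               cell_size = 1,
                               raster_res = 0.25,
                               n_layers = 19L,
                               n_species = 40L,
                               sad_x = 0.96,
                               niche_breadth = 0.35,
                               occ_threshold = 0.01,
                               noise_sd = 0.05,
                               n_gbif = 600L,
                               n_revision = 1500L,
                               gbif_effort = c(SW = 0.5, SE = 8, NW = 0.5, NE = 1),
                               revision_effort = c(SW = 1, SE = 1, NW = 1, NE = 1),
                               duplicate_fraction = 0.1,
                               n_near_miss = 0L) {
  sc <- as.list(environment())
  stopifnot(sc$n_species >= 2L, sc$duplicate_fraction >= 0,
            sc$duplicate_fraction <= 1, all(sc$gbif_effort >= 0))
  class(sc) <- "synthetic_scenario"
  sc
}

# latent climate factors, each scaled to [0, 1] over the extent
latent_factors <- function(scenario, lon, lat) {
  e <- scenario$extent
  cbind(f1 = (lat - e[2]) / (e[4] - e[2]),
        f2 = (lon - e[1]) / (e[3] - e[1]))
}

#' Synthetic climate layer stack
#'
#' Layer 1 is the pure latitudinal factor (strictly monotone in latitude at
#' fixed longitude) and layer 2 the pure longitudinal one; the remaining
#' layers are seeded random mixtures of the two factors plus pixel noise, so
#' two latent axes carry most of the variance — the structure a 2-component
#' PCA summarises well.
#'
#' @param scenario a [synthetic_scenario()]
#' @return a [bioclim_stack()]
#' @export
make_synthetic_bioclim <- function(scenario) {
  e <- scenario$extent
  res <- scenario$raster_res
  ncols <- round((e[3] - e[1]) / res)
  nrows <- round((e[4] - e[2]) / res)
  px_lon <- e[1] + (seq_len(ncols) - 0.5) * res
  px_lat <- e[4] - (seq_len(nrows) - 0.5) * res   # top row = north
  lonm <- matrix(px_lon, nrow = nrows, ncol = ncols, byrow = TRUE)
  latm <- matrix(px_lat, nrow = nrows, ncol = ncols)
  f <- latent_factors(scenario, as.vector(lonm), as.vector(latm))
  rng <- local_rng(scenario$seed + 1L)
  layers <- vector("list", scenario$n_layers)
  layers[[1L]] <- matrix(f[, "f1"], nrow = nrows)
  if (scenario$n_layers >= 2L) layers[[2L]] <- matrix(f[, "f2"], nrow = nrows)
  if (scenario$n_layers >= 3L) {
    for (j in 3:scenario$n_layers) {
      w <- stats::rnorm(2L)
      eps <- stats::rnorm(nrows * ncols, sd = scenario$noise_sd)
      layers[[j]] <- matrix(f %*% w + eps, nrow = nrows)
    }
  }
  restore_rng(rng)
  names(layers) <- sprintf("bio%02d", seq_along(layers))
  bioclim_stack(layers, e)
}

#' Synthetic region and land polygons
#'
#' Four quadrant regions (SW, SE, NW, NE) and a land mask covering the full
#' extent.
#'
#' @param scenario a [synthetic_scenario()]
#' @return list with `regions` and `land`, both [polyset()]s
#' @export
make_synthetic_polygons <- function(scenario) {
  e <- scenario$extent
  mx <- (e[1] + e[3]) / 2
  my <- (e[2] + e[4]) / 2
  regions <- polyset(list(
    rect_feature(e[1], e[2], mx, my, "SW"),
    rect_feature(mx, e[2], e[3], my, "SE"),
    rect_feature(e[1], my, mx, e[4], "NW"),
    rect_feature(mx, my, e[3], e[4], "NE")))
  land <- polyset(list(rect_feature(e[1], e[2], e[3], e[4], "land")))
  list(regions = regions, land = land)
}

int_to_epithet <- function(i) {
  # deterministic lowercase epithets: 1 -> "speca", 27 -> "specaa", ...
  letters_only <- function(k) {
    out <- ""
    repeat {
      out <- paste0(letters[(k - 1L) %% 26L + 1L], out)
      k <- (k - 1L) %/% 26L
      if (k == 0L) break
    }
    out
  }
  paste0("spec", vapply(i, letters_only, ""))
}

#' Synthetic species pool with climate niches
#'
#' Relative abundances follow a log-series (rank k proportional to
#' `sad_x^k / k`, normalised to sum 1). Each species receives a uniform
#' niche centre in the 2-D latent-factor space and the scenario's niche
#' breadth. A species' occupancy of a cell is its abundance times a
#' Gaussian match between the cell's latent coordinates and the niche
#' centre; the cell's true richness counts species whose occupancy exceeds
#' the scenario threshold, and sampling never draws a species below it, so
#' observed richness can never exceed the truth.
#'
#' @param scenario a [synthetic_scenario()]
#' @param grid the analysis grid (defaults to the scenario's own grid)
#' @return list with `species` (data.frame: `species`, `abundance`,
#'   `center1`, `center2`, `breadth`), `occupancy` (cells x species
#'   matrix), `cell_truth` (data.frame: `cell_id`, `true_richness`), `grid`
#' @export
make_species_pool <- function(scenario, grid = NULL) {
  if (is.null(grid)) grid <- build_grid(scenario$extent, scenario$cell_size)
  k <- seq_len(scenario$n_species)
  ab <- scenario$sad_x^k / k
  ab <- ab / sum(ab)
  rng <- local_rng(scenario$seed + 2L)
  centers <- cbind(stats::runif(scenario$n_species),
                   stats::runif(scenario$n_species))
  restore_rng(rng)
  species <- data.frame(
    species = paste("Synthogenus", int_to_epithet(k)),
    abundance = ab,
    center1 = centers[, 1L], center2 = centers[, 2L],
    breadth = scenario$niche_breadth)
  cells <- grid$cells[grid$cells$is_land, ]
  latent <- latent_factors(scenario, cells$centroid_lon, cells$centroid_lat)
  d2 <- outer(latent[, "f1"], species$center1, `-`)^2 +
    outer(latent[, "f2"], species$center2, `-`)^2
  occ <- sweep(exp(-d2 / (2 * scenario$niche_breadth^2)), 2L, ab, `*`)
  occ[occ < scenario$occ_threshold] <- 0
  rownames(occ) <- cells$id
  colnames(occ) <- species$species
  cell_truth <- data.frame(cell_id = cells$id,
                           true_richness = rowSums(occ > 0))
  list(species = species, occupancy = occ, cell_truth = cell_truth,
       grid = grid)
}

collector_pool <- c("J. Smith", "A. Dupont", "M. van der Berg", "K. Okafor",
                    "L. Fernandez", "P. O'Neill", "R. Traore", "E. Bjornstad")

perturb_collector <- function(x) {
  # reformat "J. Smith" -> "Smith, J" style; rule-preserving (same token set)
  toks <- strsplit(x, " +")[[1L]]
  paste0(toupper(paste(rev(toks), collapse = ", ")))
}

perturb_locality <- function(x) {
  gsub(" ", ",  ", toupper(x))
}

#' Simulate the two occurrence datasets
#'
#' Draws records cell-by-cell with probability proportional to regional
#' effort times total cell occupancy, then species within the cell
#' proportional to occupancy. The gbif-like set uses the scenario's skewed
#' regional effort, the revision-like set its near-uniform one. A
#' `duplicate_fraction` of gbif-like rows is then cloned into the
#' revision-like set with rule-preserving perturbations (label reformatting
#' and coordinate jitter under one degree); optional near-miss clones
#' violate exactly one dedup rule. All injected rows are recorded in the
#' truth table.
#'
#' @param scenario a [synthetic_scenario()]
#' @param pool a [make_species_pool()] result (built if `NULL`)
#' @return list with `gbif`, `revision` (occurrence data.frames) and
#'   `truth`: list with `cell_truth`, `species`, `duplicate_pairs`
#'   (data.frame `gbif_row`, `revision_row`), `near_miss_rows` (revision row
#'   indices)
#' @export
simulate_occurrences <- function(scenario, pool = NULL) {
  if (is.null(pool)) pool <- make_species_pool(scenario)
  grid <- pool$grid
  cells <- grid$cells[grid$cells$is_land, ]
  polys <- make_synthetic_polygons(scenario)
  grid_r <- assign_regions(grid, polys$regions)
  region <- grid_r$cells$region[match(cells$id, grid_r$cells$id)]
  occ <- pool$occupancy
  cell_mass <- rowSums(occ)

  draw_set <- function(n, effort, source, seed_off) {
    w <- cell_mass * as.numeric(effort[region])
    if (all(w == 0)) stop("no cell has positive sampling weight")
    if (n > 0 && sum(w > 0) == 0L) stop("requested records but no feasible cells")
    rng <- local_rng(scenario$seed + seed_off)
    on.exit(restore_rng(rng))
    ci <- sample.int(nrow(cells), n, replace = TRUE, prob = w)
    sp <- vapply(ci, function(i) {
      p <- occ[i, ]
      sample.int(ncol(occ), 1L, prob = p)
    }, integer(1L))
    lon <- cells$lon_min[ci] + stats::runif(n) * scenario$cell_size
    lat <- cells$lat_min[ci] + stats::runif(n) * scenario$cell_size
    year <- sample(1960:2015, n, replace = TRUE)
    has_month <- stats::runif(n) < 0.5
    month <- sample.int(12L, n, replace = TRUE)
    event_date <- ifelse(has_month, sprintf("%d-%02d", year, month),
                         as.character(year))
    data.frame(
      species = colnames(occ)[sp],
      lat = lat, lon = lon, year = year, event_date = event_date,
      collector = sample(collector_pool, n, replace = TRUE),
      locality = sprintf("Locality %d site %d, %s sector", cells$id[ci],
                         sample.int(500L, n, replace = TRUE), region[ci]),
      count = stats::rpois(n, 2) + 1L,
      country = region[ci],
      source = source,
      valid_coords = TRUE,
      stringsAsFactors = FALSE)
  }

  gbif <- draw_set(scenario$n_gbif, scenario$gbif_effort, "gbif", 3L)
  revision <- draw_set(scenario$n_revision, scenario$revision_effort,
                       "revision", 4L)

  n_dup <- floor(scenario$duplicate_fraction * scenario$n_gbif)
  rng <- local_rng(scenario$seed + 5L)
  dup_idx <- if (n_dup > 0) sort(sample.int(scenario$n_gbif, n_dup)) else integer()
  jitter <- function(k) stats::runif(k, -0.4, 0.4)
  clones <- gbif[dup_idx, , drop = FALSE]
  if (n_dup > 0) {
    clones$collector <- vapply(clones$collector, perturb_collector, "")
    clones$locality <- vapply(clones$locality, perturb_locality, "")
    e <- scenario$extent
    # jitter stays inside the study area so clones survive the land filter
    clones$lat <- pmin(pmax(clones$lat + jitter(n_dup), e[2] + 1e-6), e[4] - 1e-6)
    clones$lon <- pmin(pmax(clones$lon + jitter(n_dup), e[1] + 1e-6), e[3] - 1e-6)
    clones$source <- "revision"
  }
  near_rows <- integer()
  if (scenario$n_near_miss > 0) {
    nm_idx <- sample.int(scenario$n_gbif, scenario$n_near_miss)
    nm <- gbif[nm_idx, , drop = FALSE]
    shift_year <- stats::runif(scenario$n_near_miss) < 0.5
    nm$year <- nm$year + ifelse(shift_year, 1L, 0L)
    nm$event_date <- vapply(seq_len(nrow(nm)), function(i) {
      if (is.na(nm$event_date[i])) return(NA_character_)
      sub("^\\d{4}", as.character(nm$year[i]), nm$event_date[i])
    }, "")
    nm$lon <- nm$lon + ifelse(shift_year, 0, 1.6)
    nm$source <- "revision"
    near_rows <- nrow(revision) + nrow(clones) + seq_len(nrow(nm))
    clones <- rbind(clones, nm)
  }
  restore_rng(rng)
  revision_out <- rbind(revision, clones)
  rownames(revision_out) <- NULL
  dup_pairs <- data.frame(gbif_row = dup_idx,
                          revision_row = nrow(revision) + seq_along(dup_idx))
  truth <- list(cell_truth = pool$cell_truth, species = pool$species,
                duplicate_pairs = dup_pairs, near_miss_rows = near_rows)
  list(gbif = gbif, revision = revision_out, truth = truth)
}
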