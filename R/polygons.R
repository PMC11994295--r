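#' Labelled polygon sets
#'
#' A `polyset` is a minimal container for labelled (multi)polygons in
#' geographic (lon/lat, WGS84) coordinates: a list of features, each a list
#' with a `label` and `rings`, where `rings` is a list of closed N x 2
#' matrices (columns lon, lat). Ring membership is decided by the even-odd
#' rule, so interior rings act as holes. Polygon sets are read from and
#' written to GeoJSON `FeatureCollection`s.
#'
#' @param features list of features, each `list(label =, rings =)`
#' @return an object of class `polyset`
#' @export
polyset <- function(features) {
  stopifnot(is.list(features))
  for (f in features) {
    stopifnot(is.list(f$rings), length(f$rings) >= 1L)
    for (r in f$rings) stopifnot(is.matrix(r), ncol(r) == 2L, nrow(r) >= 3L)
  }
  labels <- vapply(features, function(f) as.character(f$label %||% NA_character_), "")
  structure(list(features = features, labels = labels), class = "polyset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
length.polyset <- function(x) length(x$features)

#' @export
print.polyset <- function(x, ...) {
  cat(sprintf("<polyset: %d feature(s): %s>\n", length(x),
              paste(utils::head(x$labels, 8L), collapse = ", ")))
  invisible(x)
}

#' Build a rectangular polygon feature
#'
#' Convenience constructor used for synthetic region/land masks.
#'
#' @param lon_min,lat_min,lon_max,lat_max rectangle bounds in degrees
#' @param label feature label
#' @return a feature list suitable for [polyset()]
#' @export
rect_feature <- function(lon_min, lat_min, lon_max, lat_max, label = NA) {
  ring <- cbind(
    lon = c(lon_min, lon_max, lon_max, lon_min, lon_min),
    lat = c(lat_min, lat_min, lat_max, lat_max, lat_min))
  list(label = label, rings = list(ring))
}

#' Test point membership in one polyset feature
#'
#' Even-odd rule across the feature's rings; points on a ring boundary count
#' as inside.
#'
#' @param lon,lat numeric vectors of equal length
#' @param feature one element of `polyset$features`
#' @return logical vector
#' @export
point_in_feature <- function(lon, lat, feature) {
  n_in <- integer(length(lon))
  for (r in feature$rings) {
    # pracma::inpolygon treats boundary points as inside
    inside <- pracma::inpolygon(lon, lat, r[, 1L], r[, 2L], boundary = TRUE)
    n_in <- n_in + as.integer(inside)
  }
  n_in %% 2L == 1L
}

#' Locate points within a labelled polygon set
#'
#' @param lon,lat numeric vectors
#' @param polys a [polyset()]
#' @return integer vector of feature indices (`NA` where no feature contains
#'   the point). With `all_matches = TRUE`, a list of index vectors.
#' @param all_matches return every containing feature, not just the first
#' @export
locate_points <- function(lon, lat, polys, all_matches = FALSE) {
  stopifnot(inherits(polys, "polyset"), length(lon) == length(lat))
  hit <- matrix(FALSE, nrow = length(lon), ncol = length(polys))
  for (j in seq_along(polys$features)) {
    hit[, j] <- point_in_feature(lon, lat, polys$features[[j]])
  }
  if (all_matches) {
    return(apply(hit, 1L, which, simplify = FALSE))
  }
  idx <- rep(NA_integer_, length(lon))
  for (i in seq_along(idx)) {
    w <- which(hit[i, ])
    if (length(w)) idx[i] <- w[1L]
  }
  idx
}

seg_intersects <- function(p1, p2, q1, q2) {
  d1 <- (q2[1] - q1[1]) * (p1[2] - q1[2]) - (q2[2] - q1[2]) * (p1[1] - q1[1])
  d2 <- (q2[1] - q1[1]) * (p2[2] - q1[2]) - (q2[2] - q1[2]) * (p2[1] - q1[1])
  d3 <- (p2[1] - p1[1]) * (q1[2] - p1[2]) - (p2[2] - p1[2]) * (q1[1] - p1[1])
  d4 <- (p2[1] - p1[1]) * (q2[2] - p1[2]) - (p2[2] - p1[2]) * (q2[1] - p1[1])
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

#' Does a lon/lat rectangle intersect any feature of a polyset?
#'
#' Exact for simple rings: true if a ring vertex falls in the rectangle, a
#' rectangle corner falls in the feature, or any ring edge crosses a
#' rectangle edge.
#'
#' @param bounds numeric `c(lon_min, lat_min, lon_max, lat_max)`
#' @param polys a [polyset()]
#' @return logical scalar
#' @export
rect_intersects <- function(bounds, polys) {
  if (length(polys) == 0L) return(FALSE)
  cx <- c(bounds[1], bounds[3], bounds[3], bounds[1])
  cy <- c(bounds[2], bounds[2], bounds[4], bounds[4])
  corners <- cbind(c(cx, cx[1]), c(cy, cy[1]))
  for (f in polys$features) {
    if (any(point_in_feature(cx, cy, f))) return(TRUE)
    for (r in f$rings) {
      vin <- r[, 1L] >= bounds[1] & r[, 1L] <= bounds[3] &
        r[, 2L] >= bounds[2] & r[, 2L] <= bounds[4]
      if (any(vin)) return(TRUE)
      for (i in seq_len(nrow(r) - 1L)) {
        for (j in 1:4) {
          if (seg_intersects(r[i, ], r[i + 1L, ],
                             corners[j, ], corners[j + 1L, ])) {
            return(TRUE)
          }
        }
      }
    }
  }
  FALSE
}

#' Read a polygon set from GeoJSON
#'
#' Accepts `FeatureCollection`s of `Polygon` / `MultiPolygon` features; the
#' feature label is taken from the first available of the properties named in
#' `label_keys`.
#'
#' @param path GeoJSON file
#' @param label_keys property names to try, in order, for the feature label
#' @return a [polyset()]
#' @export
read_polygons <- function(path, label_keys = c("label", "name", "region", "country")) {
  if (!file.exists(path)) stop("polygon file not found: ", path)
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection in ", path)
  }
  ring_mat <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("lon", "lat")
    m
  }
  feats <- lapply(gj$features, function(f) {
    label <- NA_character_
    for (k in label_keys) {
      if (!is.null(f$properties[[k]])) { label <- f$properties[[k]]; break }
    }
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(poly) lapply(poly, ring_mat)),
                            recursive = FALSE),
      stop("unsupported geometry type: ", geom$type))
    list(label = label, rings = rings)
  })
  polyset(feats)
}

#' Write a polygon set to GeoJSON
#'
#' @param polys a [polyset()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_polygons <- function(polys, path) {
  stopifnot(inherits(polys, "polyset"))
  feats <- lapply(polys$features, function(f) {
    coords <- lapply(f$rings, function(r) {
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1L], r[i, 2L]))
    })
    list(type = "Feature",
         properties = list(label = f$label),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}
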