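#' Bioclimatic raster stacks
#'
#' A `bioclim_stack` holds co-registered climate layers on one regular
#' lon/lat grid: a named list of numeric matrices (rows top-down, i.e. the
#' first matrix row is the northernmost, as in ESRI ASCII grids) plus the
#' shared extent and pixel size. Layers are exchanged on disk as one ESRI
#' ASCII grid (`.asc`) file per layer — a plain-text raster format that
#' carries its own georeferencing header.
#'
#' @param layers named list of equal-dimension numeric matrices
#' @param extent numeric `c(lon_min, lat_min, lon_max, lat_max)`
#' @return object of class `bioclim_stack`
#' @export
bioclim_stack <- function(layers, extent) {
  stopifnot(is.list(layers), length(layers) >= 1L, length(extent) == 4L)
  d <- dim(layers[[1L]])
  for (l in layers) stopifnot(is.matrix(l), identical(dim(l), d))
  csx <- (extent[3] - extent[1]) / d[2L]
  csy <- (extent[4] - extent[2]) / d[1L]
  if (abs(csx - csy) > 1e-9) stop("pixels must be square in degrees")
  if (is.null(names(layers))) {
    names(layers) <- sprintf("bio%02d", seq_along(layers))
  }
  structure(list(layers = layers, extent = as.numeric(extent),
                 nrows = d[1L], ncols = d[2L], cellsize = csx),
            class = "bioclim_stack")
}

#' @export
print.bioclim_stack <- function(x, ...) {
  cat(sprintf("<bioclim_stack: %d layer(s), %d x %d px at %g deg>\n",
              length(x$layers), x$nrows, x$ncols, x$cellsize))
  invisible(x)
}

#' Read / write a single raster layer as ESRI ASCII grid
#'
#' @param path `.asc` file
#' @return `read_ascii_grid`: list with `values` (matrix, top row = north),
#'   `extent`, `cellsize`, `nodata`
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    parts <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(parts) == 2L && grepl("^[a-zA-Z]", parts[1L])) {
      hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
    } else {
      seek(con, pos)
      break
    }
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("incomplete ASCII grid header in ", path)
  }
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(con, what = numeric(), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid body size mismatch in ", path)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(values = m,
       extent = c(hdr$xllcorner, hdr$yllcorner,
                  hdr$xllcorner + hdr$ncols * hdr$cellsize,
                  hdr$yllcorner + hdr$nrows * hdr$cellsize),
       cellsize = hdr$cellsize, nodata = nodata)
}

#' @rdname read_ascii_grid
#' @param values numeric matrix, top row = north
#' @param extent `c(lon_min, lat_min, lon_max, lat_max)`
#' @param nodata value written for `NA` pixels
#' @export
write_ascii_grid <- function(values, extent, path, nodata = -9999) {
  stopifnot(is.matrix(values))
  hdr <- c(sprintf("ncols %d", ncol(values)),
           sprintf("nrows %d", nrow(values)),
           sprintf("xllcorner %.10g", extent[1]),
           sprintf("yllcorner %.10g", extent[2]),
           sprintf("cellsize %.10g", (extent[3] - extent[1]) / ncol(values)),
           sprintf("NODATA_value %g", nodata))
  body <- apply(values, 1L, function(r) {
    r[is.na(r)] <- nodata
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write a whole stack (one `.asc` per layer)
#'
#' `write_stack` writes `<dir>/<layer name>.asc`; `read_stack` reads every
#' `.asc` in `dir` (sorted by name) and checks they share extent and size.
#'
#' @param dir directory of `.asc` files
#' @return a [bioclim_stack()]
#' @export
read_stack <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(files)) stop("no .asc layers found in ", dir)
  grids <- lapply(files, read_ascii_grid)
  ext <- grids[[1L]]$extent
  for (g in grids) {
    if (max(abs(g$extent - ext)) > 1e-9) stop("layer extents differ in ", dir)
  }
  layers <- lapply(grids, `[[`, "values")
  names(layers) <- sub("\\.asc$", "", basename(files))
  bioclim_stack(layers, ext)
}

#' @rdname read_stack
#' @param stack a [bioclim_stack()]
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "bioclim_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$layers)) {
    write_ascii_grid(stack$layers[[nm]], stack$extent,
                     file.path(dir, paste0(nm, ".asc")))
  }
  invisible(dir)
}

#' Aggregate bioclim layers to the analysis grid
#'
#' Computes, for every land cell of `grid`, the mean of each layer over the
#' pixels whose centres fall inside the cell (half-open cell intervals, the
#' same convention as [assign_cells()]); no-data pixels are ignored. Cells
#' with no valid pixel in any layer are dropped from the matrix and listed in
#' `dropped`. 19 layers are expected (the standard bioclim set); any other
#' count proceeds with a warning.
#'
#' @param stack a [bioclim_stack()]
#' @param grid a [build_grid()] result
#' @return object of class `env_matrix`: list with `values` (cells x layers
#'   matrix, rownames = cell ids), `cell_ids`, `dropped`
#' @export
aggregate_bioclim <- function(stack, grid) {
  stopifnot(inherits(stack, "bioclim_stack"), inherits(grid, "sampcov_grid"))
  if (length(stack$layers) != 19L) {
    warning(sprintf("expected 19 bioclim layers, got %d; proceeding",
                    length(stack$layers)))
  }
  cs <- stack$cellsize
  px_lon <- stack$extent[1] + (seq_len(stack$ncols) - 0.5) * cs
  px_lat <- stack$extent[4] - (seq_len(stack$nrows) - 0.5) * cs
  centers <- data.frame(lon = rep(px_lon, each = stack$nrows),
                        lat = rep(px_lat, times = stack$ncols))
  centers <- assign_cells(centers, grid)
  land_ids <- grid$cells$id[grid$cells$is_land]
  in_cell <- !centers$unassigned & centers$cell_id %in% land_ids
  f <- factor(centers$cell_id[in_cell], levels = land_ids)
  vals <- matrix(NA_real_, nrow = length(land_ids), ncol = length(stack$layers),
                 dimnames = list(land_ids, names(stack$layers)))
  for (j in seq_along(stack$layers)) {
    v <- as.vector(stack$layers[[j]])[in_cell]
    sums <- tapply(v, f, function(x) mean(x, na.rm = TRUE))
    vals[, j] <- as.numeric(sums)
  }
  ok <- rowSums(is.na(vals)) == 0L
  dropped <- land_ids[!ok]
  if (length(dropped)) {
    message(length(dropped), " cell(s) without valid pixels dropped from the environmental matrix")
  }
  structure(list(values = vals[ok, , drop = FALSE],
                 cell_ids = land_ids[ok], dropped = dropped),
            class = "env_matrix")
}
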