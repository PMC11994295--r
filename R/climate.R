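#' Principal components of the environmental matrix
#'
#' Correlation-matrix PCA (columns standardised to mean 0, sd 1 first):
#' the bioclim variables mix units, so covariance PCA would be dominated by
#' the large-valued precipitation layers. Component signs are fixed by
#' making each component's largest-magnitude loading positive, so results
#' are deterministic across platforms.
#'
#' @param env an [aggregate_bioclim()] result, or a plain numeric matrix
#'   with cells as rows
#' @param n_components number of axes to keep in `scores`
#' @return object of class `pca_result`: list with `scores` (cells x
#'   `n_components`, rownames = cell ids), `loadings`, `var_explained`
#'   (all components), `center`, `scale`, `cell_ids`
#' @export
run_pca <- function(env, n_components = 2L) {
  vals <- if (inherits(env, "env_matrix")) env$values else as.matrix(env)
  cell_ids <- if (inherits(env, "env_matrix")) env$cell_ids else
    seq_len(nrow(vals))
  if (nrow(vals) < 3L || ncol(vals) < 2L) {
    stop("PCA needs at least 3 cells and 2 variables")
  }
  sds <- apply(vals, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance variable(s): ",
         paste(colnames(vals)[sds == 0], collapse = ", "))
  }
  p <- stats::prcomp(vals, center = TRUE, scale. = TRUE)
  flip <- apply(p$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  p$rotation <- sweep(p$rotation, 2L, flip, `*`)
  p$x <- sweep(p$x, 2L, flip, `*`)
  ve <- p$sdev^2 / sum(p$sdev^2)
  scores <- p$x[, seq_len(n_components), drop = FALSE]
  rownames(scores) <- cell_ids
  structure(list(scores = scores, loadings = p$rotation,
                 var_explained = ve, center = p$center, scale = p$scale,
                 cell_ids = cell_ids),
            class = "pca_result")
}

#' Project new observations onto fitted components
#'
#' @param pca a [run_pca()] result
#' @param newdata matrix with the same variables as the fit
#' @return score matrix with the same columns as `pca$scores`
#' @export
project_pca <- function(pca, newdata) {
  z <- sweep(sweep(as.matrix(newdata), 2L, pca$center), 2L, pca$scale, `/`)
  (z %*% pca$loadings)[, seq_len(ncol(pca$scores)), drop = FALSE]
}

#' Bin the 2-D climate space into climate types
#'
#' Splits the observed PC1 and PC2 ranges into `n_bins_per_axis` equal-width
#' intervals each (half-open, last interval closed above), giving up to
#' `n_bins_per_axis^2` equal-area bins of score space. Each occupied bin is
#' one "climate type". A degenerate axis (all scores equal) collapses to a
#' single bin on that axis.
#'
#' @param pca a [run_pca()] result (uses the first two score columns)
#' @param n_bins_per_axis bins per axis
#' @return object of class `climate_typing`: list with `cell_types`
#'   (data.frame: `cell_id`, `pc1`, `pc2`, `bin1`, `bin2`, `type_id`),
#'   `type_table` (data.frame: `type_id`, `frequency`, `rarity` once
#'   scored), `bin_edges` (list `pc1`, `pc2`), `n_bins_per_axis`
#' @export
bin_climate_space <- function(pca, n_bins_per_axis = 6L) {
  stopifnot(inherits(pca, "pca_result"), ncol(pca$scores) >= 2L)
  s1 <- pca$scores[, 1L]
  s2 <- pca$scores[, 2L]
  if (any(!is.finite(s1)) || any(!is.finite(s2))) stop("non-finite PC scores")
  edges <- function(x) {
    if (max(x) == min(x)) return(c(min(x), min(x)))  # degenerate: one bin
    seq(min(x), max(x), length.out = n_bins_per_axis + 1L)
  }
  e1 <- edges(s1); e2 <- edges(s2)
  bin_of <- function(x, e) {
    if (length(e) == 2L && e[1L] == e[2L]) return(rep(1L, length(x)))
    b <- findInterval(x, e, rightmost.closed = TRUE, left.open = FALSE)
    pmin(pmax(b, 1L), length(e) - 1L)
  }
  b1 <- bin_of(s1, e1); b2 <- bin_of(s2, e2)
  type_id <- paste(b1, b2, sep = "-")
  cell_types <- data.frame(cell_id = pca$cell_ids, pc1 = s1, pc2 = s2,
                           bin1 = b1, bin2 = b2, type_id = type_id,
                           row.names = NULL)
  freq <- table(type_id)
  type_table <- data.frame(type_id = names(freq),
                           frequency = as.integer(freq),
                           rarity = NA_real_, row.names = NULL)
  structure(list(cell_types = cell_types, type_table = type_table,
                 bin_edges = list(pc1 = e1, pc2 = e2),
                 n_bins_per_axis = n_bins_per_axis),
            class = "climate_typing")
}

#' @export
print.climate_typing <- function(x, ...) {
  cat(sprintf("<climate_typing: %d cell(s) in %d occupied type(s) (%d x %d bins)>\n",
              nrow(x$cell_types), nrow(x$type_table),
              x$n_bins_per_axis, x$n_bins_per_axis))
  invisible(x)
}

#' Min-max climate-rarity scores
#'
#' Assigns each occupied climate type a rarity in [0, 1] by min-max scaling
#' its inverse frequency: the most frequent type scores 0 (common), the
#' least frequent 1 (rare). If all frequencies are equal every type scores
#' 0.
#'
#' @param typing a [bin_climate_space()] result
#' @return `typing` with `type_table$rarity` filled in and a
#'   `cell_types$rarity` column added
#' @export
rarity_scores <- function(typing) {
  stopifnot(inherits(typing, "climate_typing"))
  f <- typing$type_table$frequency
  rng <- max(f) - min(f)
  typing$type_table$rarity <- if (rng == 0) rep(0, length(f)) else
    (max(f) - f) / rng
  idx <- match(typing$cell_types$type_id, typing$type_table$type_id)
  typing$cell_types$frequency <- typing$type_table$frequency[idx]
  typing$cell_types$rarity <- typing$type_table$rarity[idx]
  typing
}

#' Climate-type distribution of a set of cells
#'
#' Relative frequency of each climate type among `cell_ids`, over the full
#' set of the typing's occupied types (types absent from the subset get 0).
#' Cells are counted with multiplicity, so passing one cell id per
#' occurrence record gives the record-weighted distribution.
#'
#' @param typing a [bin_climate_space()] result
#' @param cell_ids cell ids (with repeats allowed); `NULL` = all typed cells
#' @return named numeric vector over `typing$type_table$type_id`, summing
#'   to 1
#' @export
type_distribution <- function(typing, cell_ids = NULL) {
  stopifnot(inherits(typing, "climate_typing"))
  types <- typing$type_table$type_id
  if (is.null(cell_ids)) {
    p <- typing$type_table$frequency
  } else {
    t_of <- typing$cell_types$type_id[match(cell_ids,
                                            typing$cell_types$cell_id)]
    t_of <- t_of[!is.na(t_of)]
    if (!length(t_of)) stop("none of the cell_ids are typed")
    p <- as.integer(table(factor(t_of, levels = types)))
  }
  stats::setNames(p / sum(p), types)
}
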