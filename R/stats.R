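#' Schoener's D niche overlap
#'
#' D = 1 - 0.5 * sum_i |p_i - q_i| between two discrete distributions over
#' the same support (here: climate types). 0 means disjoint support, 1
#' identical distributions. Inputs must each sum to 1; nothing is silently
#' renormalised.
#'
#' @param p,q non-negative numeric vectors of equal length summing to 1. If
#'   both are named, `q` is aligned to `p`'s names (a name missing from one
#'   vector counts as probability 0 there).
#' @param tol tolerance for the sum-to-one check
#' @return numeric scalar in [0, 1]
#' @export
schoener_d <- function(p, q, tol = 1e-8) {
  if (!is.null(names(p)) && !is.null(names(q))) {
    support <- union(names(p), names(q))
    p <- stats::setNames(ifelse(support %in% names(p), p[support], 0), support)
    q <- stats::setNames(ifelse(support %in% names(q), q[support], 0), support)
  }
  if (length(p) != length(q)) stop("p and q must share a support")
  if (any(p < 0) || any(q < 0)) stop("negative probabilities")
  if (abs(sum(p) - 1) > tol || abs(sum(q) - 1) > tol) {
    stop("p and q must each sum to 1 (no silent renormalisation)")
  }
  1 - 0.5 * sum(abs(p - q))
}

#' Resampling null test for niche overlap
#'
#' Compares the observed overlap between a record set's climate-type
#' distribution and the study area's against a null built by repeatedly
#' drawing `n_draw` occurrence records at random (without replacement, by
#' default) from the full occurrence pool and computing the same overlap.
#' The one-sided p-value, with add-one correction, is the probability that a
#' random draw covers climate space at least as well as the observed set:
#' p = (1 + #\{D_null >= D_obs\}) / (1 + n_iter). An observed overlap below
#' every null draw therefore reports p = 1 (the set covers climate space
#' *worse* than random).
#'
#' @param occurrence_cells cell ids of the full occurrence pool (one entry
#'   per record)
#' @param observed_cells cell ids whose overlap with the study area is the
#'   observed statistic (e.g. the well-sampled cells)
#' @param typing a [bin_climate_space()] result for the study area
#' @param n_draw records per null draw (conventionally as many occurrences
#'   as there are well-sampled cells)
#' @param n_iter number of null draws
#' @param seed RNG seed
#' @param replace sample records with replacement instead
#' @return object of class `overlap_result`: list with `D_obs`,
#'   `null_draws`, `p_value`, `n_draw`, `n_iter`, `seed`
#' @export
null_overlap_test <- function(occurrence_cells, observed_cells, typing,
                              n_draw, n_iter = 1000L, seed = 1L,
                              replace = FALSE) {
  occurrence_cells <- occurrence_cells[!is.na(occurrence_cells)]
  if (!replace && n_draw > length(occurrence_cells)) {
    stop("n_draw exceeds the number of available occurrence records")
  }
  realm <- type_distribution(typing)
  d_obs <- schoener_d(type_distribution(typing, observed_cells), realm)
  rng <- local_rng(seed)
  draws <- vapply(seq_len(n_iter), function(i) {
    cells <- sample(occurrence_cells, n_draw, replace = replace)
    schoener_d(type_distribution(typing, cells), realm)
  }, numeric(1L))
  restore_rng(rng)
  p <- (1 + sum(draws >= d_obs)) / (1 + n_iter)
  structure(list(D_obs = d_obs, null_draws = draws, p_value = p,
                 n_draw = n_draw, n_iter = n_iter, seed = seed),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap: D_obs=%.3f p=%.4g (n_draw=%d, n_iter=%d)>\n",
              x$D_obs, x$p_value, x$n_draw, x$n_iter))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D statistic = sup |ECDF_a - ECDF_b|, p-value from the asymptotic
#' two-sample distribution.
#'
#' @param sample_a,sample_b numeric vectors (each of length >= 2)
#' @return list with `D_stat` and `p_value`
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("both samples need at least 2 observations")
  }
  res <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(D_stat = unname(res$statistic), p_value = unname(res$p.value))
}

#' Gaussian kernel density profile
#'
#' Evaluates a Gaussian kernel density estimate at arbitrary grid points,
#' with Silverman's rule-of-thumb bandwidth by default — the smoothed
#' profiles used to compare the climate-score distribution of well-sampled
#' cells against all cells on a shared axis.
#'
#' @param values observations (>= 2 distinct values unless `bandwidth`
#'   given)
#' @param eval_grid points at which to evaluate the density
#' @param bandwidth kernel sd; default `stats::bw.nrd0(values)`
#' @return data.frame with `x` (= `eval_grid`) and `density`
#' @export
kde_profile <- function(values, eval_grid, bandwidth = NULL) {
  values <- values[!is.na(values)]
  if (is.null(bandwidth)) {
    if (length(unique(values)) < 2L) {
      stop("all values identical: supply an explicit bandwidth")
    }
    bandwidth <- stats::bw.nrd0(values)
  }
  dens <- vapply(eval_grid, function(x0) {
    mean(stats::dnorm((x0 - values) / bandwidth)) / bandwidth
  }, numeric(1L))
  data.frame(x = eval_grid, density = dens)
}

round_half_up <- function(x, digits = 0) {
  # print-style rounding (0.5 away from zero), matching reported tables
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Coverage summary with reporting conventions
#'
#' Turns raw counts into the percentages used in coverage reports:
#' cell and climate-type coverage to two decimals, dataset contribution
#' shares to one decimal, and an integer-rounded variant of every
#' percentage. All raw counts are retained, and every percentage recomputes
#' exactly from its counts.
#'
#' @param counts named list; recognised pairs (numerator/denominator):
#'   `computable_cells`/`total_cells`, `ws_cells`/`total_cells`,
#'   `occupied_types`/`possible_types`, `set_entries`/`total_entries`,
#'   `set_specimens`/`total_specimens`. Only supplied pairs are summarised.
#' @return object of class `coverage_summary`: list of the input counts
#'   plus, per pair, `<name>_pct` (2 dp for cells/types, 1 dp for
#'   contributions) and `<name>_pct_int`
#' @export
summarize_coverage <- function(counts) {
  pairs <- list(
    computable_cells = c("computable_cells", "total_cells", 2),
    ws_cells = c("ws_cells", "total_cells", 2),
    occupied_types = c("occupied_types", "possible_types", 2),
    set_entries = c("set_entries", "total_entries", 1),
    set_specimens = c("set_specimens", "total_specimens", 1))
  out <- counts
  for (nm in names(pairs)) {
    num_key <- pairs[[nm]][1L]; den_key <- pairs[[nm]][2L]
    digits <- as.integer(pairs[[nm]][3L])
    if (is.null(counts[[num_key]]) || is.null(counts[[den_key]])) next
    den <- counts[[den_key]]
    if (den == 0) stop("zero denominator for ", nm)
    pct <- 100 * counts[[num_key]] / den
    out[[paste0(nm, "_pct")]] <- round_half_up(pct, digits)
    out[[paste0(nm, "_pct_int")]] <- round_half_up(pct, 0)
  }
  structure(out, class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
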