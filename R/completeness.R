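#' Species accumulation curve for one grid cell
#'
#' Expected cumulative species count as a function of the number of records
#' examined, averaged over random orderings of the records. The effort unit
#' is the database record (table row). With `n <= exhaustive_max` records the
#' average is taken exactly over all `n!` orderings; otherwise over `n_perm`
#' seeded random permutations. The last point always equals the observed
#' richness.
#'
#' @param species character vector, one entry per record in the cell
#' @param n_perm number of random orderings (ignored when exhaustive)
#' @param seed RNG seed for the permutations
#' @param exhaustive_max use exact enumeration up to this many records
#' @return object of class `accum_curve`: data.frame with `n_records` (1..N)
#'   and `expected_richness`
#' @export
accumulation_curve <- function(species, n_perm = 200L, seed = 1L,
                               exhaustive_max = 6L) {
  species <- species[!is.na(species)]
  n <- length(species)
  if (n == 0L) stop("cannot build an accumulation curve for an empty cell")
  code <- as.integer(factor(species))
  if (n <= exhaustive_max) {
    perms <- pracma::perms(seq_len(n))
    acc <- rowMeans(apply(perms, 1L, function(ord) cummax_distinct(code[ord])))
  } else {
    rng <- local_rng(seed)
    tot <- numeric(n)
    for (k in seq_len(n_perm)) {
      ord <- sample.int(n)
      tot <- tot + cummax_distinct(code[ord])
    }
    restore_rng(rng)
    acc <- tot / n_perm
  }
  structure(data.frame(n_records = seq_len(n), expected_richness = acc),
            class = c("accum_curve", "data.frame"))
}

# cumulative number of distinct codes seen along a sequence
cummax_distinct <- function(code) {
  cumsum(!duplicated(code))
}

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible()
}

#' Fit the Clench (Michaelis-Menten) model to an accumulation curve
#'
#' Fits S(n) = a n / (1 + b n) by nonlinear least squares
#' (Levenberg-Marquardt), starting from the linearised regression of n/S on
#' n (intercept 1/a, slope b/a). The estimated total richness is the
#' asymptote a/b. The asymptote can fall below the observed richness on
#' concave-down-enough data; that case is flagged downstream, not hidden.
#'
#' @param curve an [accumulation_curve()] result (or data.frame with
#'   `n_records`, `expected_richness`)
#' @return object of class `clench_fit`: list with `a`, `b`, `asymptote`,
#'   `converged`, `rss`
#' @export
fit_clench <- function(curve) {
  n <- curve$n_records
  s <- curve$expected_richness
  if (length(unique(n)) < 3L) {
    stop("Clench fit needs at least 3 distinct effort levels")
  }
  lin <- stats::lm(I(n / s) ~ n)
  a0 <- 1 / max(stats::coef(lin)[1L], 1e-8)
  b0 <- max(stats::coef(lin)[2L] * a0, 1e-8)
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ a * n / (1 + b * n),
                      start = list(a = a0, b = b0),
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(a = NA_real_, b = NA_real_, asymptote = NA_real_,
                          converged = FALSE, rss = NA_real_),
                     class = "clench_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 asymptote = unname(cf["a"] / cf["b"]),
                 converged = fit$convInfo$isConv %||% TRUE,
                 rss = sum(stats::resid(fit)^2)),
            class = "clench_fit")
}

#' @export
print.clench_fit <- function(x, ...) {
  cat(sprintf("<clench_fit: a=%.4g b=%.4g asymptote=%.4g converged=%s>\n",
              x$a, x$b, x$asymptote, x$converged))
  invisible(x)
}

#' Per-cell inventory completeness
#'
#' Completeness is 100 * S_obs / asymptote: the share of the species
#' predicted for the cell that have actually been recorded. When the fitted
#' asymptote falls below S_obs the percentage is clamped to 100 and the
#' `clamped` flag set. Cells whose fit did not converge are not computable.
#'
#' @param species character vector of the cell's record identifications
#' @param fit a [fit_clench()] result for the cell's curve
#' @param cell_id identifier carried through to the output
#' @return one-row data.frame: `cell_id`, `n_records`, `S_obs`, `ratio`,
#'   `a`, `b`, `asymptote`, `completeness_pct`, `clamped`, `computable`
#' @export
cell_completeness <- function(species, fit, cell_id = NA_integer_) {
  species <- species[!is.na(species)]
  n <- length(species)
  s_obs <- length(unique(species))
  out <- data.frame(cell_id = cell_id, n_records = n, S_obs = s_obs,
                    ratio = n / s_obs, a = fit$a, b = fit$b,
                    asymptote = fit$asymptote,
                    completeness_pct = NA_real_, clamped = FALSE,
                    computable = isTRUE(fit$converged))
  if (!out$computable) return(out)
  pct <- 100 * s_obs / fit$asymptote
  if (pct > 100) {
    pct <- 100
    out$clamped <- TRUE
  }
  out$completeness_pct <- pct
  out
}

#' Well-sampled classification
#'
#' A computable cell is well-sampled iff it has more than
#' `thresholds$records` records, completeness above `thresholds$pct`
#' percent, and a records-to-species ratio above `thresholds$ratio` — all
#' three strict inequalities.
#'
#' @param cc a [cell_completeness()] row (or data.frame of them)
#' @param thresholds list with `records`, `pct`, `ratio`
#' @return logical vector
#' @export
classify_well_sampled <- function(cc, thresholds = list(records = 20, pct = 75,
                                                        ratio = 5)) {
  cc$computable & !is.na(cc$completeness_pct) &
    cc$n_records > thresholds$records &
    cc$completeness_pct > thresholds$pct &
    cc$ratio > thresholds$ratio
}

#' Completeness table for a whole occurrence set
#'
#' Runs curve construction, Clench fitting, completeness and well-sampled
#' classification for every grid cell with records. Cells with fewer than 3
#' records (too few effort levels for the fit) or with a non-converged fit
#' are reported with `computable = FALSE`. Deterministic given `seed`: cell
#' `i` uses seed `seed + cell_id` for its permutations.
#'
#' @param records occurrence data.frame with `cell_id` and `species`
#' @param n_perm permutations per accumulation curve
#' @param seed base RNG seed
#' @param thresholds passed to [classify_well_sampled()]
#' @return data.frame, one row per occupied cell, with the
#'   [cell_completeness()] columns plus `well_sampled`
#' @export
completeness_table <- function(records, n_perm = 200L, seed = 1L,
                               thresholds = list(records = 20, pct = 75,
                                                 ratio = 5)) {
  records <- records[!is.na(records$cell_id) & !is.na(records$species), ]
  ids <- sort(unique(records$cell_id))
  rows <- lapply(ids, function(cid) {
    sp <- records$species[records$cell_id == cid]
    if (length(sp) < 3L || length(unique(sp)) < 1L) {
      fit <- structure(list(a = NA_real_, b = NA_real_, asymptote = NA_real_,
                            converged = FALSE, rss = NA_real_),
                       class = "clench_fit")
      return(cell_completeness(sp, fit, cell_id = cid))
    }
    curve <- accumulation_curve(sp, n_perm = n_perm,
                                seed = (seed + cid) %% .Machine$integer.max)
    fit <- fit_clench(curve)
    cell_completeness(sp, fit, cell_id = cid)
  })
  out <- do.call(rbind, rows)
  out$well_sampled <- classify_well_sampled(out, thresholds)
  out
}
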