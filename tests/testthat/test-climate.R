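test_that("ASCII grid layers round-trip and stacks validate extents", {
  m <- matrix(runif(12), nrow = 3)
  m[2, 2] <- NA
  path <- tempfile(fileext = ".asc")
  write_ascii_grid(m, c(0, 0, 4, 3), path)
  back <- read_ascii_grid(path)
  expect_equal(back$values, m, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$extent, c(0, 0, 4, 3))

  dir <- tempfile(); dir.create(dir)
  st <- bioclim_stack(list(a = matrix(1, 2, 2), b = matrix(2, 2, 2)),
                      c(0, 0, 2, 2))
  write_stack(st, dir)
  back <- read_stack(dir)
  expect_equal(names(back$layers), c("a", "b"))
  expect_equal(back$layers$b, st$layers$b, tolerance = 1e-9)
})

test_that("aggregate_bioclim means pixels per cell and drops no-data cells", {
  # 4x4 pixels over a 2x2-cell grid: each cell holds a 2x2 pixel block
  vals <- matrix(0, 4, 4)
  vals[3:4, 1:2] <- matrix(c(1, 3, 2, 4), 2)  # SW cell pixels 1..4
  const <- matrix(7, 4, 4)
  nodata <- matrix(NA_real_, 4, 4)
  nodata[1:2, 3:4] <- NA  # NE cell all missing
  nodata[3:4, 1:2] <- 5; nodata[1:2, 1:2] <- 5; nodata[3:4, 3:4] <- 5
  st <- bioclim_stack(list(v = vals, c7 = const, nd = nodata), c(0, 0, 2, 2))
  g <- build_grid(c(0, 0, 2, 2), 1)
  expect_warning(env <- aggregate_bioclim(st, g), "19")
  # NE cell (id 4) dropped: no valid pixel in layer nd
  expect_setequal(env$cell_ids, c(1L, 2L, 3L))
  expect_equal(env$dropped, 4L)
  expect_equal(env$values[as.character(1), "v"], 2.5, ignore_attr = TRUE)
  expect_true(all(env$values[, "c7"] == 7))
})

test_that("PCA is deterministic, ordered, and reconstructs the input", {
  set.seed(10)
  f1 <- rnorm(60); f2 <- rnorm(60)
  mat <- cbind(a = f1, b = 2 * f1 + 0.1 * rnorm(60), c = f2,
               d = f2 - f1, e = rnorm(60))
  p <- run_pca(mat, n_components = 2)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-12)
  expect_lt(max(abs(colMeans(p$scores))), 1e-10)
  # sign convention: largest loading of each component positive
  for (j in 1:2) {
    v <- p$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  # full reconstruction of the standardised matrix
  z <- scale(mat)
  full <- run_pca(mat, n_components = ncol(mat))
  recon <- full$scores %*% t(full$loadings)
  expect_lt(max(abs(recon - z)), 1e-8)
  expect_error(run_pca(cbind(a = rep(1, 10), b = rnorm(10))), "zero-variance")
})

test_that("perfectly collinear two-variable data loads PC1 with all variance", {
  x <- rnorm(30)
  p <- run_pca(cbind(a = x, b = -2 * x))
  expect_equal(p$var_explained[1], 1, tolerance = 1e-12)
})

test_that("climate-space binning: corners, ties, degenerate axes", {
  fake_pca <- function(s1, s2) {
    structure(list(scores = cbind(PC1 = s1, PC2 = s2),
                   cell_ids = seq_along(s1)), class = "pca_result")
  }
  p <- fake_pca(c(0, 0, 1, 1), c(0, 1, 0, 1))
  ty <- bin_climate_space(p, n_bins_per_axis = 2)
  expect_equal(nrow(ty$type_table), 4L)
  expect_true(all(ty$type_table$frequency == 1L))

  # all points identical -> a single occupied type
  ty2 <- bin_climate_space(fake_pca(rep(2, 5), rep(3, 5)), 4)
  expect_equal(nrow(ty2$type_table), 1L)

  # interior edge goes to the higher bin (half-open intervals)
  ty3 <- bin_climate_space(fake_pca(c(0, 0.5, 1), c(0, 0, 0)), 2)
  expect_equal(ty3$cell_types$bin1, c(1L, 2L, 2L))

  # conservation: frequencies sum to the number of typed cells
  set.seed(3)
  ty4 <- bin_climate_space(fake_pca(rnorm(200), rnorm(200)), 6)
  expect_equal(sum(ty4$type_table$frequency), 200L)

  # binning is invariant to positive rescaling of both axes
  s1 <- rnorm(50); s2 <- rnorm(50)
  a <- bin_climate_space(fake_pca(s1, s2), 5)
  b <- bin_climate_space(fake_pca(s1 * 7, s2 * 7), 5)
  expect_equal(a$cell_types$type_id, b$cell_types$type_id)
})

test_that("rarity is a min-max scale of inverse frequency", {
  fake_typing <- function(freqs) {
    ids <- paste0("t", seq_along(freqs))
    structure(list(
      cell_types = data.frame(cell_id = seq_len(sum(freqs)),
                              type_id = rep(ids, freqs)),
      type_table = data.frame(type_id = ids, frequency = freqs,
                              rarity = NA_real_)),
      class = "climate_typing")
  }
  ty <- rarity_scores(fake_typing(c(10L, 5L, 1L)))
  expect_equal(ty$type_table$rarity, c(0, 5 / 9, 1))
  expect_equal(rarity_scores(fake_typing(c(4L, 4L, 4L)))$type_table$rarity,
               rep(0, 3))
  expect_equal(rarity_scores(fake_typing(7L))$type_table$rarity, 0)
  # antitone in frequency
  ty2 <- rarity_scores(fake_typing(c(9L, 3L, 6L, 1L)))
  o <- order(ty2$type_table$frequency, decreasing = TRUE)
  expect_true(all(diff(ty2$type_table$rarity[o]) >= 0))
})

test_that("type_distribution spans all occupied types and sums to one", {
  fake_pca <- structure(list(scores = cbind(PC1 = c(0, 1, 2, 3),
                                            PC2 = c(0, 0, 1, 1)),
                             cell_ids = 1:4), class = "pca_result")
  ty <- bin_climate_space(fake_pca, 2)
  p_all <- type_distribution(ty)
  expect_equal(sum(p_all), 1)
  p_sub <- type_distribution(ty, cell_ids = c(1L, 1L, 2L))
  expect_equal(sum(p_sub), 1)
  expect_equal(length(p_sub), nrow(ty$type_table))
  expect_error(type_distribution(ty, cell_ids = 999L), "typed")
})
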