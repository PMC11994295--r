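test_that("accumulation curve matches the rarefaction closed form exactly when exhaustive", {
  # 4 records, 2 species (2 + 2): expected curve 1, 5/3, 2, 2
  sp <- c("a", "a", "b", "b")
  curve <- accumulation_curve(sp)
  expect_equal(curve$expected_richness, c(1, 5/3, 2, 2))
  expect_equal(curve$expected_richness, rarefaction_oracle(sp))

  # random compositions with <= 6 records
  set.seed(21)
  for (i in 1:20) {
    sp <- sample(letters[1:4], sample(2:6, 1), replace = TRUE)
    curve <- accumulation_curve(sp)
    expect_equal(curve$expected_richness, rarefaction_oracle(sp),
                 tolerance = 1e-12)
  }
})

test_that("accumulation curve properties: flat, monotone, ends at S_obs", {
  flat <- accumulation_curve(rep("a", 5))
  expect_equal(flat$expected_richness, rep(1, 5))

  set.seed(33)
  sp <- sample(paste("sp", 1:8), 40, replace = TRUE)
  curve <- accumulation_curve(sp, n_perm = 50, seed = 2)
  expect_true(all(diff(curve$expected_richness) >= 0))
  expect_equal(curve$expected_richness[40], length(unique(sp)))
  expect_true(curve$expected_richness[1] >= 1)
  # Monte-Carlo mean close to the exact rarefaction expectation
  expect_equal(curve$expected_richness, rarefaction_oracle(sp),
               tolerance = 0.05)
  # seeded reproducibility
  again <- accumulation_curve(sp, n_perm = 50, seed = 2)
  expect_identical(curve, again)
  expect_error(accumulation_curve(character()), "empty")
})

test_that("adding a record of a new species never lowers the curve end", {
  set.seed(7)
  sp <- sample(c("a", "b", "c"), 12, replace = TRUE)
  base <- accumulation_curve(sp, n_perm = 30, seed = 1)
  grown <- accumulation_curve(c(sp, "zz_new"), n_perm = 30, seed = 1)
  expect_gte(utils::tail(grown$expected_richness, 1),
             utils::tail(base$expected_richness, 1))
})

test_that("Clench fit recovers noiseless parameters and the asymptote identity", {
  n <- 1:50
  curve <- data.frame(n_records = n, expected_richness = 2 * n / (1 + 0.1 * n))
  fit <- fit_clench(curve)
  expect_true(fit$converged)
  expect_equal(fit$a, 2, tolerance = 1e-4)
  expect_equal(fit$b, 0.1, tolerance = 1e-4)
  expect_equal(fit$asymptote, fit$a / fit$b)
  expect_error(fit_clench(curve[1:2, ]), "3 distinct")
})

test_that("completeness percentage follows definition and clamps at 100", {
  fit <- structure(list(a = 1, b = 0.1, asymptote = 10, converged = TRUE,
                        rss = 0), class = "clench_fit")
  cc <- cell_completeness(rep(letters[1:8], 2), fit, cell_id = 3L)
  expect_equal(cc$completeness_pct, 80)
  expect_equal(cc$ratio, 2)
  expect_false(cc$clamped)

  fit$asymptote <- 9.5
  cc2 <- cell_completeness(c(letters[1:10]), fit)
  expect_equal(cc2$completeness_pct, 100)
  expect_true(cc2$clamped)

  fit$converged <- FALSE
  cc3 <- cell_completeness(letters[1:5], fit)
  expect_false(cc3$computable)
  expect_true(is.na(cc3$completeness_pct))
})

test_that("well-sampled classification uses strict thresholds", {
  row <- function(n, pct, ratio) {
    data.frame(n_records = n, completeness_pct = pct, ratio = ratio,
               computable = TRUE)
  }
  expect_true(classify_well_sampled(row(21, 76, 5.1)))
  expect_false(classify_well_sampled(row(20, 99, 10)))   # records not > 20
  expect_false(classify_well_sampled(row(100, 75, 8)))   # pct not > 75
  expect_false(classify_well_sampled(row(100, 99, 5)))   # ratio not > 5
})

test_that("densely sampled cells approach full completeness", {
  # sample a 12-species pool until every species is seen several times
  set.seed(91)
  ab <- random_simplex(12)
  sp <- sample(paste("sp", 1:12), 400, replace = TRUE, prob = ab)
  curve <- accumulation_curve(sp, n_perm = 100, seed = 4)
  fit <- fit_clench(curve)
  cc <- cell_completeness(sp, fit)
  expect_true(cc$computable)
  expect_gte(cc$completeness_pct, 90)
})

test_that("completeness_table is deterministic and flags tiny cells", {
  set.seed(55)
  recs <- data.frame(
    cell_id = c(rep(1L, 30), rep(2L, 2), rep(3L, 8)),
    species = c(sample(paste("sp", 1:5), 30, replace = TRUE),
                c("sp a", "sp b"),
                sample(paste("sp", 1:4), 8, replace = TRUE)))
  t1 <- completeness_table(recs, n_perm = 50, seed = 9)
  t2 <- completeness_table(recs, n_perm = 50, seed = 9)
  expect_identical(t1, t2)
  expect_false(t1$computable[t1$cell_id == 2])  # < 3 records
  expect_true(all(t1$ratio >= 1))
})
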