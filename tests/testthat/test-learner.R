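test_that("feature assembly freezes IQMs + age + sex + vROI column order", {
  sim <- small_sim(seed = 41, n_iqms = 10)
  tab <- compute_relative_volumes(sim$cohort)
  F1 <- assemble_features(tab, rois = roi_names(tab)[1])
  expect_equal(ncol(F1), 10 + 2 + 1)
  expect_equal(tail(colnames(F1), 3), c("age", "sex",
                                        paste0("vROI.", roi_names(tab)[1])))
  expect_error(assemble_features(tab, iqms = c("iqm01", "nope")), "nope")

  tab2 <- tab
  tab2$iqm01 <- 1
  expect_warning(assemble_features(tab2, rois = roi_names(tab)[1]), "constant")
})

test_that("component basis retains the minimal k for the variance threshold", {
  set.seed(42)
  # variance confined to a 2-D subspace plus tiny jitter
  n <- 200
  basis_vec <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:2]
  X <- matrix(rnorm(n * 2), n, 2) %*% t(basis_vec) +
    matrix(rnorm(n * 6, 0, 1e-6), n, 6)
  b <- fit_component_basis(X, 0.99)
  expect_equal(b$k, 2L)

  # 10 independent equal-variance columns: 9 explain only ~90%
  Y <- matrix(rnorm(5000 * 10), 5000, 10)
  b2 <- fit_component_basis(Y, 0.99)
  expect_equal(b2$k, 10L)
  expect_equal(fit_component_basis(Y, 1.0)$k, 10L)
  expect_error(fit_component_basis(Y, 1.5), "threshold")

  # back-projection loses at most (1 - threshold) of the total variance
  b3 <- fit_component_basis(X, 0.95)
  std <- sweep(sweep(X, 2, b3$center), 2, b3$scale, "/")
  recon <- project_basis(b3, X) %*% t(b3$rotation)
  lost <- sum((std - recon)^2) / sum(sweep(std, 2, colMeans(std))^2)
  expect_lte(lost, 0.05 + 1e-8)
})

test_that("LOSO folds merge small scanners and cap the largest", {
  scanners <- rep(c("W", "X", "Y", "Z"), c(200, 40, 25, 20))
  fl <- loso_folds(scanners, merge_below = 30)
  expect_setequal(unique(fl$fold), c("W", "X", ".merged"))
  expect_equal(sum(fl$use[scanners == "W"]), 40L)  # capped to second largest
  expect_true(all(fl$use[scanners != "W"]))

  set.seed(1)
  fl2 <- loso_folds(rep(c("A", "B"), c(1000, 60)), merge_below = 30)
  expect_equal(sum(fl2$use[rep(c("A", "B"), c(1000, 60)) == "A"]), 60L)

  # reproducible under the same seed
  set.seed(5); a <- loso_folds(scanners, 30)
  set.seed(5); b <- loso_folds(scanners, 30)
  expect_identical(a, b)
})

test_that("loso_search scores the grid per ROI with deterministic tie-break", {
  sim <- small_sim(seed = 43, n_scanners = 4, n_per = 20, n_rois = 3)
  tab <- sim$cohort
  sh <- stepwise_harmonize(tab, steps = "scanner")
  grid <- data.frame(num_trees = c(20L, 20L), max_depth = c(0L, 0L),
                     min_leaf = c(2L, 2L))  # identical rows force a tie
  res <- loso_search(tab, sh$corrections, grid = grid, merge_below = 5L,
                     seed = 44)
  expect_equal(nrow(res$choices), 3L)
  expect_true(all(rownames(res$choices) == roi_names(tab)))
  expect_equal(nrow(res$cv_report), 4 * 2 * 3)  # folds x grid x ROIs
  # the search is reproducible under a fixed seed
  res2 <- loso_search(tab, sh$corrections, grid = grid, merge_below = 5L,
                      seed = 44)
  expect_identical(res$choices, res2$choices)
  expect_identical(res$cv_report, res2$cv_report)
  expect_error(loso_search(tab, sh$corrections, grid = grid[0, ]), "empty")
  two <- tab[tab$scanner %in% unique(tab$scanner)[1:2], ]
  expect_error(loso_search(two, NULL), "3 scanners")
})

test_that("training is deterministic and handles degenerate targets", {
  sim <- small_sim(seed = 45, n_scanners = 4, n_per = 20, n_rois = 3)
  tab <- sim$cohort
  sh <- stepwise_harmonize(tab, steps = "scanner")
  m1 <- harmony_train(tab, sh$corrections, seed = 7,
                      hyper = list(num_trees = 30L, max_depth = 0L, min_leaf = 2L))
  m2 <- harmony_train(tab, sh$corrections, seed = 7,
                      hyper = list(num_trees = 30L, max_depth = 0L, min_leaf = 2L))
  expect_identical(predict_corrections(m1, tab)$cumulative,
                   predict_corrections(m2, tab)$cumulative)

  # all-zero corrections -> constant (zero) predictions
  zero <- sh$corrections
  zero$cumulative[] <- 0
  expect_warning(harmony_train(tab, zero, rois = roi_names(tab)[1], seed = 7),
                 "zero-variance")
  m0 <- suppressWarnings(harmony_train(tab, zero, seed = 7))
  p0 <- predict_corrections(m0, tab)
  expect_lt(max(abs(p0$cumulative)),
            1e-3 * min(apply(relvol_matrix(tab), 2, sd)))
})

test_that("apply adds predicted corrections exactly and flags out-of-range", {
  sim <- small_sim(seed = 46, n_scanners = 4, n_per = 20, n_rois = 3)
  tab <- sim$cohort
  sh <- stepwise_harmonize(tab, steps = "scanner")
  model <- harmony_train(tab, sh$corrections, seed = 8,
                         hyper = list(num_trees = 30L, max_depth = 0L,
                                      min_leaf = 2L))
  res <- harmony_apply(model, tab)
  expect_equal(relvol_matrix(res$table) - relvol_matrix(tab),
               res$corrections$cumulative, tolerance = 1e-12)
  expect_equal(nrow(res$range_flags), 0L)

  # a single subject from an unknown scanner is a valid input
  one <- tab[5, ]
  one$scanner <- "UNKNOWN"
  out1 <- harmony_apply(model, one)
  expect_equal(nrow(relvol_matrix(out1$table)), 1L)

  # out-of-range IQM: flagged (with a warning) but still predicted
  far <- tab[3, ]
  far$iqm01 <- max(tab$iqm01) + 10
  expect_warning(out2 <- harmony_apply(model, far), "training range")
  expect_equal(out2$range_flags$feature, "iqm01")
  expect_true(is.finite(out2$corrections$cumulative[1, 1]))
})

# (the full out-of-scanner recovery experiment lives in test-acceptance.R,
# criterion 5)
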