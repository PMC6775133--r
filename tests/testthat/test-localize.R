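test_that("random-search bookkeeping: credit conservation and determinism", {
  tensor <- make_test_tensor(n_el = 8, trials_per_class = 4, n_classes = 4,
                             informative = 1:4, effect = 2, seed = 61)
  map <- random_search_importance(tensor, n_iter = 60, seed = 13)
  expect_equal(sum(map$inclusion_counts), sum(map$subset_sizes))
  expect_equal(sum(map$inclusion_counts),
               sum(lengths(map$subsets)))
  seen <- map$inclusion_counts > 0
  expect_lt(abs(mean(map$z[seen])), 1e-10)
  expect_equal(stats::sd(map$z[seen]), 1, tolerance = 1e-10)
  map2 <- random_search_importance(tensor, n_iter = 60, seed = 13)
  expect_identical(map, map2)
  map3 <- random_search_importance(tensor, n_iter = 60, seed = 14)
  expect_false(identical(map$accs, map3$accs))
})

test_that("a single all-electrode iteration gives equal means and zero z", {
  tensor <- make_test_tensor(n_el = 5, trials_per_class = 3, n_classes = 4,
                             informative = 1:4, effect = 2, seed = 62)
  map <- random_search_importance(tensor, n_iter = 1,
                                  subset_rule = "fixed_fraction",
                                  fraction = 1, seed = 1)
  expect_equal(unique(map$mean_acc), map$accs[1])
  expect_true(all(map$z == 0))
  expect_length(importance_convergence(
    random_search_importance(tensor, n_iter = 2, seed = 1)), 1)
  expect_error(importance_convergence(map), "n_iter")
})

test_that("the convergence curve matches a naive pairwise oracle", {
  tensor <- make_test_tensor(n_el = 6, trials_per_class = 3, n_classes = 4,
                             informative = 1:4, effect = 1.5, seed = 63)
  map <- random_search_importance(tensor, n_iter = 25, seed = 21)
  curve <- importance_convergence(map)
  oracle <- naive_convergence(map)
  expect_length(curve, 24)
  expect_equal(curve, oracle, tolerance = 1e-10)
  # the final entry is the single correlation of patterns n-1 and n
  expect_equal(curve[24], oracle[24])
})

test_that("the importance pattern stabilizes on a strong signal", {
  tensor <- make_test_tensor(n_el = 8, trials_per_class = 5, n_classes = 4,
                             informative = 1:4, effect = 3, seed = 64)
  map <- random_search_importance(tensor, n_iter = 200, seed = 5)
  curve <- importance_convergence(map)
  tail_part <- curve[180:199]
  expect_gt(min(tail_part, na.rm = TRUE), 0.9)
})

test_that("an informative electrode earns the top importance score", {
  hits <- vapply(1:20, function(s) {
    tensor <- make_test_tensor(n_el = 16, trials_per_class = 10,
                               n_classes = 4, informative = 1, effect = 4,
                               seed = 600 + s)
    map <- random_search_importance(tensor, n_iter = 150, seed = s)
    which.max(map$z) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pure-noise importance maps show no reproducible hotspot", {
  zs <- lapply(1:2, function(s) {
    tensor <- make_test_tensor(n_el = 12, trials_per_class = 5,
                               n_classes = 4, informative = integer(0),
                               seed = 70 + s)
    random_search_importance(tensor, n_iter = 150, seed = 70 + s)$z
  })
  expect_lt(abs(stats::cor(zs[[1]], zs[[2]], method = "spearman")), 0.6)
})

test_that("searchlight covers every position of every window size", {
  lay <- grid_layout(3, 4, 4)
  tensor <- make_test_tensor(n_el = 12, trials_per_class = 3, n_classes = 4,
                             informative = 1:4, effect = 2, seed = 65,
                             layout = lay)
  sl <- searchlight(tensor, lay)
  for (k in 1:3) {
    expect_equal(sum(sl$cells$size == k), (3 - k + 1) * (4 - k + 1))
  }
  expect_equal(sl$summary$area_cm2, (1:3 * 4 / 10)^2)
  expect_true(all(diff(sl$summary$area_cm2) > 0))
  expect_true(all(sl$cells$row + sl$cells$size - 1 <= 3))
  expect_true(all(sl$cells$col + sl$cells$size - 1 <= 4))

  # the full-grid window equals plain leave-one-out on all electrodes
  lay2 <- grid_layout(2, 2, 4)
  tensor2 <- make_test_tensor(n_el = 4, trials_per_class = 3, n_classes = 4,
                              informative = 1:4, effect = 2, seed = 66,
                              layout = lay2)
  sl2 <- searchlight(tensor2, lay2)
  expect_equal(sum(sl2$cells$size == 2), 1)
  expect_equal(sl2$cells$accuracy[sl2$cells$size == 2],
               loocv(tensor2, "spatial")$mean_acc)
})

test_that("windows without usable electrodes are recorded as missing", {
  lay <- grid_layout(2, 3, 4)
  # tensor only carries channels 1:4 (grid positions row 1 and (2,1))
  tensor <- make_test_tensor(n_el = 4, trials_per_class = 3, n_classes = 4,
                             informative = 1:4, effect = 2, seed = 67,
                             layout = lay)
  sl <- searchlight(tensor, lay)
  empty <- sl$cells$size == 1 & sl$cells$row == 2 & sl$cells$col >= 2
  expect_true(all(is.na(sl$cells$accuracy[empty])))
  expect_true(all(sl$cells$n_electrodes[empty] == 0))
})

test_that("minimal-area lookup follows the (k * spacing)^2 convention", {
  mk <- function(maxes, spacing = 4) {
    structure(list(
      summary = data.frame(size = seq_along(maxes), max_accuracy = maxes,
                           best_row = 1L, best_col = 1L,
                           area_cm2 = (seq_along(maxes) * spacing / 10)^2),
      layout = grid_layout(8, 8, spacing)), class = "searchlight_result")
  }
  res <- min_area_for_accuracy(mk(c(0.3, 0.65, 0.85, 0.9)), 0.7)
  expect_true(res$reached)
  expect_equal(res$size, 3)
  expect_equal(res$area_cm2, 1.44)

  not <- min_area_for_accuracy(mk(c(0.3, 0.65)), 0.9)
  expect_false(not$reached)
  expect_true(is.na(not$area_cm2))

  zero <- min_area_for_accuracy(mk(c(0.3, 0.65)), 0)
  expect_equal(zero$size, 1)
  expect_equal(zero$area_cm2, (4 / 10)^2)
})

test_that("single-electrode windows use nearest-template matching", {
  # an informative electrode alone must beat chance in a 1 x 1 window
  lay <- grid_layout(1, 2, 4)
  set.seed(68)
  labels <- rep(1:4, each = 10)
  data <- cbind(2 * labels + rnorm(40, sd = 0.3), rnorm(40))
  tensor <- trial_tensor(data, labels, layout = lay)
  sl <- searchlight(tensor, lay, sizes = 1)
  acc <- sl$cells$accuracy[sl$cells$col == 1]
  expect_gt(acc, 0.8)
  expect_lt(sl$cells$accuracy[sl$cells$col == 2], 0.6)
  tpls <- build_templates(tensor, mode = "spatial")
  one_el <- structure(list(mode = "spatial",
                           templates = lapply(tpls$templates, `[`, 1),
                           classes = 1:4), class = "template_set")
  expect_equal(classify_trial(data[1, 1], one_el), 1)
})
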