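test_that("boxcar smoothing matches a direct convolution oracle exactly", {
  set.seed(41)
  x <- rnorm(200)
  for (w in c(1L, 5L, 16L, 33L)) {
    expect_equal(hfbdecode:::moving_average(x, w), boxcar_oracle(x, w),
                 tolerance = 1e-12)
  }
  # unit impulse -> plateau of height 1/window of the right width
  imp <- numeric(101)
  imp[51] <- 1
  sm <- hfbdecode:::moving_average(imp, 11L)
  expect_equal(sum(sm > 1e-12), 11)
  expect_equal(unique(round(sm[sm > 1e-12], 12)), 1 / 11)
})

test_that("smoothing, z-scoring and epoching produce a well-formed tensor", {
  env <- make_test_env(n_el = 4, trials_per_class = 3, rest_trials = 3,
                       effect = 2, seed = 42)
  tensor <- smooth_zscore_epoch(env, smoothing_s = 0.5, epoch_s = 2)
  expect_equal(dim(tensor$data), c(12, 4, round(2 * env$fs)))
  expect_equal(sort(unique(tensor$labels)), 1:4)
  expect_equal(as.integer(table(tensor$labels)), rep(3L, 4))

  # the z-scored full-run series has mean 0 and sd 1 per electrode
  window <- max(1L, round(0.5 * env$fs))
  for (e in 1:2) {
    s <- hfbdecode:::moving_average(env$power[e, ], window)
    z <- (s - mean(s)) / stats::sd(s)
    expect_lt(abs(mean(z)), 1e-10)
    expect_equal(stats::sd(z), 1, tolerance = 1e-6)
  }

  # constant envelope -> all-zero tensor, not NaN
  env_const <- make_test_env(n_el = 2, trials_per_class = 2, rest_trials = 2,
                             effect = 0, noise_sd = 1, seed = 1)
  env_const$power[] <- 7
  t0 <- smooth_zscore_epoch(env_const)
  expect_true(all(t0$data == 0))

  env_bad <- make_test_env(n_el = 2, trials_per_class = 2, rest_trials = 2)
  env_bad$events$onset_sample[nrow(env_bad$events)] <-
    ncol(env_bad$power) - 3L
  expect_error(smooth_zscore_epoch(env_bad), "past the recording")
  expect_error(smooth_zscore_epoch(env, electrodes = integer(0)), "nonempty")
})

test_that("templates are class means of the training trials", {
  # 2 classes x 2 trials, 3 electrodes, 2 time points; hand arithmetic
  d <- array(0, c(4, 3, 2))
  d[1, , ] <- matrix(c(1, 2, 3, 5, 6, 7), 3)
  d[2, , ] <- matrix(c(3, 4, 5, 7, 8, 9), 3)
  d[3, , ] <- matrix(c(10, 0, 0, 10, 0, 0), 3)
  d[4, , ] <- matrix(c(10, 0, 0, 10, 0, 0), 3)
  tensor <- trial_tensor(d, c(1, 1, 2, 2))

  tpl_sp <- build_templates(tensor, mode = "spatial")
  expect_equal(tpl_sp$templates[[1]], c(mean(c(1, 5, 3, 7)),
                                        mean(c(2, 6, 4, 8)),
                                        mean(c(3, 7, 5, 9))))
  tpl_st <- build_templates(tensor, mode = "spatiotemporal")
  expect_equal(tpl_st$templates[[1]],
               (matrix(c(1, 2, 3, 5, 6, 7), 3) +
                  matrix(c(3, 4, 5, 7, 8, 9), 3)) / 2)
  # single training trial per class: template equals that trial
  tpl_one <- build_templates(tensor, train = c(1, 3), mode = "spatiotemporal")
  expect_equal(tpl_one$templates[[1]], d[1, , ])
  # identical trials: template identical to each
  expect_equal(tpl_sp$templates[[2]], rowMeans(d[3, , ]))
  expect_error(build_templates(tensor, train = c(1, 2)), "no training trials")
})

test_that("winner-takes-all correlation classification is correct on toys", {
  tpls <- structure(list(mode = "spatial",
                         templates = list(c(1, 0, 0), c(0, 1, 0),
                                          c(0, 0, 1), c(1, 1, 0)),
                         classes = 1:4),
                    class = "template_set")
  expect_equal(classify_trial(c(1, 0.1, 0), tpls), 1)
  expect_equal(classify_trial(c(0.2, 5, 0.1), tpls), 2)
  # hand-checked: correlations with (0.9, 1.1, 0) are highest for template 4
  expect_equal(classify_trial(c(0.9, 1.1, 0), tpls), 4)
  # positive affine transforms leave the prediction unchanged
  expect_equal(classify_trial(10 + 3 * c(0.2, 5, 0.1), tpls), 2)
  # zero-variance trial -> all correlations 0 -> lowest class index
  expect_equal(classify_trial(c(2, 2, 2), tpls), 1)
})

test_that("stratified folds have the published 10 x 8 (2 per class) shape", {
  labels <- rep(1:4, each = 20)
  folds <- make_folds(labels, k = 10, seed = 3)
  expect_length(folds, 10)
  for (f in folds) {
    expect_length(f, 8)
    expect_equal(as.integer(table(labels[f])), rep(2L, 4))
  }
  expect_equal(sort(unlist(folds)), 1:80)
  expect_identical(make_folds(labels, 10, seed = 3),
                   make_folds(labels, 10, seed = 3))
  expect_error(make_folds(rep(1:4, each = 18), k = 10), "not divisible")
})

test_that("leave-one-out matches a naive per-trial oracle in both modes", {
  set.seed(44)
  for (mode in c("spatial", "spatiotemporal")) {
    tensor <- make_test_tensor(n_el = 5, trials_per_class = 4, n_classes = 3,
                               informative = 1:2, effect = 1.2,
                               seed = 44, n_time = 3)
    cv <- loocv(tensor, mode)
    expect_equal(cv$n_folds, 12)
    expect_equal(cv$mean_acc, naive_loocv_acc(tensor, mode))
    expect_equal(sum(cv$confusion), 12)
  }
  # perfectly separable toy -> accuracy 1
  sep <- make_test_tensor(n_el = 4, trials_per_class = 3, n_classes = 4,
                          informative = 1:4, effect = 50, seed = 45)
  expect_equal(loocv(sep, "spatial")$mean_acc, 1)
})

test_that("accuracy is invariant to per-electrode affine gain and offset", {
  # the per-electrode z-scoring step absorbs any positive affine rescaling
  # applied identically to train and test, so fold accuracies match exactly
  env <- make_test_env(n_el = 6, trials_per_class = 5, rest_trials = 5,
                       effect = 1.5, seed = 46)
  env2 <- env
  a <- c(0.2, 3, 11, 0.5, 7, 1.3)
  b <- c(-4, 2, 0, 9, -1, 5)
  for (e in 1:6) env2$power[e, ] <- a[e] * env$power[e, ] + b[e]
  cv1 <- crossvalidate(env, "spatial", k = 5, seed = 3, n_perm = 200)
  cv2 <- crossvalidate(env2, "spatial", k = 5, seed = 3, n_perm = 200)
  expect_equal(cv1$fold_acc, cv2$fold_acc)
  expect_equal(cv1$confusion, cv2$confusion)
})

test_that("spatial and spatio-temporal modes agree on time-constant data", {
  tensor <- make_test_tensor(n_el = 5, trials_per_class = 5, n_classes = 4,
                             informative = 1:2, effect = 1.5, seed = 47)
  rep_t <- tensor
  rep_t$data <- array(rep(tensor$data, 4), c(dim(tensor$data)[1:2], 4))
  sp <- loocv(rep_t, "spatial")
  st <- loocv(rep_t, "spatiotemporal")
  expect_equal(sp$fold_acc, st$fold_acc)
})

test_that("the full cross-validated pipeline decodes a separable envelope", {
  env <- make_test_env(n_el = 8, trials_per_class = 10, rest_trials = 10,
                       effect = 4, seed = 48)
  cv <- crossvalidate(env, "spatial", k = 5, seed = 2, n_perm = 300,
                      return_details = TRUE)
  expect_equal(cv$mean_acc, 1)
  expect_equal(cv$n_folds, 5)
  expect_equal(sum(cv$confusion), 40)
  expect_equal(as.integer(rowSums(cv$confusion)), rep(10L, 4))
  expect_equal(mean(cv$fold_acc), cv$mean_acc)
  # per-fold selection found the four informative electrodes
  expect_true(all(cv$details$fold_selected[, 1:4]))

  # mean accuracy near chance when labels are shuffled
  set.seed(49)
  labs <- env$events$label
  mov <- which(labs != "rest")
  labs[mov] <- sample(labs[mov])
  cv0 <- crossvalidate(env, "spatial", k = 5, seed = 2, n_perm = 300,
                       labels = labs)
  expect_lt(cv0$mean_acc, 0.6)
  expect_error(crossvalidate(env, "spatial", labels = rev(labs)),
               "rest trials in place")
})

test_that("SNR ladder: accuracy is non-decreasing in effect size", {
  accs <- vapply(c(0.3, 0.8, 1.6, 3), function(eff) {
    mean(vapply(1:4, function(s) {
      tensor <- make_test_tensor(n_el = 6, trials_per_class = 5,
                                 n_classes = 4, informative = 1:2,
                                 effect = eff, seed = 50 + s)
      loocv(tensor, "spatial")$mean_acc
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.05)) # allow one small inversion
  expect_gt(accs[4], accs[1])
})

test_that("permutation test of accuracy follows the add-one rule", {
  env <- make_test_env(n_el = 6, trials_per_class = 4, rest_trials = 4,
                       effect = 5, seed = 51)
  res <- accuracy_significance(env, "spatial", k = 4, n_perm = 199, seed = 7,
                               cv_args = list(n_perm = 300))
  expect_equal(res$p_value, 1 / 200) # observed beats every permutation
  expect_gte(min(res$perm_acc), 0)
  expect_error(accuracy_significance(env, "spatial", k = 4, n_perm = 50),
               "n_perm")
})

test_that("permutation p-values are roughly uniform under the null", {
  set.seed(52)
  ps <- vapply(1:40, function(s) {
    env <- make_test_env(n_el = 3, trials_per_class = 3, rest_trials = 3,
                         effect = 0, seed = 500 + s, fs = 8, cue_s = 1,
                         iti_s = 1)
    accuracy_significance(env, "spatial", k = 3, n_perm = 119, seed = s,
                          cv_args = list(select = FALSE, smoothing_s = 0.25,
                                         epoch_s = 1.5))$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.05)
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})
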