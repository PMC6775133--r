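# Centered moving average with window truncated at the run edges: each output
# sample is the mean of the available input samples within +/- half a window.
moving_average <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(x)
  hi <- pmin(n, seq_len(n) + half)
  lo <- pmax(1L, seq_len(n) - half)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
}

#' Smooth, z-score and epoch an HFB envelope into a trial tensor
#'
#' Applies a centred moving average of `smoothing_s` seconds to every
#' electrode's envelope (window truncated at the run edges), z-scores each
#' electrode over the full run (an electrode with zero variance becomes all
#' zeros), and epochs the movement trials into windows of `epoch_s` seconds
#' starting at cue onset. Rest trials are not epoched.
#'
#' @param env An [gabor_power()] envelope.
#' @param electrodes Channel indices to keep (default all).
#' @param smoothing_s Moving-average window in seconds (default 0.5).
#' @param epoch_s Epoch length in seconds from cue onset (default 2).
#' @return A `trial_tensor`: `data` (trials x electrodes x time array),
#'   `labels` (integer class per trial), `classes` (class names),
#'   `electrodes`, `fs`, `layout` and the smoothing/epoch parameters.
#' @export
smooth_zscore_epoch <- function(env, electrodes = NULL, smoothing_s = 0.5,
                                epoch_s = 2.0) {
  stopifnot(inherits(env, "hfb_envelope"))
  if (is.null(electrodes)) electrodes <- seq_len(nrow(env$power))
  if (length(electrodes) < 1L) stop("electrodes must be nonempty", call. = FALSE)
  fs <- env$fs
  window <- max(1L, round(smoothing_s * fs))
  n <- ncol(env$power)

  z <- matrix(0, length(electrodes), n)
  for (j in seq_along(electrodes)) {
    s <- moving_average(env$power[electrodes[j], ], window)
    sdv <- stats::sd(s)
    z[j, ] <- if (sdv > 0) (s - mean(s)) / sdv else 0
  }

  ev <- env$events
  mov <- which(ev$label != "rest")
  classes <- sort(unique(ev$label[mov]))
  n_t <- round(epoch_s * fs)
  data <- array(NA_real_, c(length(mov), length(electrodes), n_t))
  for (j in seq_along(mov)) {
    i0 <- env_index(ev$onset_sample[mov[j]], env$hop)
    if (i0 + n_t - 1L > n) stop("epoch extends past the recording", call. = FALSE)
    data[j, , ] <- z[, i0:(i0 + n_t - 1L)]
  }
  structure(
    list(data = data, labels = match(ev$label[mov], classes),
         classes = classes, electrodes = as.integer(electrodes), fs = fs,
         layout = env$layout, smoothing_s = smoothing_s, epoch_s = epoch_s),
    class = "trial_tensor"
  )
}

#' Construct a trial tensor directly
#'
#' Low-level constructor, mainly for simulation studies that operate at the
#' trial-feature level (bypassing the signal chain).
#'
#' @param data Trials x electrodes x time array (a trials x electrodes matrix
#'   is promoted to a single time point).
#' @param labels Integer class labels, one per trial.
#' @param electrodes Channel indices (default `1:n_electrodes`).
#' @param layout Optional [grid_layout()].
#' @param fs Nominal sampling rate of the time axis.
#' @return A `trial_tensor`.
#' @export
trial_tensor <- function(data, labels, electrodes = NULL, layout = NULL,
                         fs = 1) {
  if (length(dim(data)) == 2L) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3L, dim(data)[1] == length(labels))
  labels <- as.integer(labels)
  if (is.null(electrodes)) electrodes <- seq_len(dim(data)[2])
  structure(
    list(data = data, labels = labels,
         classes = paste0("class_", sort(unique(labels))),
         electrodes = as.integer(electrodes), fs = fs, layout = layout,
         smoothing_s = NA_real_, epoch_s = dim(data)[3] / fs),
    class = "trial_tensor"
  )
}

# Spatial features: per-trial, per-electrode mean over the epoch.
spatial_features <- function(tensor) {
  apply(tensor$data, c(1, 2), mean)
}

# Flattened spatio-temporal features: trials x (electrodes*time), electrode
# index varying fastest so column blocks of an electrode subset are contiguous.
flat_features <- function(tensor) {
  d <- dim(tensor$data)
  matrix(tensor$data, d[1], d[2] * d[3])
}

# Column indices of an electrode subset inside the flattened feature matrix.
flat_cols <- function(subset, n_el, n_t) {
  as.vector(outer(subset, (seq_len(n_t) - 1L) * n_el, "+"))
}

#' Build per-class templates from training trials
#'
#' A class's template is the mean over that class's training trials — of the
#' per-electrode time-averaged pattern for `mode = "spatial"`, or of the full
#' electrode x time pattern for `mode = "spatiotemporal"`.
#'
#' @param tensor A `trial_tensor`.
#' @param train Integer indices of the training trials.
#' @param mode `"spatial"` or `"spatiotemporal"`.
#' @return A `template_set`: list with `mode` and `templates` (one vector or
#'   matrix per class).
#' @export
build_templates <- function(tensor, train = seq_along(tensor$labels),
                            mode = c("spatial", "spatiotemporal")) {
  mode <- match.arg(mode)
  classes <- sort(unique(tensor$labels))
  templates <- vector("list", length(classes))
  for (ci in seq_along(classes)) {
    idx <- train[tensor$labels[train] == classes[ci]]
    if (length(idx) < 1L) stop("a class has no training trials", call. = FALSE)
    if (mode == "spatial") {
      m <- apply(tensor$data[idx, , , drop = FALSE], 2, mean)
    } else {
      m <- apply(tensor$data[idx, , , drop = FALSE], c(2, 3), mean)
    }
    templates[[ci]] <- m
  }
  structure(list(mode = mode, templates = templates, classes = classes),
            class = "template_set")
}

#' Classify one trial by template correlation (winner-takes-all)
#'
#' Pearson-correlates the trial's feature vector (spatial: per-electrode
#' time-averaged pattern; spatio-temporal: flattened electrode x time matrix)
#' with each class template and returns the best-correlated class. Ties —
#' including the degenerate all-zero-correlation case of a zero-variance
#' trial — go to the lowest class index. For one-dimensional features (a
#' single electrode in spatial mode, where a correlation across electrodes
#' is undefined) the nearest template by absolute distance wins instead,
#' which keeps single-electrode searchlight windows meaningful.
#'
#' @param trial Electrode vector (spatial) or electrode x time matrix.
#' @param templates A [build_templates()] result.
#' @return Integer predicted class.
#' @export
classify_trial <- function(trial, templates) {
  stopifnot(inherits(templates, "template_set"))
  if (templates$mode == "spatial" && is.matrix(trial)) trial <- rowMeans(trial)
  v <- as.numeric(trial)
  scores <- if (length(v) == 1L) {
    vapply(templates$templates, function(tm) -abs(v - as.numeric(tm)),
           numeric(1))
  } else {
    vapply(templates$templates,
           function(tm) safe_cor(v, as.numeric(tm)), numeric(1))
  }
  templates$classes[which.max(scores)]
}

#' Stratified folds for k-fold cross-validation
#'
#' Splits movement trials into `k` folds with an equal number of trials of
#' every class per fold (for the standard 80-trial, 4-class design and
#' `k = 10`: 10 folds of 8 trials, 2 per class). Assignment is a seeded
#' random permutation within each class.
#'
#' @param labels Integer class labels of the movement trials.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of `k` integer vectors of trial indices.
#' @export
make_folds <- function(labels, k = 10L, seed = NULL) {
  classes <- sort(unique(labels))
  folds <- vector("list", k)
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      if (length(idx) %% k != 0L) {
        stop(sprintf(
          "class %s has %d trials, not divisible into %d folds", cl,
          length(idx), k), call. = FALSE)
      }
      idx <- sample(idx)
      per <- length(idx) / k
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], idx[((f - 1) * per + 1):(f * per)])
      }
    }
  })
  lapply(folds, sort)
}

# Fast leave-one-out template-matching on a trials x features matrix.
# Templates are class means excluding the held-out trial. Returns the
# integer predictions (ties and zero-variance rows -> lowest class index).
loo_predict <- function(feats, y) {
  classes <- sort(unique(y))
  n <- nrow(feats)
  cormat <- matrix(0, n, length(classes))
  for (ci in seq_along(classes)) {
    in_c <- y == classes[ci]
    n_c <- sum(in_c)
    s_c <- colSums(feats[in_c, , drop = FALSE])
    tpl <- matrix(s_c, n, ncol(feats), byrow = TRUE)
    tpl[in_c, ] <- tpl[in_c, ] - feats[in_c, , drop = FALSE]
    denom <- ifelse(in_c, n_c - 1L, n_c)
    if (any(denom < 1L)) stop("need >= 2 trials per class", call. = FALSE)
    tpl <- tpl / denom
    cormat[, ci] <- match_scores(feats, tpl)
  }
  classes[max.col(cormat, ties.method = "first")]
}

new_cv_result <- function(fold_acc, preds, truth, classes, mode, k) {
  confusion <- table(factor(truth, levels = classes),
                     factor(preds, levels = classes))
  structure(
    list(fold_acc = fold_acc, mean_acc = mean(fold_acc),
         sd_acc = stats::sd(fold_acc),
         confusion = unclass(confusion), n_folds = length(fold_acc),
         classes = classes, mode = mode, k = k, p_value = NULL),
    class = "cv_result"
  )
}

# Core of the cross-validated template-matching pipeline, shared by
# crossvalidate() and accuracy_significance(). Works on precomputed selection
# features (per-trial means over ALL trials) and a precomputed tensor.
cv_core <- function(means_all, labels_all, tensor, mov_idx, candidates,
                    mode, k, seed, n_perm, alpha, fdr_family, select,
                    return_details = FALSE) {
  y <- match(labels_all[mov_idx], sort(unique(labels_all[mov_idx])))
  classes <- sort(unique(y))
  folds <- make_folds(y, k, seed)
  cand_pos <- match(candidates, tensor$electrodes)
  if (anyNA(cand_pos)) stop("candidate electrodes missing from tensor", call. = FALSE)

  feats_sp <- spatial_features(tensor)
  if (mode == "spatiotemporal") {
    feats_fl <- flat_features(tensor)
    n_t <- dim(tensor$data)[3]
  }

  rest_rows <- which(labels_all == "rest")
  fold_acc <- numeric(k)
  preds <- integer(length(mov_idx))
  sel_masks <- matrix(NA, k, length(candidates))
  templates <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds[[f]]
    train <- setdiff(seq_along(mov_idx), test)
    el <- candidates
    if (select) {
      rows <- c(mov_idx[train], rest_rows)
      sel <- permutation_fdr(means_all[rows, candidates, drop = FALSE],
                             labels_all[rows], n_perm = n_perm, alpha = alpha,
                             seed = if (is.null(seed)) NULL else seed + 7919L * f,
                             fdr_family = fdr_family)
      sel_masks[f, ] <- sel$selected
      # no electrode significant: fall back to the full candidate set
      if (any(sel$selected)) el <- candidates[sel$selected]
    }
    pos <- match(el, tensor$electrodes)
    if (mode == "spatial") {
      ftr <- feats_sp[, pos, drop = FALSE]
    } else {
      ftr <- feats_fl[, flat_cols(pos, length(tensor$electrodes), n_t),
                      drop = FALSE]
    }
    tpl <- matrix(0, length(classes), ncol(ftr))
    for (ci in seq_along(classes)) {
      idx <- train[y[train] == classes[ci]]
      if (!length(idx)) stop("a class has no training trials", call. = FALSE)
      tpl[ci, ] <- colMeans(ftr[idx, , drop = FALSE])
    }
    cors <- match_scores(ftr[test, , drop = FALSE][rep(seq_along(test),
                                                       length(classes)), ,
                                                   drop = FALSE],
                         tpl[rep(seq_along(classes), each = length(test)), ,
                             drop = FALSE])
    cors <- matrix(cors, length(test), length(classes))
    preds[test] <- classes[max.col(cors, ties.method = "first")]
    fold_acc[f] <- mean(preds[test] == y[test])
    if (return_details) templates[[f]] <- tpl
  }
  res <- new_cv_result(fold_acc, preds, y, classes, mode, k)
  if (return_details) {
    res$details <- list(fold_selected = sel_masks, candidates = candidates,
                        templates = templates, folds = folds)
  }
  res
}

#' Template-matching classification with k-fold cross-validation
#'
#' Runs the full decoding procedure on an HFB envelope: the envelope is
#' smoothed (0.5 s moving average), z-scored over the run and epoched into
#' 2 s trials; movement trials are split into `k` stratified folds; within
#' each fold, responsive electrodes are selected on the training trials only
#' (movement-vs-rest permutation r-squared with FDR, [permutation_fdr()]),
#' class templates are averaged from the training trials, and each held-out
#' trial is assigned to the best-correlated template. Rest trials are used
#' for electrode selection but never classified. If a fold selects no
#' electrode, all candidate electrodes are used for that fold.
#'
#' @param env An [gabor_power()] envelope.
#' @param mode `"spatial"` (time-averaged patterns) or `"spatiotemporal"`
#'   (full electrode x time patterns).
#' @param k Number of folds (per-class trial counts must be divisible by it).
#' @param seed Integer seed for fold assignment and selection permutations.
#' @param electrodes Candidate channels (e.g. the included channels of a
#'   [detect_bad_channels()] mask); default all.
#' @param select Run per-fold electrode selection (default TRUE).
#' @param n_perm,alpha,fdr_family Selection parameters, see
#'   [permutation_fdr()].
#' @param smoothing_s,epoch_s See [smooth_zscore_epoch()].
#' @param labels Optional replacement trial labels (used by the accuracy
#'   permutation test); must keep rest trials at their original positions.
#' @param return_details Also return per-fold selection masks, templates and
#'   fold assignments.
#' @return A `cv_result`: per-fold accuracies, their mean and SD, the pooled
#'   confusion matrix (rows = true class), and optionally `details`.
#' @export
crossvalidate <- function(env, mode = c("spatial", "spatiotemporal"), k = 10L,
                          seed = 1L, electrodes = NULL, select = TRUE,
                          n_perm = 1000L, alpha = 0.05,
                          fdr_family = "within_movement",
                          smoothing_s = 0.5, epoch_s = 2.0, labels = NULL,
                          return_details = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(env, "hfb_envelope"))
  if (is.null(electrodes)) electrodes <- seq_len(nrow(env$power))
  tm <- trial_means(env)
  labels_all <- if (is.null(labels)) tm$labels else labels
  if (length(labels_all) != length(tm$labels) ||
      !identical(labels_all == "rest", tm$labels == "rest")) {
    stop("replacement labels must keep rest trials in place", call. = FALSE)
  }
  mov_idx <- which(labels_all != "rest")
  tensor <- smooth_zscore_epoch(env, electrodes, smoothing_s, epoch_s)
  cv_core(tm$means, labels_all, tensor, mov_idx, electrodes, mode, k, seed,
          n_perm, alpha, fdr_family, select, return_details)
}

#' Leave-one-trial-out cross-validation on a trial tensor
#'
#' One fold per trial; templates are rebuilt from the remaining trials. The
#' electrode set is taken as given (no inner selection) — this is the
#' data-efficient variant used by the localization procedures.
#'
#' @param tensor A `trial_tensor`.
#' @param mode `"spatial"` or `"spatiotemporal"`.
#' @param electrodes Optional channel indices (subset of
#'   `tensor$electrodes`); default all.
#' @return A `cv_result` with one fold per trial.
#' @export
loocv <- function(tensor, mode = c("spatial", "spatiotemporal"),
                  electrodes = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(tensor, "trial_tensor"))
  pos <- if (is.null(electrodes)) seq_along(tensor$electrodes)
         else match(electrodes, tensor$electrodes)
  if (anyNA(pos) || !length(pos)) stop("unknown electrodes", call. = FALSE)
  y <- tensor$labels
  if (min(table(y)) < 2L) stop("need >= 2 trials per class", call. = FALSE)
  if (mode == "spatial") {
    feats <- spatial_features(tensor)[, pos, drop = FALSE]
  } else {
    feats <- flat_features(tensor)[, flat_cols(pos, length(tensor$electrodes),
                                               dim(tensor$data)[3]),
                                   drop = FALSE]
  }
  preds <- loo_predict(feats, y)
  new_cv_result(as.numeric(preds == y), preds, y, sort(unique(y)), mode,
                k = length(y))
}

#' Permutation significance of cross-validated accuracy
#'
#' Repeats the full cross-validation (including per-fold electrode selection)
#' with the movement-class labels permuted among movement trials, and returns
#' the add-one permutation p-value of the observed mean accuracy.
#'
#' @inheritParams crossvalidate
#' @param n_perm Number of label permutations (>= 100).
#' @param cv_args List of further arguments passed to the cross-validation
#'   (e.g. `n_perm` for the inner electrode selection).
#' @return The observed `cv_result` with `p_value` filled in and a
#'   `perm_acc` vector attached.
#' @export
accuracy_significance <- function(env, mode = c("spatial", "spatiotemporal"),
                                  k = 10L, n_perm = 199L, seed = 1L,
                                  electrodes = NULL, cv_args = list()) {
  mode <- match.arg(mode)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  if (is.null(electrodes)) electrodes <- seq_len(nrow(env$power))
  tm <- trial_means(env)
  mov_idx <- which(tm$labels != "rest")
  args <- utils::modifyList(
    list(n_perm = 1000L, alpha = 0.05, fdr_family = "within_movement",
         select = TRUE, smoothing_s = 0.5, epoch_s = 2.0), cv_args)
  tensor <- smooth_zscore_epoch(env, electrodes, args$smoothing_s,
                                args$epoch_s)
  run_cv <- function(lab, sd) {
    cv_core(tm$means, lab, tensor, mov_idx, electrodes, mode, k, sd,
            args$n_perm, args$alpha, args$fdr_family, args$select)
  }
  obs <- run_cv(tm$labels, seed)
  perm_acc <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      lab <- tm$labels
      lab[mov_idx] <- sample(lab[mov_idx])
      run_cv(lab, seed + i)$mean_acc
    }, numeric(1))
  })
  obs$p_value <- (1 + sum(perm_acc >= obs$mean_acc)) / (n_perm + 1)
  obs$perm_acc <- perm_acc
  obs
}

#' Binomial reference p-value for a cross-validated accuracy
#'
#' A quick exact binomial test of the pooled correct count against chance.
#' Only a reference: cross-validated trials are not independent, so this is
#' approximate — prefer [accuracy_significance()].
#'
#' @param cv A `cv_result`.
#' @param chance Chance accuracy (default `1/n_classes`).
#' @return p-value from [stats::binom.test()].
#' @export
binomial_accuracy_p <- function(cv, chance = 1 / length(cv$classes)) {
  n <- sum(cv$confusion)
  correct <- sum(diag(cv$confusion))
  stats::binom.test(correct, n, p = chance, alternative = "greater")$p.value
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s template matching, %d folds: mean acc %.3f (sd %.3f)%s\n",
              x$mode, x$n_folds, x$mean_acc, x$sd_acc,
              if (!is.null(x$p_value)) sprintf(", p = %.4g", x$p_value) else ""))
  invisible(x)
}
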