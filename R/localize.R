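#' Random-search electrode importance
#'
#' Draws `n_iter` random electrode subsets, scores each with spatial-mode
#' leave-one-trial-out template matching ([loocv()]), and credits every
#' member electrode with that subset's accuracy. An electrode's importance is
#' its mean accuracy over the subsets that contained it, z-scored across
#' electrodes. A convergence diagnostic tracks how the importance pattern at
#' iteration \eqn{i} (the running mean-accuracy vector over iterations
#' \eqn{1..i}) correlates, on average, with the patterns of all subsequent
#' iterations: the closer to 1, the more stable the map.
#'
#' Subset sizes follow `subset_rule`: `"uniform"` draws the size uniformly on
#' `[1, n_electrodes]` and then a uniform subset of that size;
#' `"fixed_fraction"` always uses `round(fraction * n_electrodes)`.
#'
#' @param tensor A `trial_tensor`.
#' @param n_iter Number of random subsets (default 5000).
#' @param subset_rule `"uniform"` (default) or `"fixed_fraction"`.
#' @param fraction Subset fraction for `"fixed_fraction"`.
#' @param seed Integer seed; identical seeds reproduce the map bit-for-bit.
#' @return An `importance_map`: `mean_acc` and `z` per electrode,
#'   `inclusion_counts`, `subset_sizes`, the per-iteration `accs`, the
#'   `convergence` curve (length `n_iter - 1`, with the number of skipped
#'   undefined correlations), and the electrode/layout bookkeeping. Before an
#'   electrode's first inclusion its running mean is taken as 0 in the
#'   convergence patterns; electrodes never included have `mean_acc = NA`
#'   and are excluded from the z-scoring.
#' @export
random_search_importance <- function(tensor, n_iter = 5000L,
                                     subset_rule = c("uniform",
                                                     "fixed_fraction"),
                                     fraction = 0.5, seed = NULL) {
  stopifnot(inherits(tensor, "trial_tensor"))
  subset_rule <- match.arg(subset_rule)
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  feats <- spatial_features(tensor)
  y <- tensor$labels
  if (min(table(y)) < 2L) stop("need >= 2 trials per class", call. = FALSE)
  n_el <- ncol(feats)
  if (n_el < 2L) stop("need >= 2 electrodes", call. = FALSE)

  acc_sum <- counts <- numeric(n_el)
  accs <- sizes <- numeric(n_iter)
  subsets <- vector("list", n_iter)
  running <- matrix(0, n_el, n_iter)
  with_seed(seed, {
    for (i in seq_len(n_iter)) {
      size <- switch(subset_rule,
                     uniform = sample.int(n_el, 1L),
                     fixed_fraction = max(1L, round(fraction * n_el)))
      subset <- sort(sample.int(n_el, size))
      preds <- loo_predict(feats[, subset, drop = FALSE], y)
      a <- mean(preds == y)
      acc_sum[subset] <- acc_sum[subset] + a
      counts[subset] <- counts[subset] + 1
      accs[i] <- a
      sizes[i] <- size
      subsets[[i]] <- subset
      running[, i] <- ifelse(counts > 0, acc_sum / pmax(counts, 1), 0)
    }
  })

  mean_acc <- ifelse(counts > 0, acc_sum / pmax(counts, 1), NA_real_)
  seen <- counts > 0
  z <- rep(NA_real_, n_el)
  if (sum(seen) > 1L) {
    sdv <- stats::sd(mean_acc[seen])
    z[seen] <- if (is.finite(sdv) && sdv > 0) {
      (mean_acc[seen] - mean(mean_acc[seen])) / sdv
    } else 0
  } else if (sum(seen) == 1L) z[seen] <- 0

  conv <- convergence_curve(running)

  structure(
    list(mean_acc = mean_acc, z = z, inclusion_counts = counts,
         n_iter = n_iter, accs = accs, subset_sizes = sizes,
         subsets = subsets, convergence = conv$curve,
         convergence_skipped = conv$skipped, subset_rule = subset_rule,
         electrodes = tensor$electrodes, layout = tensor$layout),
    class = "importance_map"
  )
}

# Mean correlation of each running pattern with all subsequent ones, via
# suffix sums of the standardized (unit-norm, centered) pattern columns.
convergence_curve <- function(running) {
  n_iter <- ncol(running)
  if (n_iter < 2L) return(list(curve = numeric(0), skipped = 0L))
  u <- sweep(running, 2, colMeans(running), "-")
  nrm <- sqrt(colSums(u^2))
  valid <- nrm > 0
  u[, valid] <- sweep(u[, valid, drop = FALSE], 2, nrm[valid], "/")
  u[, !valid] <- 0
  # suffix sums over columns j > i
  suffix <- u[, n_iter:1, drop = FALSE]
  suffix <- t(apply(suffix, 1, cumsum))[, n_iter:1, drop = FALSE]
  n_valid_after <- rev(cumsum(rev(as.numeric(valid))))
  curve <- rep(NA_real_, n_iter - 1L)
  skipped <- 0L
  for (i in seq_len(n_iter - 1L)) {
    nv <- n_valid_after[i + 1L]
    if (!valid[i] || nv == 0L) {
      skipped <- skipped + 1L
      next
    }
    s <- suffix[, i + 1L]
    curve[i] <- sum(u[, i] * s) / nv
  }
  list(curve = curve, skipped = skipped)
}

#' Convergence diagnostic of an importance map
#'
#' @param map An [random_search_importance()] result.
#' @return Numeric vector of length `n_iter - 1`: entry \eqn{i} is the mean
#'   Pearson correlation of the running importance pattern after \eqn{i}
#'   iterations with the patterns after every later iteration. Undefined
#'   correlations (zero-variance patterns) are `NA`; their count is in
#'   `map$convergence_skipped`.
#' @export
importance_convergence <- function(map) {
  stopifnot(inherits(map, "importance_map"))
  if (map$n_iter < 2L) stop("n_iter must be >= 2 for convergence", call. = FALSE)
  map$convergence
}

#' Searchlight decoding accuracy over the electrode grid
#'
#' Slides square windows of growing size (1x1, 2x2, ..., up to the full grid)
#' over every position of the electrode grid and computes the spatial-mode
#' leave-one-trial-out accuracy using only the window's electrodes. Excluded
#' electrodes inside a window are simply omitted; a window with no usable
#' electrode is recorded as `NA`. Per window size the maximum accuracy over
#' positions and the covered cortical area, `(size * spacing_mm / 10)^2` cm².
#'
#' @param tensor A `trial_tensor` whose electrodes live on `layout`.
#' @param layout A [grid_layout()]; default the tensor's layout.
#' @param sizes Window sizes to evaluate; default `1:min(n_rows, n_cols)`.
#' @return A `searchlight_result`: `cells` (one row per size x position with
#'   the accuracy and electrode count) and `summary` (per size: maximum
#'   accuracy, its position, `area_cm2`).
#' @export
searchlight <- function(tensor, layout = tensor$layout, sizes = NULL) {
  stopifnot(inherits(tensor, "trial_tensor"), inherits(layout, "grid_layout"))
  y <- tensor$labels
  if (min(table(y)) < 2L) stop("need >= 2 trials per class", call. = FALSE)
  feats <- spatial_features(tensor)
  pos <- channel_positions(layout)
  el_row <- pos$row[match(tensor$electrodes, pos$channel)]
  el_col <- pos$col[match(tensor$electrodes, pos$channel)]
  if (is.null(sizes)) sizes <- seq_len(min(layout$n_rows, layout$n_cols))

  cells <- list()
  for (k in sizes) {
    for (r in seq_len(layout$n_rows - k + 1L)) {
      for (cc in seq_len(layout$n_cols - k + 1L)) {
        in_win <- which(el_row >= r & el_row <= r + k - 1L &
                        el_col >= cc & el_col <= cc + k - 1L)
        acc <- if (length(in_win)) {
          mean(loo_predict(feats[, in_win, drop = FALSE], y) == y)
        } else NA_real_
        cells[[length(cells) + 1L]] <-
          data.frame(size = k, row = r, col = cc,
                     n_electrodes = length(in_win), accuracy = acc)
      }
    }
  }
  cells <- do.call(rbind, cells)
  summary <- do.call(rbind, lapply(sizes, function(k) {
    sub <- cells[cells$size == k, ]
    if (all(is.na(sub$accuracy))) {
      best <- NA_integer_
      mx <- NA_real_
    } else {
      best <- which.max(sub$accuracy)
      mx <- sub$accuracy[best]
    }
    data.frame(size = k,
               max_accuracy = mx,
               best_row = if (is.na(best)) NA_integer_ else sub$row[best],
               best_col = if (is.na(best)) NA_integer_ else sub$col[best],
               area_cm2 = (k * layout$spacing_mm / 10)^2)
  }))
  structure(list(cells = cells, summary = summary, layout = layout),
            class = "searchlight_result")
}

#' Minimal cortical area reaching an accuracy threshold
#'
#' The smallest searchlight size whose maximum accuracy exceeds `threshold`
#' (strictly), converted to cm² with the `(size * spacing / 10)^2`
#' convention.
#'
#' @param result A [searchlight()] result.
#' @param threshold Accuracy threshold in `(0, 1)` — e.g. 0.7.
#' @return A list with `reached` (logical), `size` and `area_cm2` (`NA` when
#'   no size qualifies).
#' @export
min_area_for_accuracy <- function(result, threshold) {
  stopifnot(inherits(result, "searchlight_result"))
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)", call. = FALSE)
  s <- result$summary
  ok <- which(!is.na(s$max_accuracy) & s$max_accuracy > threshold)
  if (!length(ok)) {
    return(list(reached = FALSE, size = NA_integer_, area_cm2 = NA_real_))
  }
  i <- ok[which.min(s$size[ok])]
  list(reached = TRUE, size = s$size[i], area_cm2 = s$area_cm2[i])
}

#' @export
print.importance_map <- function(x, ...) {
  cat(sprintf("<importance_map> %d electrodes, %d iterations; top z = %.2f at electrode %d\n",
              length(x$z), x$n_iter, max(x$z, na.rm = TRUE),
              x$electrodes[which.max(x$z)]))
  invisible(x)
}

#' @export
print.searchlight_result <- function(x, ...) {
  cat("<searchlight_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Plot an importance map on the electrode grid
#'
#' @param x An `importance_map` with a layout.
#' @param what `"z"` or `"mean_acc"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.importance_map <- function(x, what = c("z", "mean_acc"), ...) {
  what <- match.arg(what)
  if (is.null(x$layout)) stop("importance map has no layout", call. = FALSE)
  v <- rep(NA_real_, x$layout$n_channels)
  v[x$electrodes] <- x[[what]]
  m <- matrix(v, x$layout$n_rows, x$layout$n_cols, byrow = TRUE)
  graphics::image(seq_len(x$layout$n_cols), seq_len(x$layout$n_rows),
                  t(m[x$layout$n_rows:1, , drop = FALSE]),
                  xlab = "column", ylab = "row",
                  main = sprintf("electrode importance (%s)", what), ...)
  invisible(x)
}
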