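#' Per-trial mean HFB activity
#'
#' Averages the envelope of every electrode over each trial's active window
#' (from cue onset until the end of the cue). These per-trial means are the
#' inputs of the responsiveness statistics and of electrode selection.
#'
#' @param env An [gabor_power()] envelope.
#' @param trials Optional integer vector of trial (event-row) indices;
#'   default all trials.
#' @return A list with `means` (trials x electrodes matrix) and `labels`
#'   (character vector, one per trial).
#' @export
trial_means <- function(env, trials = NULL) {
  stopifnot(inherits(env, "hfb_envelope"))
  ev <- env$events
  if (is.null(trials)) trials <- seq_len(nrow(ev))
  n_keep <- ncol(env$power)
  means <- matrix(NA_real_, length(trials), nrow(env$power))
  for (j in seq_along(trials)) {
    tr <- trials[j]
    if (ev$duration_samples[tr] < 1L) stop("empty trial window", call. = FALSE)
    i0 <- env_index(ev$onset_sample[tr], env$hop)
    i1 <- env_index(ev$onset_sample[tr] + ev$duration_samples[tr] - 1L, env$hop)
    if (i1 > n_keep) stop("trial window extends past the recording", call. = FALSE)
    means[j, ] <- rowMeans(env$power[, i0:i1, drop = FALSE])
  }
  list(means = means, labels = ev$label[trials])
}

#' Responsiveness (r-squared) of electrodes to one movement
#'
#' The squared Pearson correlation between the per-trial mean HFB activity
#' and a binary active-vs-rest design: trials of `movement` coded 1, rest
#' trials coded 0, all other trials excluded. Electrodes whose means have
#' zero variance across the retained trials get r-squared 0.
#'
#' @param means Trials x electrodes matrix of per-trial means.
#' @param labels Trial labels (`"rest"` marks rest trials).
#' @param movement The movement label to contrast against rest.
#' @return Numeric vector of r-squared values in `[0, 1]`, one per electrode.
#' @export
movement_r2 <- function(means, labels, movement) {
  keep <- labels %in% c(movement, "rest")
  y <- as.numeric(labels[keep] == movement)
  if (sum(y) < 2 || sum(1 - y) < 2) {
    stop("need >= 2 trials of the movement and >= 2 rest trials", call. = FALSE)
  }
  m <- means[keep, , drop = FALSE]
  r <- suppressWarnings(as.numeric(stats::cor(y, m)))
  r[!is.finite(r)] <- 0
  r^2
}

#' Permutation significance of electrode responsiveness, with FDR control
#'
#' For each movement, the observed per-electrode r-squared (movement vs rest,
#' [movement_r2()]) is compared against a Monte-Carlo distribution obtained by
#' shuffling the active/rest labels `n_perm` times. P-values use the add-one
#' convention \eqn{p = (1 + \#\{r^2_{perm} \ge r^2_{obs}\}) / (n_perm + 1)},
#' so the smallest attainable p is `1/(n_perm+1)`. Benjamini-Hochberg FDR is
#' then applied at level `alpha`, by default across electrodes within each
#' movement (`fdr_family = "within_movement"`); `"global"` corrects across
#' electrodes and movements jointly, which controls the family-wise rate of
#' the whole selection map under a global null.
#'
#' An electrode is *selected* when it is significant for at least one
#' movement.
#'
#' @param means Trials x electrodes matrix of per-trial mean activity.
#' @param labels Trial labels; `"rest"` marks rest trials, every other value
#'   is a movement.
#' @param n_perm Number of label permutations (default 10000).
#' @param alpha FDR level (default 0.05).
#' @param seed Integer seed for the permutation draw.
#' @param fdr_family `"within_movement"` (default) or `"global"`.
#' @return A `selection_result`: list with matrices `r2`, `pvals`, `sig`
#'   (electrodes x movements), logical vector `selected`, and the parameters.
#' @export
permutation_fdr <- function(means, labels, n_perm = 10000L, alpha = 0.05,
                            seed = NULL,
                            fdr_family = c("within_movement", "global")) {
  fdr_family <- match.arg(fdr_family)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  movements <- sort(setdiff(unique(labels), "rest"))
  n_el <- ncol(means)
  r2 <- p <- matrix(NA_real_, n_el, length(movements),
                    dimnames = list(NULL, movements))
  with_seed(seed, {
    for (mi in seq_along(movements)) {
      mv <- movements[mi]
      keep <- labels %in% c(mv, "rest")
      y <- as.numeric(labels[keep] == mv)
      m <- means[keep, , drop = FALSE]
      obs <- movement_r2(means, labels, mv)

      # all permutations at once: r2 = cor(shuffled design, means)^2
      yp <- replicate(n_perm, sample(y))
      rp <- suppressWarnings(stats::cor(yp, m))
      rp[!is.finite(rp)] <- 0
      r2p <- rp^2 # n_perm x n_el
      exceed <- colSums(r2p >= matrix(obs, n_perm, n_el, byrow = TRUE))
      r2[, mi] <- unname(obs)
      p[, mi] <- unname(1 + exceed) / (n_perm + 1)
    }
  })
  if (fdr_family == "within_movement") {
    sig <- apply(p, 2, function(col) stats::p.adjust(col, "BH") <= alpha)
    sig <- matrix(sig, n_el, length(movements), dimnames = dimnames(p))
  } else {
    adj <- stats::p.adjust(as.numeric(p), "BH")
    sig <- matrix(adj <= alpha, n_el, length(movements), dimnames = dimnames(p))
  }
  structure(
    list(r2 = r2, pvals = p, sig = sig, selected = rowSums(sig) > 0,
         alpha = alpha, n_perm = as.integer(n_perm), fdr_family = fdr_family,
         movements = movements),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %d electrodes x %d movements; %d selected (alpha=%g, %d perms, FDR %s)\n",
    nrow(x$r2), ncol(x$r2), sum(x$selected), x$alpha, x$n_perm, x$fdr_family))
  invisible(x)
}
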