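# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately written with different algorithms than the
# package code paths they check.

# Short-time-Fourier band log-power oracle: a sliding windowed DFT computed
# directly in the time domain (no FFT, no padding, no decimation machinery),
# with a single fixed Gaussian window whose width matches the wavelet bank's
# averaging time at the band centre ("matched windows"). Per-frequency power
# at 1 Hz spacing is converted to dB and averaged over the band, mirroring
# the package's bin-then-average order. Returns the window-centre sample
# indices and the oracle series.
stft_band_logpower <- function(x, fs, f_lo = 60, f_hi = 130,
                               hop_s = 0.02, fwhm_cycles = 4) {
  f0 <- (f_lo + f_hi) / 2
  sigma_t <- fwhm_cycles / f0 / (2 * sqrt(2 * log(2)))
  half <- ceiling(4 * sigma_t * fs)
  tt <- (-half:half) / fs
  w <- exp(-tt^2 / (2 * sigma_t^2))
  freqs <- seq(f_lo, f_hi, by = 1)
  E <- w * exp(-2i * pi * outer(tt, freqs))  # windowed exponentials, col per f
  hop <- max(1L, round(hop_s * fs))
  centers <- seq(half + 1L, length(x) - half, by = hop)
  segs <- vapply(centers, function(c) x[(c - half):(c + half)],
                 numeric(2L * half + 1L))
  p <- Mod(crossprod(segs, E))^2             # frames x frequencies
  list(centers = centers, values = rowMeans(10 * log10(p + 1e-300)))
}

# Direct-convolution moving-average oracle (edge-truncated), O(n * w).
boxcar_oracle <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

# Naive leave-one-trial-out template matching through the public
# single-trial API (loop over trials, rebuild templates each time).
naive_loocv_acc <- function(tensor, mode) {
  n <- length(tensor$labels)
  preds <- integer(n)
  for (i in seq_len(n)) {
    tpl <- build_templates(tensor, train = setdiff(seq_len(n), i), mode = mode)
    trial <- tensor$data[i, , ]
    if (is.null(dim(trial))) trial <- matrix(trial, ncol = 1L)
    preds[i] <- classify_trial(trial, tpl)
  }
  mean(preds == tensor$labels)
}

# Naive convergence diagnostic from stored subsets/accuracies: rebuild the
# running mean-accuracy patterns and average pairwise correlations directly.
naive_convergence <- function(map) {
  n_el <- length(map$mean_acc)
  n_it <- map$n_iter
  acc_sum <- counts <- numeric(n_el)
  pats <- matrix(0, n_el, n_it)
  for (i in seq_len(n_it)) {
    s <- map$subsets[[i]]
    acc_sum[s] <- acc_sum[s] + map$accs[i]
    counts[s] <- counts[s] + 1
    pats[, i] <- ifelse(counts > 0, acc_sum / pmax(counts, 1), 0)
  }
  curve <- rep(NA_real_, n_it - 1L)
  for (i in seq_len(n_it - 1L)) {
    cs <- vapply((i + 1L):n_it, function(j) {
      suppressWarnings(stats::cor(pats[, i], pats[, j]))
    }, numeric(1))
    cs <- cs[!is.na(cs)]
    if (stats::sd(pats[, i]) > 0 && length(cs)) curve[i] <- mean(cs)
  }
  curve
}

# Build an hfb_envelope object directly: baseline Gaussian noise with
# per-class additive bumps on chosen electrodes during active windows.
# Cheap, bypasses the signal chain; for classification-stage tests.
make_test_env <- function(n_el = 6, trials_per_class = 4, rest_trials = 4,
                          n_classes = 4, fs = 32, cue_s = 1, iti_s = 1,
                          effect = 2, effect_electrodes = NULL, noise_sd = 1,
                          seed = 1, layout = NULL) {
  set.seed(seed)
  classes <- paste0("class_", seq_len(n_classes))
  labels <- sample(c(rep(classes, each = trials_per_class),
                     rep("rest", rest_trials)))
  n_tr <- length(labels)
  slot <- round(fs * (cue_s + iti_s))
  cue <- round(fs * cue_s)
  lead <- round(fs)
  n <- lead + n_tr * slot + 2 * round(fs * max(0, 2 - cue_s - iti_s)) +
    round(fs * 2)
  onsets <- lead + (seq_len(n_tr) - 1L) * slot + 1L
  if (is.null(effect_electrodes)) {
    # one dedicated electrode per class, cycling if needed
    effect_electrodes <- lapply(seq_len(n_classes),
                                function(k) ((k - 1L) %% n_el) + 1L)
  }
  power <- matrix(stats::rnorm(n_el * n, sd = noise_sd), n_el, n)
  for (j in seq_len(n_tr)) {
    k <- match(labels[j], classes)
    if (is.na(k)) next
    idx <- onsets[j]:(onsets[j] + cue - 1L)
    for (e in effect_electrodes[[k]]) {
      power[e, idx] <- power[e, idx] + effect
    }
  }
  if (is.null(layout)) layout <- grid_layout(1, n_el, 4)
  structure(
    list(power = power, fs = fs, hop = 1L, fs_signal = fs, layout = layout,
         events = data.frame(onset_sample = as.integer(onsets),
                             duration_samples = as.integer(cue),
                             label = labels, stringsAsFactors = FALSE),
         f_lo = 60, f_hi = 130, bin_hz = 1, fwhm_cycles = 4),
    class = "hfb_envelope"
  )
}

# Gaussian trial-feature tensor with class-specific patterns: the j-th
# informative electrode responds (mean + effect) to class ((j-1) mod C) + 1
# and stays at baseline otherwise; all other electrodes are pure noise.
make_test_tensor <- function(n_el = 16, trials_per_class = 20, n_classes = 4,
                             informative = 1, effect = 3, seed = 1,
                             layout = NULL, n_time = 1) {
  set.seed(seed)
  labels <- rep(seq_len(n_classes), each = trials_per_class)
  n <- length(labels)
  data <- array(stats::rnorm(n * n_el * n_time), c(n, n_el, n_time))
  for (j in seq_along(informative)) {
    cls <- ((j - 1L) %% n_classes) + 1L
    e <- informative[j]
    data[labels == cls, e, ] <- data[labels == cls, e, ] + effect
  }
  trial_tensor(data, labels, layout = layout)
}

tiny_grid_run <- function(n_rows = 2, n_cols = 2, trials_per_class = 3,
                          rest_trials = 3, effect_db = 0, seed = 1, ...) {
  centers <- list(c(1, 1), c(1, n_cols), c(n_rows, 1), c(n_rows, n_cols))
  generate_run(sim_config(layout = grid_layout(n_rows, n_cols, 4),
                          class_centers = centers,
                          trials_per_class = trials_per_class,
                          rest_trials = rest_trials, effect_db = effect_db,
                          seed = seed, ...))
}
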