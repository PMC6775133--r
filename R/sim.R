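#' Simulation configuration for synthetic high-density ECoG runs
#'
#' Bundles the design of a single recording run: a cued movement task with
#' `n_classes` movement conditions plus rest, trials in one pseudorandom
#' order, a 1/f background, shared line noise, and class-specific
#' high-frequency-band (HFB) amplitude increases that are spatially clustered
#' on the electrode grid.
#'
#' The defaults reproduce a typical high-density recording: 20 trials per
#' movement class plus 20 rest trials, 1500 ms visual cues, a 1500 ms
#' inter-trial interval, 512 Hz sampling and an 8 x 8 grid with 4 mm
#' inter-electrode distance (a 2000 Hz / 128-channel / 3 mm variant is a
#' matter of changing `sampling_rate_hz` and `layout`).
#'
#' @param sampling_rate_hz Sampling rate in Hz (typically 512 or 2000).
#' @param layout A [grid_layout()]; default 8 x 8 at 4 mm.
#' @param n_classes Number of movement classes (default 4).
#' @param trials_per_class Movement trials per class (default 20).
#' @param rest_trials Number of rest trials (default 20).
#' @param cue_duration_s Cue (active) duration in seconds (default 1.5).
#' @param iti_s Inter-trial interval in seconds (default 1.5).
#' @param line_freq_hz Power-line frequency in Hz (default 50).
#' @param line_amp Amplitude of the fundamental line component in units of
#'   the background standard deviation (harmonics at 1/2 and 1/4 of this);
#'   0 disables line noise.
#' @param class_centers List of `c(row, col)` grid positions, one per class,
#'   marking the centre of that class's HFB response. Default: four
#'   quadrant positions (only defined for `n_classes = 4`).
#' @param effect_sigma_mm Spatial Gaussian spread (mm) of each class's HFB
#'   amplitude bump.
#' @param effect_db HFB log-power increase, in dB, at the bump centre during
#'   active trials. 0 disables the class effect entirely.
#' @param noise_exponent Spectral slope of the background: power falls as
#'   \eqn{1/f^{\alpha}} with \eqn{\alpha} = `noise_exponent` (default 2,
#'   a typical ECoG broadband slope).
#' @param onset_jitter_s Movement onset jitter: the HFB response of each
#'   active trial starts uniformly 0..`onset_jitter_s` seconds after cue
#'   onset (default 0.2 s).
#' @param bad_channel_fraction Fraction of channels corrupted after synthesis
#'   (see [inject_bad_channels()]); default 0.
#' @param amplitude_uv Overall signal scale (microvolt-like arbitrary units).
#' @param seed Integer seed; identical configurations produce bit-identical
#'   runs.
#'
#' @return An object of class `sim_config`.
#' @seealso [generate_run()]
#' @export
sim_config <- function(sampling_rate_hz = 512,
                       layout = grid_layout(8, 8, 4),
                       n_classes = 4L,
                       trials_per_class = 20L,
                       rest_trials = 20L,
                       cue_duration_s = 1.5,
                       iti_s = 1.5,
                       line_freq_hz = 50,
                       line_amp = 1,
                       class_centers = NULL,
                       effect_sigma_mm = 5,
                       effect_db = 5,
                       noise_exponent = 2,
                       onset_jitter_s = 0.2,
                       bad_channel_fraction = 0,
                       amplitude_uv = 40,
                       seed = 1L) {
  stopifnot(inherits(layout, "grid_layout"))
  stop_if_not_scalar_pos(sampling_rate_hz, "sampling_rate_hz")
  if (trials_per_class < 1L) stop("trials_per_class must be > 0", call. = FALSE)
  if (rest_trials < 0L) stop("rest_trials must be >= 0", call. = FALSE)
  if (cue_duration_s <= 0) stop("cue_duration_s must be > 0", call. = FALSE)
  if (iti_s <= 0) stop("iti_s must be > 0", call. = FALSE)
  if (effect_db < 0) stop("effect_db must be >= 0", call. = FALSE)
  if (bad_channel_fraction < 0 || bad_channel_fraction >= 1) {
    stop("bad_channel_fraction must be in [0, 1)", call. = FALSE)
  }
  n_classes <- as.integer(n_classes)
  if (is.null(class_centers)) {
    if (n_classes != 4L) {
      stop("default class_centers only defined for 4 classes; supply your own",
           call. = FALSE)
    }
    r1 <- max(1L, round(layout$n_rows / 3))
    r2 <- min(layout$n_rows, round(2 * layout$n_rows / 3))
    c1 <- max(1L, round(layout$n_cols / 3))
    c2 <- min(layout$n_cols, round(2 * layout$n_cols / 3))
    class_centers <- list(c(r1, c1), c(r1, c2), c(r2, c1), c(r2, c2))
  }
  if (length(class_centers) != n_classes) {
    stop("class_centers must have one (row, col) entry per class", call. = FALSE)
  }
  class_centers <- lapply(class_centers, as.numeric)
  for (cc in class_centers) {
    if (length(cc) != 2L || cc[1] < 1 || cc[1] > layout$n_rows ||
        cc[2] < 1 || cc[2] > layout$n_cols) {
      stop("class center outside the grid", call. = FALSE)
    }
  }
  structure(
    list(sampling_rate_hz = sampling_rate_hz, layout = layout,
         n_classes = n_classes, trials_per_class = as.integer(trials_per_class),
         rest_trials = as.integer(rest_trials),
         cue_duration_s = cue_duration_s, iti_s = iti_s,
         line_freq_hz = line_freq_hz, line_amp = line_amp,
         class_centers = class_centers, effect_sigma_mm = effect_sigma_mm,
         effect_db = effect_db, noise_exponent = noise_exponent,
         onset_jitter_s = onset_jitter_s,
         bad_channel_fraction = bad_channel_fraction,
         amplitude_uv = amplitude_uv, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Frequency-domain synthesis of one real-valued noise trace of length n.
# `amp` gives the spectral amplitude at each positive FFT bin (length K-1,
# bins 1..K-1 where K = floor(n/2)). Returns the unnormalized trace whose
# expected per-bin power is proportional to amp^2.
spectral_noise <- function(n, amp) {
  k <- length(amp)
  z <- complex(real = stats::rnorm(k), imaginary = stats::rnorm(k)) / sqrt(2)
  spec <- complex(length.out = n)
  spec[2:(k + 1L)] <- amp * z
  spec[n - (0:(k - 1L))] <- Conj(spec[2:(k + 1L)])
  Re(stats::fft(spec, inverse = TRUE)) / n
}

#' Generate a synthetic ECoG recording run
#'
#' Synthesizes a continuous multichannel recording with the statistical
#' structure the downstream analysis assumes: per-channel \eqn{1/f^\alpha}
#' Gaussian background noise, a shared power-line sinusoid (plus harmonics at
#' half and quarter amplitude), and, during each active trial, an additive
#' band-limited (60-130 Hz) noise component, independent across channels,
#' whose amplitude follows a spatial Gaussian centred on that class's grid
#' position. The added component has the same in-band spectral shape as the
#' background, so the per-frequency log-power rise is flat across the band
#' and equals `effect_db` at the bump centre (in expectation). Rest trials
#' and inter-trial intervals carry no class effect.
#'
#' @param config A [sim_config()].
#' @return An object of class `ecog_run`: list with `signal` (channels x
#'   samples matrix), `sampling_rate_hz`, `layout`, `events` (data frame with
#'   `onset_sample`, `duration_samples`, `label`) and `truth` (class centers,
#'   per-channel per-class gains, corrupted channels, seed).
#' @examples
#' run <- generate_run(sim_config(layout = grid_layout(2, 2, 4),
#'                                trials_per_class = 2, rest_trials = 2,
#'                                seed = 7))
#' table(run$events$label)
#' @export
generate_run <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate_hz
  lay <- config$layout
  n_ch <- lay$n_channels
  classes <- paste0("class_", seq_len(config$n_classes))

  n_trials <- config$n_classes * config$trials_per_class + config$rest_trials
  slot <- round(fs * (config$cue_duration_s + config$iti_s))
  lead_in <- round(fs * 1.0)
  tail <- round(fs * 1.0)
  n_samp <- lead_in + n_trials * slot + tail
  cue_samp <- round(fs * config$cue_duration_s)

  band <- c(60, 130)
  if (band[2] >= fs / 2) {
    stop("sampling rate too low for the 60-130 Hz effect band", call. = FALSE)
  }

  with_seed(config$seed, {
    labels <- sample(c(rep(classes, each = config$trials_per_class),
                       rep("rest", config$rest_trials)))
    onsets <- lead_in + (seq_len(n_trials) - 1L) * slot + 1L
    events <- data.frame(onset_sample = as.integer(onsets),
                         duration_samples = as.integer(cue_samp),
                         label = labels, stringsAsFactors = FALSE)

    # spectral template of the background (unit-variance after scaling)
    ng <- next_fast_len(n_samp)
    k_pos <- floor(ng / 2) - 1L
    f_pos <- (1:k_pos) / ng * fs
    # spectrum flattened below 1 Hz (a recording chain's high-pass region)
    amp_bg <- pmax(f_pos, 1)^(-config$noise_exponent / 2)
    # expected variance of spectral_noise with this amp (two hermitian halves)
    norm_bg <- sqrt(2 * sum(amp_bg^2)) / ng
    in_band <- f_pos >= band[1] & f_pos <= band[2]
    amp_fx <- amp_bg * in_band

    # per-channel, per-class amplitude gains from the spatial Gaussian
    pos <- channel_positions(lay)
    gains <- matrix(0, n_ch, config$n_classes)
    g0 <- sqrt(10^(config$effect_db / 10) - 1)
    for (k in seq_len(config$n_classes)) {
      ctr <- config$class_centers[[k]]
      d2 <- ((pos$row - ctr[1])^2 + (pos$col - ctr[2])^2) * lay$spacing_mm^2
      gains[, k] <- g0 * exp(-d2 / (2 * config$effect_sigma_mm^2))
    }
    if (config$effect_db == 0) gains[] <- 0

    line <- numeric(n_samp)
    if (config$line_amp > 0) {
      t_sec <- (seq_len(n_samp) - 1L) / fs
      for (h in 1:3) {
        f_h <- config$line_freq_hz * h
        if (f_h >= fs / 2) break
        a_h <- config$line_amp / 2^(h - 1)
        line <- line + a_h * sin(2 * pi * f_h * t_sec +
                                   stats::runif(1, 0, 2 * pi))
      }
    }
    signal <- matrix(0, n_ch, n_samp)
    for (ch in seq_len(n_ch)) {
      signal[ch, ] <- spectral_noise(ng, amp_bg)[1:n_samp] / norm_bg + line
    }

    # class effects: one independent band-limited stream per affected channel,
    # same spectral shape (and normalizer) as the background so the per-bin
    # power ratio during a trial is exactly 1 + gain^2
    active <- which(events$label != "rest")
    affected <- which(rowSums(gains > 0.02) > 0)
    if (length(active) && length(affected)) {
      ramp_n <- max(1L, round(0.02 * fs))
      ramp <- (1 - cos(pi * seq_len(ramp_n) / ramp_n)) / 2
      jit <- round(stats::runif(length(active), 0, config$onset_jitter_s) * fs)
      for (ch in affected) {
        e <- spectral_noise(ng, amp_fx)[1:n_samp] / norm_bg
        for (j in seq_along(active)) {
          tr <- active[j]
          k <- match(events$label[tr], classes)
          g <- gains[ch, k]
          if (g <= 0.02) next
          i0 <- events$onset_sample[tr] + jit[j]
          i1 <- events$onset_sample[tr] + cue_samp - 1L
          if (i1 <= i0) next
          w <- rep(1, i1 - i0 + 1L)
          nr <- min(ramp_n, length(w) %/% 2)
          if (nr > 0) {
            w[1:nr] <- ramp[seq_len(nr)]
            w[length(w) - (nr:1) + 1L] <- rev(ramp[seq_len(nr)])
          }
          signal[ch, i0:i1] <- signal[ch, i0:i1] + g * w * e[i0:i1]
        }
      }
    }

    signal <- signal * config$amplitude_uv

    run <- structure(
      list(signal = signal, sampling_rate_hz = fs, layout = lay,
           events = events,
           truth = list(class_centers = config$class_centers, gains = gains,
                        effect_db = config$effect_db,
                        bad_channels = integer(0), seed = config$seed)),
      class = "ecog_run"
    )

    if (config$bad_channel_fraction > 0) {
      inj <- inject_bad_channels(run, config$bad_channel_fraction,
                                 mode = "noisy", seed = config$seed + 1L)
      run <- inj$run
    }
    run
  })
}

#' Corrupt a subset of channels of a run
#'
#' Emulates the flat and noisy electrodes that are discarded during
#' preprocessing of clinical recordings. Flat channels are replaced by a
#' constant; noisy channels have their variance multiplied by approximately
#' `var_factor` (100 by default; the added line component interferes with the
#' run's own line noise, so the factor is not exact) and gain strong line
#' noise.
#'
#' @param run An `ecog_run`.
#' @param fraction Fraction of channels to corrupt, in `[0, 1)`.
#' @param mode `"flat"` or `"noisy"`.
#' @param seed Integer seed for the channel draw.
#' @param var_factor Variance multiplier for noisy mode (default 100).
#' @return A list with the modified `run` and the integer vector
#'   `bad_channels` of corrupted channel indices (ground truth).
#' @export
inject_bad_channels <- function(run, fraction, mode = c("flat", "noisy"),
                                seed = NULL, var_factor = 100) {
  stopifnot(inherits(run, "ecog_run"))
  mode <- match.arg(mode)
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)", call. = FALSE)
  n_ch <- nrow(run$signal)
  n_bad <- floor(fraction * n_ch)
  if (n_bad == 0L) {
    return(list(run = run, bad_channels = integer(0)))
  }
  with_seed(seed, {
    bad <- sort(sample(n_ch, n_bad))
    if (mode == "flat") {
      for (ch in bad) run$signal[ch, ] <- mean(run$signal[ch, ])
    } else {
      t_sec <- (seq_len(ncol(run$signal)) - 1L) / run$sampling_rate_hz
      for (ch in bad) {
        s <- stats::sd(run$signal[ch, ])
        run$signal[ch, ] <- run$signal[ch, ] * sqrt(var_factor) +
          10 * s * sin(2 * pi * 50 * t_sec + stats::runif(1, 0, 2 * pi))
      }
    }
    run$truth$bad_channels <- sort(union(run$truth$bad_channels, bad))
    list(run = run, bad_channels = bad)
  })
}

#' @export
print.ecog_run <- function(x, ...) {
  cat(sprintf("<ecog_run> %d channels x %d samples @ %g Hz, %d trials\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate_hz,
              nrow(x$events)))
  print(x$layout)
  invisible(x)
}
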