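#' Detect flat and noisy channels
#'
#' Screens every channel of a run against two exclusion rules used before
#' re-referencing: a channel is *flat* when its sample variance falls below
#' `flat_var_tol`, and *noisy* when its variance exceeds
#' `noisy_var_factor` times the median variance of the non-flat channels, or
#' when its line-band power ratio (power within +/- 1 Hz of the line
#' frequency and its harmonics, relative to the neighbouring 2-5 Hz flanks)
#' exceeds `noisy_line_factor` times the median of that ratio.
#'
#' The rules are deterministic; thresholds are configuration, not estimates.
#'
#' @param run An `ecog_run`.
#' @param flat_var_tol Absolute variance below which a channel is flat.
#' @param noisy_var_factor Multiple of the median channel variance above
#'   which a channel is noisy.
#' @param noisy_line_factor Multiple of the median line-band power ratio
#'   above which a channel is noisy.
#' @param line_freq_hz Line frequency used for the line-band rule.
#' @return A `channel_mask`: data frame with columns `channel`, `included`,
#'   `reason` (`"none"`, `"flat"` or `"noisy"`).
#' @export
detect_bad_channels <- function(run, flat_var_tol = 1e-8,
                                noisy_var_factor = 10,
                                noisy_line_factor = 10,
                                line_freq_hz = 50) {
  stopifnot(inherits(run, "ecog_run"))
  stop_if_not_scalar_pos(flat_var_tol, "flat_var_tol")
  stop_if_not_scalar_pos(noisy_var_factor, "noisy_var_factor")
  stop_if_not_scalar_pos(noisy_line_factor, "noisy_line_factor")
  x <- run$signal
  fs <- run$sampling_rate_hz
  n_ch <- nrow(x)
  v <- apply(x, 1, stats::var)
  reason <- rep("none", n_ch)
  reason[v < flat_var_tol] <- "flat"

  ok <- reason == "none"
  med_v <- stats::median(v[ok])
  reason[ok & v > noisy_var_factor * med_v] <- "noisy"

  # line-band power ratio per channel (periodogram band means);
  # zero-pad to a 5-smooth length so the FFT stays fast for any run length
  n <- next_fast_len(ncol(x))
  fbin <- (seq_len(n) - 1L) / n * fs
  harmonics <- line_freq_hz * (1:3)
  harmonics <- harmonics[harmonics < fs / 2]
  line_mask <- rep(FALSE, n)
  flank_mask <- rep(FALSE, n)
  for (f0 in harmonics) {
    line_mask <- line_mask | (abs(fbin - f0) <= 1)
    flank_mask <- flank_mask | (abs(fbin - f0) > 2 & abs(fbin - f0) <= 5)
  }
  if (any(line_mask) && any(flank_mask)) {
    ratio <- rep(NA_real_, n_ch)
    for (ch in seq_len(n_ch)) {
      p <- Mod(stats::fft(c(x[ch, ], numeric(n - ncol(x)))))^2
      ratio[ch] <- mean(p[line_mask]) / mean(p[flank_mask])
    }
    ok <- reason == "none"
    med_r <- stats::median(ratio[ok])
    reason[ok & ratio > noisy_line_factor * med_r] <- "noisy"
  }

  if (sum(reason == "none") < 2L) {
    stop("fewer than 2 channels remain included", call. = FALSE)
  }
  structure(
    data.frame(channel = seq_len(n_ch), included = reason == "none",
               reason = reason, stringsAsFactors = FALSE),
    class = c("channel_mask", "data.frame")
  )
}

#' Channel mask constructor
#'
#' @param included Logical vector, one entry per channel.
#' @param reason Optional character vector of exclusion reasons.
#' @return A `channel_mask` data frame.
#' @export
channel_mask <- function(included, reason = NULL) {
  included <- as.logical(included)
  if (sum(included) < 2L) stop("a channel mask must keep >= 2 channels", call. = FALSE)
  if (is.null(reason)) reason <- ifelse(included, "none", "noisy")
  structure(
    data.frame(channel = seq_along(included), included = included,
               reason = reason, stringsAsFactors = FALSE),
    class = c("channel_mask", "data.frame")
  )
}

# Squared magnitude response of an IIR filter (b, a) at normalized digital
# frequencies w (radians/sample). This is the response a forward-backward
# (zero-phase) application of the filter realizes.
iir_mag2 <- function(b, a, w) {
  z <- exp(complex(imaginary = -w))
  num <- 0 + 0i
  den <- 0 + 0i
  zk <- rep(1 + 0i, length(w))
  for (k in seq_along(b)) {
    num <- num + b[k] * zk
    if (k <= length(a)) den <- den + a[k] * zk
    zk <- zk * z
  }
  for (k in seq.int(length(b) + 1L, length.out = max(0L, length(a) - length(b)))) {
    den <- den + a[k] * zk
    zk <- zk * z
  }
  Mod(num / den)^2
}

#' Notch-filter line noise and its harmonics
#'
#' Applies a zero-phase second-order Butterworth band-stop of width
#' `bandwidth_hz` around `line_freq_hz` and each requested harmonic. The
#' filter is designed with [signal::butter()] and applied as its
#' forward-backward (squared-magnitude, phase-free) response via FFT on the
#' zero-padded recording, which is exact for the zero-phase cascade and fast
#' for long multichannel runs. Attenuation at each notch centre exceeds
#' 40 dB; the passband is flat within 1 dB outside the stop bands. Harmonics
#' at or above the Nyquist frequency are skipped with a warning.
#'
#' @param run An `ecog_run`.
#' @param line_freq_hz Line frequency in Hz.
#' @param n_harmonics Number of harmonics to remove (fundamental counts as
#'   the first).
#' @param bandwidth_hz Stop-band width per notch, in Hz.
#' @return The filtered `ecog_run`.
#' @export
notch_filter <- function(run, line_freq_hz = 50, n_harmonics = 3,
                         bandwidth_hz = 1) {
  stopifnot(inherits(run, "ecog_run"))
  stop_if_not_scalar_pos(line_freq_hz, "line_freq_hz")
  stop_if_not_scalar_pos(bandwidth_hz, "bandwidth_hz")
  fs <- run$sampling_rate_hz
  n <- ncol(run$signal)
  pad <- round(fs) # room for the notch ringing (~1/bandwidth seconds)
  L <- next_fast_len(n + 2L * pad)
  w <- 2 * pi * (0:(L %/% 2)) / L # normalized freq of the positive FFT bins
  gain <- rep(1, length(w))
  any_notch <- FALSE
  for (h in seq_len(n_harmonics)) {
    f0 <- line_freq_hz * h
    if (f0 + bandwidth_hz / 2 >= fs / 2) {
      warning(sprintf("harmonic %g Hz at or above Nyquist (%g Hz); skipped",
                      f0, fs / 2))
      next
    }
    bf <- signal::butter(2, c(f0 - bandwidth_hz / 2, f0 + bandwidth_hz / 2) /
                           (fs / 2), type = "stop")
    gain <- gain * iir_mag2(bf$b, bf$a, w)
    any_notch <- TRUE
  }
  if (!any_notch) return(run)
  full_gain <- c(gain, rev(gain[2:(L - length(w) + 1L)]))
  for (ch in seq_len(nrow(run$signal))) {
    X <- stats::fft(c(run$signal[ch, ], numeric(L - n)))
    run$signal[ch, ] <- Re(stats::fft(X * full_gain, inverse = TRUE))[1:n] / L
  }
  run
}

#' Common-average re-referencing
#'
#' Subtracts, at every sample, the mean over the included channels from each
#' included channel. Excluded channels are passed through untouched. After
#' re-referencing the mean of the included channels is zero at every sample,
#' and the operation is idempotent.
#'
#' @param run An `ecog_run`.
#' @param mask Optional [channel_mask()]; default includes every channel.
#' @return The re-referenced `ecog_run`.
#' @export
common_average_rereference <- function(run, mask = NULL) {
  stopifnot(inherits(run, "ecog_run"))
  inc <- if (is.null(mask)) rep(TRUE, nrow(run$signal)) else mask$included
  if (length(inc) != nrow(run$signal)) {
    stop("mask length does not match channel count", call. = FALSE)
  }
  if (sum(inc) < 2L) stop("common average needs >= 2 included channels", call. = FALSE)
  avg <- colMeans(run$signal[inc, , drop = FALSE])
  run$signal[inc, ] <- sweep(run$signal[inc, , drop = FALSE], 2, avg, "-")
  run
}
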