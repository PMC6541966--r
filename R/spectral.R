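#' Spectral estimation settings
#'
#' Windowed PSD estimation: Hanning-tapered segments of `window_samples`
#' samples (a power of two) with fractional `overlap`, one-sided
#' periodograms normalized so that the PSD integrates to signal power,
#' restriction to `freq_range_hz`, conversion to decibels as
#' `10*log10(max(psd, db_floor))`, and Gaussian smoothing along the frequency
#' axis with a window of `smooth_width_bins` bins (a Gaussian taper of that
#' length, `gausswin` convention `sigma = (L - 1)/5`; width 0 or 1 disables
#' smoothing). The kernel has unit mass and is renormalized where it
#' overhangs the edges of the retained range, so a frequency-flat row is
#' left unchanged.
#'
#' @param window_samples Samples per window, a power of two (default 1024,
#'   i.e. ~0.977 Hz bins at 1 kHz sampling).
#' @param overlap Fractional window overlap in `[0, 1)` (default 0.5).
#' @param freq_range_hz Two-element retained frequency range, Hz.
#' @param db_floor Power floor applied before the logarithm.
#' @param smooth_width_bins Gaussian smoothing window length in frequency
#'   bins (odd; 0 or 1 disables smoothing).
#' @return A `spectral_config` object.
#' @export
spectral_config <- function(window_samples = 1024L, overlap = 0.5,
                            freq_range_hz = c(2, 45), db_floor = 1e-12,
                            smooth_width_bins = 3L) {
  window_samples <- as.integer(window_samples)
  if (window_samples < 2L || bitwAnd(window_samples, window_samples - 1L) != 0L) {
    stop("configuration error: `window_samples` must be a power of two",
         call. = FALSE)
  }
  if (overlap < 0 || overlap >= 1) {
    stop("configuration error: `overlap` must be in [0, 1)", call. = FALSE)
  }
  if (length(freq_range_hz) != 2L || freq_range_hz[1] >= freq_range_hz[2]) {
    stop("configuration error: `freq_range_hz` must be an increasing pair",
         call. = FALSE)
  }
  smooth_width_bins <- as.integer(smooth_width_bins)
  if (smooth_width_bins > 1L && smooth_width_bins %% 2L == 0L) {
    stop("configuration error: `smooth_width_bins` must be odd (or 0/1 to ",
         "disable smoothing)", call. = FALSE)
  }
  structure(list(window_samples = window_samples, overlap = overlap,
                 freq_range_hz = as.double(freq_range_hz),
                 db_floor = db_floor,
                 smooth_width_bins = smooth_width_bins),
            class = "spectral_config")
}

hanning_taper <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))

#' Welch-style linear power spectral density matrix
#'
#' The per-window one-sided periodogram before any dB conversion or
#' smoothing: window `i` covering samples `s..s+N-1` contributes row `i` with
#' PSD `c * |FFT(w * x)|^2 / (fs * sum(w^2))` where `c` is 2 except at DC and
#' Nyquist, `w` the Hanning taper. Partial trailing windows are dropped.
#'
#' @param recording An [lfp_recording()].
#' @param config A [spectral_config()]; only `window_samples` and `overlap`
#'   are used, the full 0..Nyquist axis is returned.
#' @return List with `time_s` (window-center times), `freq_hz` (bin centers
#'   `0..Nyquist`, spacing `fs / window_samples`), and `psd` (time x
#'   frequency matrix, units^2 per Hz).
#' @export
welch_psd <- function(recording, config = spectral_config()) {
  stopifnot(inherits(recording, "lfp_recording"))
  x <- recording$samples
  fs <- recording$sampling_rate
  nwin <- config$window_samples
  if (length(x) < nwin) {
    stop("recording shorter than one analysis window (", nwin, " samples)",
         call. = FALSE)
  }
  hop <- max(1L, as.integer(round(nwin * (1 - config$overlap))))
  starts <- seq.int(1L, length(x) - nwin + 1L, by = hop)
  w <- hanning_taper(nwin)
  u <- sum(w^2)
  nfreq <- nwin %/% 2L + 1L
  one_sided_scale <- c(1, rep(2, nfreq - 2L), 1) / (fs * u)
  psd <- matrix(0, nrow = length(starts), ncol = nfreq)
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + nwin - 1L)] * w
    sp <- fft(seg)[seq_len(nfreq)]
    psd[i, ] <- (Re(sp)^2 + Im(sp)^2) * one_sided_scale
  }
  list(time_s = (starts - 1L + (nwin - 1L) / 2) / fs,
       freq_hz = (seq_len(nfreq) - 1L) * fs / nwin,
       psd = psd)
}

# Gaussian taper of `width` points, gausswin convention (alpha = 2.5,
# i.e. sigma = (width - 1)/5), normalized to unit sum.
gaussian_kernel <- function(width) {
  half <- (width - 1L) %/% 2L
  sigma <- (width - 1) / 5
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

# Smooth each row along frequency; kernel renormalized where it overhangs
# the edges so a constant row stays constant.
smooth_rows <- function(m, width) {
  if (width <= 1L) return(m)
  k <- gaussian_kernel(width)
  half <- (length(k) - 1L) %/% 2L
  nc <- ncol(m)
  out <- matrix(0, nrow(m), nc)
  norm <- as.double(stats::filter(rep(1, nc), k, sides = 2))
  for (i in seq_len(nrow(m))) {
    sm <- as.double(stats::filter(m[i, ], k, sides = 2))
    # stats::filter leaves NA where the kernel overhangs; redo edges by hand
    for (j in which(is.na(sm))) {
      lo <- max(1L, j - half); hi <- min(nc, j + half)
      kk <- k[(lo - j + half + 1L):(hi - j + half + 1L)]
      sm[j] <- sum(m[i, lo:hi] * kk) / sum(kk)
    }
    na <- is.na(norm)
    sm[!na] <- sm[!na] / norm[!na]
    out[i, ] <- sm
  }
  out
}

#' Time-frequency power matrix in decibels
#'
#' Runs [welch_psd()], restricts bins to `freq_range_hz` (bin centers with
#' `low <= f <= high`), converts to decibels with the configured power floor,
#' and smooths along the frequency axis with the configured Gaussian kernel.
#'
#' @inheritParams welch_psd
#' @return An `lfp_spectrogram` object: `time_s`, `freq_hz`, `power_db`
#'   (time x frequency matrix), and the `config` used.
#' @export
lfp_spectrogram <- function(recording, config = spectral_config()) {
  wp <- welch_psd(recording, config)
  keep <- wp$freq_hz >= config$freq_range_hz[1] &
    wp$freq_hz <= config$freq_range_hz[2]
  if (!any(keep)) {
    stop("no frequency bins inside freq_range_hz; widen the range or the window",
         call. = FALSE)
  }
  db <- 10 * log10(pmax(wp$psd[, keep, drop = FALSE], config$db_floor))
  db <- smooth_rows(db, config$smooth_width_bins)
  structure(list(time_s = wp$time_s, freq_hz = wp$freq_hz[keep],
                 power_db = db, config = config),
            class = "lfp_spectrogram")
}

#' @export
print.lfp_spectrogram <- function(x, ...) {
  cat(sprintf("<lfp_spectrogram> %d windows x %d bins (%.2f-%.2f Hz), %.3f-%.3f s\n",
              nrow(x$power_db), ncol(x$power_db), min(x$freq_hz),
              max(x$freq_hz), min(x$time_s), max(x$time_s)))
  invisible(x)
}

#' Mean PSD over a time window
#'
#' Arithmetic mean (in dB) of the spectrogram rows whose window-center times
#' fall inside the half-open interval `[start, end)`.
#'
#' @param spectrogram An [lfp_spectrogram()].
#' @param time_window_s Two-element interval `c(start, end)` in seconds.
#' @return Named numeric vector over the spectrogram's frequency bins.
#' @export
mean_psd <- function(spectrogram, time_window_s) {
  stopifnot(inherits(spectrogram, "lfp_spectrogram"),
            length(time_window_s) == 2L)
  rows <- spectrogram$time_s >= time_window_s[1] &
    spectrogram$time_s < time_window_s[2]
  if (!any(rows)) {
    stop("empty phase: no window centers inside [", time_window_s[1], ", ",
         time_window_s[2], ") s", call. = FALSE)
  }
  setNames(colMeans(spectrogram$power_db[rows, , drop = FALSE]),
           format(spectrogram$freq_hz))
}

#' Long-format export of a spectrogram
#'
#' @param spectrogram An [lfp_spectrogram()].
#' @return data.frame with columns `time_s`, `freq_hz`, `power_db`.
#' @export
spectrogram_table <- function(spectrogram) {
  data.frame(
    time_s = rep(spectrogram$time_s, times = length(spectrogram$freq_hz)),
    freq_hz = rep(spectrogram$freq_hz, each = length(spectrogram$time_s)),
    power_db = as.vector(spectrogram$power_db))
}
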