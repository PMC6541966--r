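#' Band-pass filter specification
#'
#' Butterworth band-pass applied forward and backward (zero phase). `order`
#' is the total pole count of the band-pass design and must be even; the
#' default order-4 design applied forward-backward has the squared magnitude
#' of the one-pass filter, i.e. an 8th-order-like roll-off.
#'
#' @param low_hz,high_hz Pass-band edges in Hz (0 < low < high < Nyquist).
#' @param order Total number of poles of the band-pass design (even, >= 2).
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(low_hz = 2, high_hz = 45, order = 4L) {
  if (!(low_hz > 0 && high_hz > low_hz)) {
    stop("configuration error: need 0 < low_hz < high_hz", call. = FALSE)
  }
  order <- as.integer(order)
  if (order < 2L || order %% 2L != 0L) {
    stop("configuration error: `order` must be an even integer >= 2",
         call. = FALSE)
  }
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 family = "butterworth", mode = "zero-phase"),
            class = "filter_spec")
}

butter_coefs <- function(spec, sampling_rate) {
  nyq <- sampling_rate / 2
  if (spec$high_hz >= nyq) {
    stop("configuration error: high_hz (", spec$high_hz,
         " Hz) must be below the Nyquist frequency (", nyq, " Hz)",
         call. = FALSE)
  }
  # butter(n, ., "pass") yields 2n poles; order counts total poles
  signal::butter(spec$order / 2L, c(spec$low_hz, spec$high_hz) / nyq,
                 type = "pass")
}

#' Analytic magnitude response of the zero-phase filter
#'
#' Returns `|H(f)|^2`, the effective gain of the forward-backward
#' application of the designed one-pass filter; this is the oracle against
#' which filtered amplitudes can be checked.
#'
#' @param spec A [filter_spec()].
#' @param freq_hz Frequencies at which to evaluate, Hz.
#' @param sampling_rate Sampling rate of the signal the filter will see, Hz.
#' @return Numeric vector of gains (linear amplitude ratio).
#' @export
filter_response <- function(spec, freq_hz, sampling_rate) {
  ba <- butter_coefs(spec, sampling_rate)
  w <- 2 * pi * freq_hz / sampling_rate
  z <- exp(-1i * w)
  h <- vapply(z, function(zz) {
    num <- sum(ba$b * zz^(seq_along(ba$b) - 1))
    den <- sum(ba$a * zz^(seq_along(ba$a) - 1))
    Mod(num / den)
  }, numeric(1))
  h^2
}

#' Zero-phase Butterworth band-pass of an LFP recording
#'
#' Applies the designed filter forward then backward so the output has no
#' phase lag; the effective magnitude response is the squared one-pass
#' magnitude (see [filter_response()]). Before filtering, the signal is
#' extended on both sides by odd (anti-symmetric) reflection — long enough to
#' let the low-edge transient settle — and the extension is discarded
#' afterwards, so output length equals input length.
#'
#' @param recording An [lfp_recording()].
#' @param spec A [filter_spec()]; defaults to the 2-45 Hz order-4 design.
#' @return A new [lfp_recording()] with filtered samples.
#' @export
lfp_bandpass <- function(recording, spec = filter_spec()) {
  stopifnot(inherits(recording, "lfp_recording"))
  ba <- butter_coefs(spec, recording$sampling_rate)
  x <- recording$samples
  n <- length(x)
  pad <- max(3L * spec$order,
             as.integer(ceiling(3 * recording$sampling_rate / spec$low_hz)))
  pad <- min(pad, n - 1L)
  if (pad < 1L) {
    stop("recording too short to filter (need at least 2 samples)",
         call. = FALSE)
  }
  # odd-symmetric extension: continuous in value and slope at both ends
  left <- 2 * x[1L] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  ext <- c(left, x, right)
  y <- signal::filter(ba$b, ba$a, ext)
  y <- rev(signal::filter(ba$b, ba$a, rev(y)))
  lfp_recording(as.double(y[(pad + 1L):(pad + n)]), recording$sampling_rate,
                channel_id = recording$channel_id, units = recording$units)
}
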