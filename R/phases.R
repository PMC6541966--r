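#' Canonical frequency band definitions
#'
#' Five bands tiling 2-45 Hz: delta \[2,4), theta \[4,9), alpha \[9,15),
#' beta \[15,30), gamma \[30,45\]. A frequency bin belongs to a band iff
#' `low <= f < high`; the last band is closed at 45 Hz so the tiling has no
#' gap at the top edge.
#'
#' @return data.frame with columns `band`, `low_hz`, `high_hz`.
#' @export
band_definitions <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             low_hz = c(2, 4, 9, 15, 30),
             high_hz = c(4, 9, 15, 30, 45))
}

# Columns of `freq_hz` belonging to band row `i`: low <= f < high, except
# that a band reaching the table's top edge is closed there so the tiling
# has no gap. Bands are selected independently, so an extra enclosing row
# (e.g. broadband) may legitimately share bins with the named bands.
band_cols <- function(freq_hz, bands, i) {
  top <- bands$high_hz[i] == max(bands$high_hz)
  which(freq_hz >= bands$low_hz[i] &
          (freq_hz < bands$high_hz[i] |
             (top & freq_hz <= bands$high_hz[i])))
}

#' Segment trials into event-aligned phases
#'
#' For each trial the prestimulus phase is `[onset - prestim_s, onset)`, the
#' stimulus phase `[onset, withdrawal)`, and the poststimulus phase
#' `[withdrawal, withdrawal + poststim_s)`. Trials whose onset is closer than
#' `prestim_s` to the recording start are excluded with a warning. Trials
#' without a withdrawal event get a stimulus phase truncated at
#' `onset + max_stim_s` (the 20 s force-ramp duration) and are flagged.
#'
#' @param events Validated event table (see [event_table()]).
#' @param prestim_s Prestimulus duration, seconds (default 5).
#' @param poststim_s Poststimulus duration, seconds (default 5).
#' @param recording_duration Optional recording length; phase ends are
#'   clipped to it.
#' @param max_stim_s Stimulus-phase cap for trials lacking a withdrawal.
#' @return data.frame of class `phase_windows` with columns `trial_id`,
#'   `phase` (prestimulus/stimulus/poststimulus), `start_s`, `end_s`
#'   (half-open `[start, end)`), `truncated`.
#' @export
segment_phases <- function(events, prestim_s = 5, poststim_s = 5,
                           recording_duration = NULL, max_stim_s = 20) {
  events <- event_table(events, recording_duration = recording_duration)
  rows <- list()
  for (id in unique(events$trial_id)) {
    sub <- events[events$trial_id == id, ]
    onset <- sub$time_s[sub$event == "stimulus_onset"]
    withdrawal <- sub$time_s[sub$event == "paw_withdrawal"]
    if (onset - prestim_s < 0) {
      warning("trial ", id, " excluded: onset at ", onset,
              " s is closer than prestim_s = ", prestim_s,
              " s to the recording start", call. = FALSE)
      next
    }
    truncated <- length(withdrawal) == 0L
    stim_end <- if (truncated) onset + max_stim_s else withdrawal
    ph <- data.frame(
      trial_id = id,
      phase = c("prestimulus", "stimulus", "poststimulus"),
      start_s = c(onset - prestim_s, onset, stim_end),
      end_s = c(onset, stim_end, stim_end + poststim_s),
      truncated = truncated)
    if (!is.null(recording_duration)) {
      ph$end_s <- pmin(ph$end_s, recording_duration)
      ph <- ph[ph$end_s > ph$start_s, , drop = FALSE]
    }
    rows[[id]] <- ph
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("phase_windows", "data.frame")
  out
}

# PSD rows (dB) for one phase: normally the spectrogram rows whose centers
# fall in [start, end); a phase too short to contain any window center is
# recomputed from the raw recording with a single shorter window (largest
# power of two <= phase length, at least `min_window` samples).
phase_rows_db <- function(spectrogram, start_s, end_s, recording = NULL,
                          min_window = 256L) {
  sel <- spectrogram$time_s >= start_s & spectrogram$time_s < end_s
  if (any(sel)) {
    return(list(db = spectrogram$power_db[sel, , drop = FALSE],
                freq_hz = spectrogram$freq_hz))
  }
  if (is.null(recording)) return(NULL)
  n_avail <- floor((end_s - start_s) * recording$sampling_rate)
  if (n_avail < min_window) return(NULL)
  win <- 2L^floor(log2(n_avail))
  i0 <- floor(start_s * recording$sampling_rate) + 1L
  seg <- lfp_recording(recording$samples[i0:(i0 + win - 1L)],
                       recording$sampling_rate)
  cfg <- spectrogram$config
  cfg$window_samples <- win
  sub <- lfp_spectrogram(seg, cfg)
  list(db = sub$power_db, freq_hz = sub$freq_hz)
}

#' Mean band power per trial and phase
#'
#' For each trial x phase x band, the mean of the spectrogram cells (dB)
#' whose window-center time lies in the phase window and whose bin frequency
#' lies in the band. Phases that contain no spectrogram window center are
#' recomputed from `recording` with a single shorter window (power of two,
#' >= 256 samples); phases shorter than that are dropped with a warning.
#'
#' @param spectrogram An [lfp_spectrogram()].
#' @param phases A `phase_windows` table from [segment_phases()].
#' @param bands Band definitions (see [band_definitions()]).
#' @param recording Optional raw/filtered [lfp_recording()] backing the
#'   spectrogram, enabling the short-phase fallback.
#' @return data.frame with columns `trial_id`, `phase`, `band`,
#'   `mean_psd_db`; one row per trial x phase x band that had usable data.
#' @export
band_phase_means <- function(spectrogram, phases, bands = band_definitions(),
                             recording = NULL) {
  stopifnot(inherits(spectrogram, "lfp_spectrogram"))
  out <- list()
  for (i in seq_len(nrow(phases))) {
    rows <- phase_rows_db(spectrogram, phases$start_s[i], phases$end_s[i],
                          recording = recording)
    if (is.null(rows)) {
      warning("trial ", phases$trial_id[i], " phase ", phases$phase[i],
              " dropped: no usable analysis window", call. = FALSE)
      next
    }
    m <- vapply(seq_len(nrow(bands)), function(b) {
      cols <- band_cols(rows$freq_hz, bands, b)
      if (!length(cols)) return(NA_real_)
      mean(rows$db[, cols])
    }, numeric(1))
    out[[i]] <- data.frame(trial_id = phases$trial_id[i],
                           phase = phases$phase[i],
                           band = bands$band, mean_psd_db = unname(m))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean band power over occupancy intervals
#'
#' Same contract as [band_phase_means()] but pooling an arbitrary set of
#' half-open time intervals (e.g. all visits to one compartment of a
#' conditioned-place-aversion box) into a single mean per band.
#'
#' @param spectrogram An [lfp_spectrogram()].
#' @param intervals Two-column matrix or data.frame of `[start, end)` times
#'   in seconds (one row per interval).
#' @param bands Band definitions.
#' @param label Value for the output `phase` column.
#' @return data.frame with columns `phase`, `band`, `mean_psd_db`.
#' @export
compartment_phase_means <- function(spectrogram, intervals,
                                    bands = band_definitions(),
                                    label = "compartment") {
  stopifnot(inherits(spectrogram, "lfp_spectrogram"))
  intervals <- as.matrix(as.data.frame(intervals)[, 1:2])
  sel <- rep(FALSE, length(spectrogram$time_s))
  for (i in seq_len(nrow(intervals))) {
    sel <- sel | (spectrogram$time_s >= intervals[i, 1] &
                    spectrogram$time_s < intervals[i, 2])
  }
  if (!any(sel)) {
    stop("empty phase: no window centers inside the given intervals",
         call. = FALSE)
  }
  db <- spectrogram$power_db[sel, , drop = FALSE]
  m <- vapply(seq_len(nrow(bands)), function(b) {
    cols <- band_cols(spectrogram$freq_hz, bands, b)
    if (!length(cols)) return(NA_real_)
    mean(db[, cols])
  }, numeric(1))
  data.frame(phase = label, band = bands$band, mean_psd_db = unname(m))
}
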