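# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: explicit DFT sums instead of fft-based PSD,
# explicit loops instead of vectorized sums of squares.

# One-sided PSD of a single window by direct DFT summation (O(N^2)).
naive_psd_row <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  xw <- x * w
  nf <- n %/% 2 + 1
  out <- numeric(nf)
  ang <- 2 * pi * (0:(n - 1)) / n
  for (k in 0:(nf - 1)) {
    re <- sum(xw * cos(k * ang))
    im <- sum(xw * sin(k * ang))
    out[k + 1] <- re^2 + im^2
  }
  out * c(1, rep(2, nf - 2), 1) / (fs * sum(w^2))
}

# One-way rm ANOVA F by explicit loops over cells.
loop_oneway_F <- function(df) {
  subjects <- unique(df$subject)
  conditions <- unique(df$condition)
  n <- length(subjects); k <- length(conditions)
  g <- mean(df$value)
  ss_cond <- 0
  for (cc in conditions) {
    ss_cond <- ss_cond + n * (mean(df$value[df$condition == cc]) - g)^2
  }
  ss_subj <- 0
  for (s in subjects) {
    ss_subj <- ss_subj + k * (mean(df$value[df$subject == s]) - g)^2
  }
  ss_tot <- 0
  for (i in seq_len(nrow(df))) ss_tot <- ss_tot + (df$value[i] - g)^2
  ss_err <- ss_tot - ss_cond - ss_subj
  (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
}

# Mixed-design sums of squares and F statistics by explicit loops.
loop_mixed_F <- function(df) {
  groups <- unique(df$group); times <- unique(df$time)
  subjects <- unique(df$subject)
  a <- length(groups); t_ <- length(times)
  n <- length(subjects) / a
  g <- mean(df$value)
  ss_between <- 0
  for (s in subjects) {
    ss_between <- ss_between + t_ * (mean(df$value[df$subject == s]) - g)^2
  }
  ss_group <- 0
  for (gr in groups) {
    ss_group <- ss_group + n * t_ * (mean(df$value[df$group == gr]) - g)^2
  }
  ss_time <- 0
  for (tp in times) {
    ss_time <- ss_time + a * n * (mean(df$value[df$time == tp]) - g)^2
  }
  ss_cells <- 0
  for (gr in groups) for (tp in times) {
    m <- mean(df$value[df$group == gr & df$time == tp])
    ss_cells <- ss_cells + n * (m - g)^2
  }
  ss_tot <- 0
  for (i in seq_len(nrow(df))) ss_tot <- ss_tot + (df$value[i] - g)^2
  ss_sw <- ss_between - ss_group
  ss_int <- ss_cells - ss_group - ss_time
  ss_err <- ss_tot - ss_between - ss_time - ss_int
  c(group = (ss_group / (a - 1)) / (ss_sw / (a * (n - 1))),
    time = (ss_time / (t_ - 1)) / (ss_err / ((t_ - 1) * a * (n - 1))),
    interaction = (ss_int / ((a - 1) * (t_ - 1))) /
      (ss_err / ((t_ - 1) * a * (n - 1))))
}

# Hand-rolled spectrogram container for unit tests of the averaging layers.
make_spectrogram <- function(power_db, time_s, freq_hz,
                             config = spectral_config()) {
  structure(list(time_s = time_s, freq_hz = freq_hz,
                 power_db = power_db, config = config),
            class = "lfp_spectrogram")
}

# Small, fast session: short epochs, few trials.
quick_session <- function(seed = 1, n_trials = 4, noise_scale = 1,
                          band_schedules = default_band_schedules("null"),
                          ...) {
  session_config(n_trials = n_trials, noise_scale = noise_scale,
                 withdrawal_latency_range = c(2, 4), poststim_duration = 2,
                 band_schedules = band_schedules, seed = seed, ...)
}

# Full analysis chain on one synthetic session; returns per-band
# stimulus-minus-prestimulus dB differences averaged over trials.
session_band_diffs <- function(config, bands = band_definitions()) {
  ses <- generate_session(config)
  filt <- lfp_bandpass(ses$recording)
  sg <- lfp_spectrogram(filt)
  ph <- segment_phases(ses$events, recording_duration = filt$duration_s)
  bp <- band_phase_means(sg, ph, bands, recording = filt)
  con <- bp[bp$phase %in% c("prestimulus", "stimulus"), ]
  m <- tapply(con$mean_psd_db, list(con$band, con$phase), mean)
  m[, "stimulus"] - m[, "prestimulus"]
}
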