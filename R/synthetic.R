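#' Derive a child RNG seed from a master seed
#'
#' Every generated object draws from its own stream, seeded as
#' `(seed * 48271 + offset * 1664525) mod (2^31 - 1)`; the fixed offsets are
#' documented in the generator that uses them. This keeps each output
#' independent of the order in which the others are produced.
#'
#' @param seed Master seed (integer).
#' @param offset Stream index (integer).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + as.double(offset) * 1664525) %%
               2147483629)
}

#' Per-band oscillation schedule
#'
#' One sinusoidal component of a synthetic session: a band label, a carrier
#' frequency inside that band, and the component's amplitude during the
#' prestimulus/poststimulus portions versus the stimulus portion of each
#' trial. The prestimulus/stimulus amplitude contrast is what the
#' band-power analysis is meant to recover.
#'
#' @param band One of delta, theta, alpha, beta, gamma.
#' @param center_freq Carrier frequency, Hz; must lie inside the band.
#' @param prestim_amplitude,stim_amplitude Amplitudes (signal units, >= 0).
#' @return A `band_schedule` object.
#' @export
band_schedule <- function(band, center_freq, prestim_amplitude,
                          stim_amplitude) {
  bands <- band_definitions()
  if (!band %in% bands$band) {
    stop("configuration error: band_schedules: unknown band `", band, "`",
         call. = FALSE)
  }
  row <- bands[bands$band == band, ]
  last <- band == bands$band[nrow(bands)]
  inside <- center_freq >= row$low_hz &
    (if (last) center_freq <= row$high_hz else center_freq < row$high_hz)
  if (!inside) {
    stop("configuration error: band_schedules: center_freq ", center_freq,
         " Hz outside the ", band, " band [", row$low_hz, ", ", row$high_hz,
         ")", call. = FALSE)
  }
  amps <- c(prestim_amplitude, stim_amplitude)
  if (any(!is.finite(amps)) || any(amps < 0)) {
    stop("configuration error: band_schedules: amplitudes must be finite ",
         "and non-negative", call. = FALSE)
  }
  structure(list(band = band, center_freq = center_freq,
                 prestim_amplitude = prestim_amplitude,
                 stim_amplitude = stim_amplitude),
            class = "band_schedule")
}

#' Default oscillation schedules for the study's conditions
#'
#' Five components, one per band, at carriers 3, 6, 12, 22 and 38 Hz with
#' prestimulus amplitudes 8, 10, 6, 4 and 2 signal units (strong
#' oscillations over unit-scale 1/f noise). Conditions: `"null"` — stimulus
#' amplitudes equal prestimulus (no event-locked change); `"model"` —
#' broadband suppression during the stimulus phase (stimulus amplitude =
#' 0.6 x prestimulus, an injured-state-like response); `"ea"` — same as
#' null (treated-state-like: stimulation no longer changes band power).
#' These are synthetic calibration values, not measured ones.
#'
#' @param condition `"null"`, `"model"`, or `"ea"`.
#' @param stim_ratio Stimulus/prestimulus amplitude ratio used by
#'   `"model"` (default 0.6).
#' @return List of [band_schedule()] objects.
#' @export
default_band_schedules <- function(condition = c("null", "model", "ea"),
                                   stim_ratio = 0.6) {
  condition <- match.arg(condition)
  centers <- c(delta = 3, theta = 6, alpha = 12, beta = 22, gamma = 38)
  pre <- c(delta = 8, theta = 10, alpha = 6, beta = 4, gamma = 2)
  ratio <- if (condition == "model") stim_ratio else 1
  lapply(names(centers), function(b)
    band_schedule(b, centers[[b]], pre[[b]], pre[[b]] * ratio))
}

#' Synthetic recording-session configuration
#'
#' Defines one continuous recording containing `n_trials` stimulation
#' epochs. Each epoch is `prestim_duration` s of baseline, a stimulus
#' period whose length (the withdrawal latency) is drawn uniformly from
#' `withdrawal_latency_range`, and `poststim_duration` s after withdrawal;
#' epochs are separated by `pad_duration` s of padding (also placed before
#' the first epoch). The signal is 1/f^beta noise of standard deviation
#' `noise_scale` plus the scheduled sinusoids, whose amplitude envelopes
#' switch between the prestimulus and stimulus levels through a 100 ms
#' raised-cosine ramp. The oscillations already run at the prestimulus
#' level for `lead_in` s before each epoch and keep running for `lead_in` s
#' after it, so the turn-on/turn-off splatter falls outside every analysis
#' window; the central `pad_duration - 2 * lead_in` s (at least 1 s) of
#' each pad are noise-only.
#'
#' @param n_trials Number of stimulation epochs (>= 1).
#' @param sampling_rate Hz; must exceed twice the highest band edge (90 Hz).
#' @param prestim_duration Baseline seconds before each onset (default 5).
#' @param withdrawal_latency_range Uniform latency range, seconds; min > 0
#'   and max <= 20 (the force ramp lasts 20 s).
#' @param poststim_duration Seconds retained after withdrawal.
#' @param pad_duration Padding seconds between epochs; must leave at least
#'   1 s of noise-only gap, i.e. `pad_duration >= 2 * lead_in + 1`.
#' @param lead_in Seconds of prestimulus-level oscillation run up before
#'   (and kept after) each epoch, inside the pad.
#' @param noise_exponent Spectral slope beta of the 1/f^beta noise (>= 0).
#' @param noise_scale Noise standard deviation, signal units.
#' @param band_schedules Non-empty list of [band_schedule()] objects.
#' @param seed Master seed for the session's RNG streams.
#' @return A `session_config` object.
#' @export
session_config <- function(n_trials = 20L, sampling_rate = 1000,
                           prestim_duration = 5,
                           withdrawal_latency_range = c(2, 8),
                           poststim_duration = 5, pad_duration = 4,
                           lead_in = 1.5,
                           noise_exponent = 1, noise_scale = 1,
                           band_schedules = default_band_schedules(),
                           seed = 1L) {
  if (n_trials < 1L) {
    stop("configuration error: n_trials must be >= 1", call. = FALSE)
  }
  max_edge <- max(band_definitions()$high_hz)
  if (!is.finite(sampling_rate) || sampling_rate <= 2 * max_edge) {
    stop("configuration error: sampling_rate must exceed ", 2 * max_edge,
         " Hz (twice the highest band edge)", call. = FALSE)
  }
  lr <- withdrawal_latency_range
  if (length(lr) != 2L || lr[1] <= 0 || lr[2] > 20 || lr[1] > lr[2]) {
    stop("configuration error: withdrawal_latency_range must satisfy ",
         "0 < min <= max <= 20 (force ramp length)", call. = FALSE)
  }
  if (!length(band_schedules)) {
    stop("configuration error: band_schedules must be non-empty",
         call. = FALSE)
  }
  if (!all(vapply(band_schedules, inherits, logical(1), "band_schedule"))) {
    stop("configuration error: band_schedules must be band_schedule objects",
         call. = FALSE)
  }
  if (lead_in < 0 || pad_duration < 2 * lead_in + 1) {
    stop("configuration error: pad_duration must be >= 2 * lead_in + 1 s ",
         "(so pads keep a noise-only gap of >= 1 s)", call. = FALSE)
  }
  if (noise_exponent < 0 || noise_scale < 0) {
    stop("configuration error: noise_exponent and noise_scale must be >= 0",
         call. = FALSE)
  }
  structure(list(n_trials = as.integer(n_trials),
                 sampling_rate = sampling_rate,
                 prestim_duration = prestim_duration,
                 withdrawal_latency_range = as.double(lr),
                 poststim_duration = poststim_duration,
                 pad_duration = pad_duration,
                 lead_in = lead_in,
                 noise_exponent = noise_exponent,
                 noise_scale = noise_scale,
                 band_schedules = band_schedules,
                 seed = as.integer(seed)),
            class = "session_config")
}

# 1/f^beta noise via spectral shaping of white Gaussian noise,
# standardized to unit sd before scaling. The FFT runs at the next
# 2-3-5-smooth length (mixed-radix fft is pathologically slow on lengths
# with large prime factors) and the result is truncated to n.
colored_noise <- function(n, beta, fs) {
  m <- stats::nextn(n, c(2, 3, 5))
  white <- rnorm(m)
  if (beta == 0) {
    x <- white[seq_len(n)]
    return(x / sd(x))
  }
  sp <- fft(white)
  k <- 0:(m - 1)
  f <- pmin(k, m - k) * fs / m
  shape <- c(0, f[-1]^(-beta / 2))
  x <- Re(fft(sp * shape, inverse = TRUE))[seq_len(n)] / m
  x / sd(x)
}

# Replace each jump of a piecewise-constant amplitude vector with a 100 ms
# raised-cosine ramp centered on the transition. Transitions are at least a
# pad apart, so ramps never overlap.
smooth_envelope <- function(step, fs) {
  len <- max(2L, as.integer(round(0.1 * fs)))
  half <- len %/% 2L
  n <- length(step)
  ramp <- (1 - cos(pi * seq_len(len) / (len + 1))) / 2
  out <- step
  for (tr in which(diff(step) != 0)) {
    v0 <- step[tr]; v1 <- step[tr + 1L]
    idx <- (tr - half + 1L):(tr - half + len)
    ok <- idx >= 1L & idx <= n
    out[idx[ok]] <- v0 + (v1 - v0) * ramp[ok]
  }
  out
}

#' Generate one synthetic recording session
#'
#' Builds the continuous LFP trace and its event table from a
#' [session_config()]. RNG streams (see [derive_seed()]): offset 1 -
#' withdrawal latencies; offset 2 - noise; offsets 10+j - initial phase of
#' the j-th scheduled sinusoid. Identical config (including seed) gives
#' bit-identical output.
#'
#' @param config A [session_config()].
#' @return List with `recording` (an [lfp_recording()]), `events`
#'   (validated event table), and `latencies_s`.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  fs <- config$sampling_rate
  set.seed(derive_seed(config$seed, 1))
  lat <- runif(config$n_trials, config$withdrawal_latency_range[1],
               config$withdrawal_latency_range[2])
  epoch_dur <- config$prestim_duration + lat + config$poststim_duration
  epoch_start <- config$pad_duration +
    cumsum(c(0, head(epoch_dur + config$pad_duration, -1)))
  total_dur <- config$pad_duration +
    sum(epoch_dur + config$pad_duration)
  n <- as.integer(round(total_dur * fs))
  onset <- epoch_start + config$prestim_duration
  withdrawal <- onset + lat

  x <- numeric(n)
  if (config$noise_scale > 0) {
    set.seed(derive_seed(config$seed, 2))
    x <- colored_noise(n, config$noise_exponent, fs) * config$noise_scale
  }
  t <- (seq_len(n) - 1L) / fs
  # region code per sample: 0 = pad, 1 = prestimulus-level, 2 = stimulus
  fill <- function(region, t0, t1, code) {
    i0 <- max(1L, as.integer(ceiling(t0 * fs - 1e-9)) + 1L)
    i1 <- min(n, as.integer(ceiling(t1 * fs - 1e-9)))
    if (i1 >= i0) region[i0:i1] <- code
    region
  }
  region <- integer(n)
  for (i in seq_len(config$n_trials)) {
    region <- fill(region, epoch_start[i] - config$lead_in, onset[i], 1L)
    region <- fill(region, onset[i], withdrawal[i], 2L)
    region <- fill(region, withdrawal[i],
                   epoch_start[i] + epoch_dur[i] + config$lead_in, 1L)
  }
  for (j in seq_along(config$band_schedules)) {
    sch <- config$band_schedules[[j]]
    if (sch$prestim_amplitude == 0 && sch$stim_amplitude == 0) next
    set.seed(derive_seed(config$seed, 10L + j))
    phase0 <- runif(1, 0, 2 * pi)
    step <- c(0, sch$prestim_amplitude, sch$stim_amplitude)[region + 1L]
    env <- smooth_envelope(step, fs)
    x <- x + env * sin(2 * pi * sch$center_freq * t + phase0)
  }
  rec <- lfp_recording(x, fs, channel_id = "synthetic")
  trial_ids <- sprintf("trial_%02d", seq_len(config$n_trials))
  events <- event_table(data.frame(
    trial_id = rep(trial_ids, each = 2L),
    event = rep(c("stimulus_onset", "paw_withdrawal"), config$n_trials),
    time_s = as.vector(rbind(onset, withdrawal))),
    recording_duration = rec$duration_s)
  list(recording = rec, events = events, latencies_s = lat)
}

#' Synthetic behavioral-study design
#'
#' Group x timepoint mean tables and noise levels for the paw-withdrawal
#' threshold (PWT) and conditioned-place-aversion (CPA) tables. The default
#' mean tables are synthetic calibration values chosen to carry the
#' qualitative group ordering of a pain-memory experiment (injured "model"
#' group hypersensitive after each injury and avoiding the pain-paired
#' compartment after the second one; "ea" treatment group recovering faster
#' and showing no late avoidance); they are not measured values.
#'
#' @param groups Group labels.
#' @param n_per_group Subjects per group (default 7).
#' @param timepoints Ordered PWT timepoint labels.
#' @param group_mean_pwt Matrix (group x timepoint) of PWT means, grams in
#'   `[0, 50]`.
#' @param pwt_sd Reading-level PWT standard deviation, grams.
#' @param cpa_days Ordered CPA day labels; first is the baseline.
#' @param cpa_mean_occupancy Matrix (group x day) of mean pain-paired
#'   occupancy, seconds.
#' @param occupancy_sd Occupancy standard deviation, seconds.
#' @param session_length_s CPA session length (1800 s = 30 min).
#' @param total_active_mean,total_active_sd Mean/sd of the summed two-
#'   compartment occupancy per session, seconds.
#' @param seed Master seed.
#' @return A `behavior_design` object.
#' @export
behavior_design <- function(groups = c("control", "model", "ea"),
                            n_per_group = 7L,
                            timepoints = c("-1d", "4h", "1d", "5d", "13d", "15d"),
                            group_mean_pwt = default_pwt_means(),
                            pwt_sd = 3,
                            cpa_days = c("baseline", "1d", "5d", "13d", "15d"),
                            cpa_mean_occupancy = default_cpa_means(),
                            occupancy_sd = 80,
                            session_length_s = 1800,
                            total_active_mean = 1700,
                            total_active_sd = 30,
                            seed = 1L) {
  stopifnot(nrow(group_mean_pwt) == length(groups),
            ncol(group_mean_pwt) == length(timepoints),
            nrow(cpa_mean_occupancy) == length(groups),
            ncol(cpa_mean_occupancy) == length(cpa_days))
  if (any(group_mean_pwt < 0 | group_mean_pwt > 50)) {
    stop("configuration error: PWT means must lie in [0, 50] grams",
         call. = FALSE)
  }
  if (any(cpa_mean_occupancy < 0) ||
      any(cpa_mean_occupancy > session_length_s) ||
      total_active_mean > session_length_s) {
    stop("configuration error: occupancy means exceed the ",
         session_length_s, " s session length", call. = FALSE)
  }
  structure(list(groups = groups, n_per_group = as.integer(n_per_group),
                 timepoints = timepoints,
                 group_mean_pwt = group_mean_pwt, pwt_sd = pwt_sd,
                 cpa_days = cpa_days,
                 cpa_mean_occupancy = cpa_mean_occupancy,
                 occupancy_sd = occupancy_sd,
                 session_length_s = session_length_s,
                 total_active_mean = total_active_mean,
                 total_active_sd = total_active_sd,
                 seed = as.integer(seed)),
            class = "behavior_design")
}

#' @rdname behavior_design
#' @export
default_pwt_means <- function() {
  matrix(c(35, 35, 35, 35, 35, 35,   # control: stable
           35, 12, 15, 20, 33, 14,   # model: drop after each injury
           35, 12, 20, 28, 34, 30),  # ea: faster recovery, protected late
         nrow = 3, byrow = TRUE,
         dimnames = list(c("control", "model", "ea"),
                         c("-1d", "4h", "1d", "5d", "13d", "15d")))
}

#' @rdname behavior_design
#' @export
default_cpa_means <- function() {
  matrix(c(900, 880, 880, 880, 880,  # control: mild drift only
           900, 860, 850, 840, 600,  # model: strong late avoidance
           900, 860, 850, 840, 870), # ea: no late avoidance
         nrow = 3, byrow = TRUE,
         dimnames = list(c("control", "model", "ea"),
                         c("baseline", "1d", "5d", "13d", "15d")))
}

#' Generate synthetic behavioral tables
#'
#' Draws per-reading PWT values (5 ramp readings per subject x timepoint,
#' Gaussian around the group mean, clipped to the 0-50 g instrument range)
#' and per-day CPA occupancy pairs (total active time Gaussian around
#' `total_active_mean` truncated at the session length; pain-paired time
#' Gaussian around the group x day mean truncated to `[0, total]`;
#' non-pain-paired time is the remainder, so the pair never exceeds the
#' session length). RNG streams: offset 101 - PWT readings; offset 102 -
#' CPA occupancies.
#'
#' @param design A [behavior_design()].
#' @return List with `pwt` (subject, group, timepoint, trial_index, grams)
#'   and `cpa` (subject, group, day, compartment, occupancy_s) data.frames.
#' @export
generate_behavior <- function(design) {
  stopifnot(inherits(design, "behavior_design"))
  G <- length(design$groups); N <- design$n_per_group
  TT <- length(design$timepoints)
  subj <- function(g) sprintf("%s_%02d", g, seq_len(N))

  set.seed(derive_seed(design$seed, 101))
  pwt <- expand.grid(trial_index = 1:5,
                     timepoint = design$timepoints,
                     subject_idx = seq_len(N),
                     group = design$groups,
                     stringsAsFactors = FALSE)
  pwt$subject <- sprintf("%s_%02d", pwt$group, pwt$subject_idx)
  mu <- design$group_mean_pwt[cbind(match(pwt$group, design$groups),
                                    match(pwt$timepoint, design$timepoints))]
  pwt$grams <- pmin(50, pmax(0, mu + rnorm(nrow(pwt)) * design$pwt_sd))
  pwt <- pwt[order(pwt$group, pwt$subject, match(pwt$timepoint, design$timepoints),
                   pwt$trial_index),
             c("subject", "group", "timepoint", "trial_index", "grams")]
  rownames(pwt) <- NULL

  set.seed(derive_seed(design$seed, 102))
  grid <- expand.grid(day = design$cpa_days, subject_idx = seq_len(N),
                      group = design$groups, stringsAsFactors = FALSE)
  grid$subject <- sprintf("%s_%02d", grid$group, grid$subject_idx)
  total <- pmin(design$session_length_s,
                pmax(0, rnorm(nrow(grid), design$total_active_mean,
                              design$total_active_sd)))
  mu <- design$cpa_mean_occupancy[cbind(match(grid$group, design$groups),
                                        match(grid$day, design$cpa_days))]
  pain <- pmin(total, pmax(0, mu + rnorm(nrow(grid)) * design$occupancy_sd))
  cpa <- rbind(
    data.frame(grid[c("subject", "group", "day")],
               compartment = "pain_paired", occupancy_s = pain),
    data.frame(grid[c("subject", "group", "day")],
               compartment = "non_pain_paired", occupancy_s = total - pain))
  cpa <- cpa[order(cpa$group, cpa$subject,
                   match(cpa$day, design$cpa_days), cpa$compartment), ]
  rownames(cpa) <- NULL
  list(pwt = pwt, cpa = cpa)
}
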