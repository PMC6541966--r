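test_that("band definitions tile 2-45 Hz without gaps or overlaps", {
  b <- band_definitions()
  expect_equal(b$low_hz[-1], b$high_hz[-nrow(b)])
  expect_equal(b$low_hz[1], 2)
  expect_equal(b$high_hz[nrow(b)], 45)
  # each retained bin belongs to exactly one band
  freqs <- (3:46) * 1000 / 1024
  counts <- rowSums(vapply(seq_len(nrow(b)), function(i) {
    freqs %in% freqs[painlfp:::band_cols(freqs, b, i)]
  }, logical(length(freqs))))
  expect_true(all(counts == 1))
})

test_that("phase windows follow the half-open event-anchored convention", {
  ev <- data.frame(trial_id = "t1",
                   event = c("stimulus_onset", "paw_withdrawal"),
                   time_s = c(100, 104.2))
  ph <- segment_phases(ev)
  expect_equal(ph$start_s, c(95, 100, 104.2))
  expect_equal(ph$end_s, c(100, 104.2, 109.2))
  expect_equal(ph$phase, c("prestimulus", "stimulus", "poststimulus"))
  expect_false(any(ph$truncated))
})

test_that("trials too close to the recording start are excluded", {
  ev <- data.frame(trial_id = c("t1", "t1", "t2", "t2"),
                   event = rep(c("stimulus_onset", "paw_withdrawal"), 2),
                   time_s = c(3, 5, 50, 53))
  expect_warning(ph <- segment_phases(ev), "t1 excluded")
  expect_equal(unique(ph$trial_id), "t2")
})

test_that("trials lacking a withdrawal are truncated at the 20 s ramp end", {
  ev <- data.frame(trial_id = "t1", event = "stimulus_onset", time_s = 30)
  ph <- segment_phases(ev)
  stim <- ph[ph$phase == "stimulus", ]
  expect_equal(stim$start_s, 30)
  expect_equal(stim$end_s, 50)
  expect_true(stim$truncated)
})

test_that("band-phase means on a constant-by-band field are exact", {
  freqs <- (3:46) * 1000 / 1024
  theta <- freqs >= 4 & freqs < 9
  m <- matrix(-40, 10, length(freqs))
  m[, theta] <- 0
  sg <- make_spectrogram(m, time_s = seq(0.5, 5, by = 0.5), freq_hz = freqs)
  ev <- data.frame(trial_id = "t1",
                   event = c("stimulus_onset", "paw_withdrawal"),
                   time_s = c(0, 3))
  ph <- suppressWarnings(segment_phases(ev, prestim_s = 0))
  ph <- ph[ph$phase == "stimulus", ]
  bp <- band_phase_means(sg, ph)
  expect_equal(bp$mean_psd_db[bp$band == "theta"], 0)
  expect_equal(bp$mean_psd_db[bp$band == "alpha"], -40)
})

test_that("band-phase means equal a brute-force double loop", {
  set.seed(41)
  freqs <- (3:46) * 1000 / 1024
  m <- matrix(rnorm(20 * length(freqs)), 20, length(freqs))
  sg <- make_spectrogram(m, time_s = seq(0.25, 5, by = 0.25),
                         freq_hz = freqs)
  ph <- data.frame(trial_id = c("t1", "t1"),
                   phase = c("prestimulus", "stimulus"),
                   start_s = c(0, 2.5), end_s = c(2.5, 4.4),
                   truncated = FALSE)
  bp <- band_phase_means(sg, ph)
  bands <- band_definitions()
  for (r in seq_len(nrow(bp))) {
    w <- ph[ph$phase == bp$phase[r], ]
    b <- bands[bands$band == bp$band[r], ]
    acc <- c()
    for (i in seq_along(sg$time_s)) {
      if (sg$time_s[i] < w$start_s || sg$time_s[i] >= w$end_s) next
      for (j in seq_along(freqs)) {
        top <- b$high_hz == 45
        if (freqs[j] >= b$low_hz &&
            (freqs[j] < b$high_hz || (top && freqs[j] <= b$high_hz))) {
          acc <- c(acc, m[i, j])
        }
      }
    }
    expect_equal(bp$mean_psd_db[r], mean(acc))
  }
})

test_that("bin-count-weighted band means reproduce the broadband mean", {
  set.seed(42)
  freqs <- (3:46) * 1000 / 1024
  m <- matrix(rnorm(8 * length(freqs)), 8, length(freqs))
  sg <- make_spectrogram(m, time_s = seq(0.5, 4, by = 0.5), freq_hz = freqs)
  ph <- data.frame(trial_id = "t1", phase = "stimulus",
                   start_s = 0, end_s = 5, truncated = FALSE)
  bands <- band_definitions()
  bp <- band_phase_means(sg, ph, bands)
  nb <- vapply(seq_len(nrow(bands)), function(i)
    length(painlfp:::band_cols(freqs, bands, i)), numeric(1))
  broad <- band_phase_means(sg, ph, data.frame(band = "all", low_hz = 2,
                                               high_hz = 45))
  expect_equal(sum(bp$mean_psd_db * nb) / sum(nb), broad$mean_psd_db,
               tolerance = 1e-9)
})

test_that("phases without window centers fall back to a single short window", {
  set.seed(43)
  rec <- lfp_recording(rnorm(20000), 1000)
  sg <- lfp_spectrogram(rec)
  # window centers sit at 0.5115 + 0.512 k; [10.30, 10.70) contains none,
  # but its 400 samples are >= 256, so a single short window is used
  ph <- data.frame(trial_id = "t1", phase = "stimulus",
                   start_s = 10.30, end_s = 10.70, truncated = FALSE)
  expect_false(any(sg$time_s >= ph$start_s & sg$time_s < ph$end_s))
  bp <- band_phase_means(sg, ph, recording = rec)
  expect_equal(nrow(bp), 5)
  expect_true(all(is.finite(bp$mean_psd_db)))
  # shorter than 256 samples: dropped with a warning
  ph$end_s <- ph$start_s + 0.2
  expect_warning(bp2 <- band_phase_means(sg, ph, recording = rec),
                 "dropped")
  expect_null(bp2)
  # and without the recording there is no fallback at all
  ph$end_s <- ph$start_s + 0.4
  expect_warning(band_phase_means(sg, ph), "dropped")
})

test_that("compartment means pool intervals and match the loop oracle", {
  set.seed(44)
  freqs <- (3:46) * 1000 / 1024
  m <- matrix(rnorm(12 * length(freqs)), 12, length(freqs))
  sg <- make_spectrogram(m, time_s = seq(0.5, 6, by = 0.5), freq_hz = freqs)
  whole <- compartment_phase_means(sg, data.frame(start = 0, end = 7))
  ph <- data.frame(trial_id = "x", phase = "all", start_s = 0, end_s = 7,
                   truncated = FALSE)
  expect_equal(whole$mean_psd_db, band_phase_means(sg, ph)$mean_psd_db)

  # constant field: two equal-count disjoint intervals = either alone
  sgc <- make_spectrogram(matrix(-12, 12, 44), time_s = seq(0.5, 6, 0.5),
                          freq_hz = freqs)
  two <- compartment_phase_means(sgc, data.frame(start = c(0, 3),
                                                 end = c(1.5, 4.5)))
  one <- compartment_phase_means(sgc, data.frame(start = 0, end = 1.5))
  expect_equal(two$mean_psd_db, one$mean_psd_db)

  # random intervals vs explicit loop
  iv <- data.frame(start = c(0.4, 3.1), end = c(1.6, 5.2))
  got <- compartment_phase_means(sg, iv)
  rows <- which((sg$time_s >= 0.4 & sg$time_s < 1.6) |
                  (sg$time_s >= 3.1 & sg$time_s < 5.2))
  bands <- band_definitions()
  for (r in seq_len(nrow(got))) {
    cols <- painlfp:::band_cols(freqs, bands, r)
    expect_equal(got$mean_psd_db[r], mean(m[rows, cols]))
  }
  expect_error(compartment_phase_means(sg, data.frame(start = 20, end = 30)),
               "empty phase")
})
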