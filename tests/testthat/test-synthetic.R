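test_that("identical seeds give bit-identical sessions and tables", {
  cfg <- quick_session(seed = 7)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$events, b$events)
  d <- behavior_design(seed = 7)
  expect_identical(generate_behavior(d), generate_behavior(d))
  # a different seed changes the data
  c2 <- generate_session(quick_session(seed = 8))
  expect_false(identical(a$recording$samples, c2$recording$samples))
})

test_that("silent configuration yields a zero trace but a full event table", {
  cfg <- quick_session(noise_scale = 0, n_trials = 3,
                       band_schedules = list(band_schedule("theta", 6, 0, 0)))
  ses <- generate_session(cfg)
  expect_true(all(ses$recording$samples == 0))
  expect_equal(nrow(ses$events), 6)
})

test_that("event timing respects the configured latency range and spacing", {
  cfg <- session_config(n_trials = 12, withdrawal_latency_range = c(2, 8),
                        seed = 9)
  ses <- generate_session(cfg)
  expect_true(all(ses$latencies_s >= 2 & ses$latencies_s <= 8))
  on <- ses$events$time_s[ses$events$event == "stimulus_onset"]
  wd <- ses$events$time_s[ses$events$event == "paw_withdrawal"]
  expect_equal(wd - on, ses$latencies_s)
  # phases of consecutive trials never overlap
  ph <- segment_phases(ses$events,
                       recording_duration = ses$recording$duration_s)
  ph <- ph[order(ph$start_s), ]
  expect_true(all(ph$start_s[-1] >= ph$end_s[-nrow(ph)] - 1e-9))
})

test_that("a noiseless sinusoid concentrates its power near the carrier", {
  cfg <- quick_session(n_trials = 2, noise_scale = 0,
                       band_schedules = list(band_schedule("theta", 6, 1, 1)))
  ses <- generate_session(cfg)
  wp <- welch_psd(ses$recording)
  keep <- wp$freq_hz >= 2 & wp$freq_hz <= 45
  p <- colMeans(wp$psd)[keep]
  pk <- which.max(p)
  lo <- max(1, pk - 2); hi <- min(length(p), pk + 2)
  expect_gte(sum(p[lo:hi]) / sum(p), 0.95)
  expect_lt(abs(wp$freq_hz[keep][pk] - 6), 2 * 1000 / 1024)
})

test_that("the noise generator recovers its 1/f exponent", {
  for (beta in c(0.5, 1, 2)) {
    cfg <- session_config(n_trials = 1, prestim_duration = 5,
                          withdrawal_latency_range = c(19, 20),
                          poststim_duration = 30, pad_duration = 8,
                          noise_exponent = beta,
                          band_schedules = list(band_schedule("theta", 6, 0, 0)),
                          seed = 10)
    ses <- generate_session(cfg)  # > 60 s of pure noise
    wp <- welch_psd(ses$recording)
    keep <- wp$freq_hz >= 2 & wp$freq_hz <= 45
    fit <- lm(log(colMeans(wp$psd)[keep]) ~ log(wp$freq_hz[keep]))
    expect_lt(abs(-coef(fit)[2] - beta), 0.3)
  }
})

test_that("configuration errors name the offending field", {
  expect_error(session_config(n_trials = 0), "n_trials")
  expect_error(session_config(sampling_rate = 80), "sampling_rate")
  expect_error(session_config(withdrawal_latency_range = c(0, 5)),
               "withdrawal_latency_range")
  expect_error(session_config(withdrawal_latency_range = c(2, 25)),
               "withdrawal_latency_range")
  expect_error(session_config(band_schedules = list()), "band_schedules")
  expect_error(band_schedule("theta", 12, 1, 1), "center_freq")
  expect_error(band_schedule("sigma", 6, 1, 1), "unknown band")
  expect_error(band_schedule("theta", 6, -1, 1), "non-negative")
  bad_occ <- default_cpa_means(); bad_occ["model", "15d"] <- 1900
  expect_error(behavior_design(cpa_mean_occupancy = bad_occ),
               "occupancy means exceed")
  bad_pwt <- default_pwt_means(); bad_pwt[1, 1] <- 60
  expect_error(behavior_design(group_mean_pwt = bad_pwt), "\\[0, 50\\]")
})

test_that("zero reading noise reproduces the group means exactly", {
  d <- behavior_design(pwt_sd = 0, seed = 11)
  pwt <- generate_behavior(d)$pwt
  mu <- default_pwt_means()
  for (g in rownames(mu)) for (tp in colnames(mu)) {
    expect_true(all(pwt$grams[pwt$group == g & pwt$timepoint == tp] ==
                      mu[g, tp]))
  }
})

test_that("occupancy pairs never exceed the session length", {
  for (seed in 1:5) {
    cpa <- generate_behavior(behavior_design(seed = seed))$cpa
    sums <- tapply(cpa$occupancy_s, list(cpa$subject, cpa$day), sum)
    expect_true(all(sums <= 1800))
    expect_true(all(cpa$occupancy_s >= 0))
  }
})

test_that("generated PWT trajectories carry the reported group ordering", {
  # expectations over an ensemble; means across 40 seeded cohorts
  m <- 0
  for (seed in 1:40) {
    ps <- pwt_scores(generate_behavior(behavior_design(seed = seed))$pwt)
    m <- m + tapply(ps$pwt_grams, list(ps$group, ps$timepoint), mean) / 40
  }
  for (tp in c("4h", "1d", "5d", "15d")) {
    expect_lt(m["model", tp], m["control", tp])
  }
  for (tp in c("1d", "5d", "15d")) {
    expect_gt(m["ea", tp], m["model", tp])
  }
  expect_lt(abs(m["model", "-1d"] - m["control", "-1d"]), 1)
})

test_that("the default design powers the group-by-time interaction", {
  rej <- vapply(1:200, function(i) {
    ps <- pwt_scores(generate_behavior(behavior_design(seed = 7000 + i))$pwt)
    r <- rm_anova_mixed(ps, subject = "subject", group = "group",
                        time = "timepoint", value = "pwt_grams")
    r$effects$p[r$effects$effect == "group:timepoint"] < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
})

test_that("equal group means keep the interaction at its nominal size", {
  eq <- matrix(30, 3, 6, dimnames = dimnames(default_pwt_means()))
  rej <- vapply(1:1000, function(i) {
    d <- behavior_design(group_mean_pwt = eq, seed = 8000 + i)
    ps <- pwt_scores(generate_behavior(d)$pwt)
    r <- rm_anova_mixed(ps, subject = "subject", group = "group",
                        time = "timepoint", value = "pwt_grams")
    r$effects$p[r$effects$effect == "group:timepoint"] < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
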