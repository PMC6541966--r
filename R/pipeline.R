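#' Full-run configuration
#'
#' Bundles everything one reproducible end-to-end run needs: a master seed
#' (split per stage via [derive_seed()]: offset 11 seeds the recording
#' session, offset 12 the behavioral tables), the session and behavior
#' generators, the filter and spectral settings, band definitions, and the
#' significance level. `condition` selects the default oscillation
#' schedules (see [default_band_schedules()]).
#'
#' @param seed Master seed.
#' @param condition `"model"`, `"ea"`, or `"null"`.
#' @param session Optional [session_config()] override.
#' @param behavior Optional [behavior_design()] override.
#' @param filter A [filter_spec()].
#' @param spectral A [spectral_config()].
#' @param bands Band definitions table.
#' @param alpha Significance level (default 0.05).
#' @param n_trials,stim_ratio Convenience pass-throughs used when `session`
#'   is not supplied.
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1L, condition = c("model", "ea", "null"),
                       session = NULL, behavior = NULL,
                       filter = filter_spec(), spectral = spectral_config(),
                       bands = band_definitions(), alpha = 0.05,
                       n_trials = 20L, stim_ratio = 0.6) {
  condition <- match.arg(condition)
  if (is.null(session)) {
    session <- session_config(
      n_trials = n_trials,
      band_schedules = default_band_schedules(condition, stim_ratio),
      seed = derive_seed(seed, 11))
  }
  if (is.null(behavior)) {
    behavior <- behavior_design(seed = derive_seed(seed, 12))
  }
  structure(list(seed = as.integer(seed), condition = condition,
                 session = session, behavior = behavior, filter = filter,
                 spectral = spectral, bands = bands, alpha = alpha),
            class = "run_config")
}

#' Rebuild a run configuration from a run's manifest
#'
#' Reads the `manifest.json` written by [run_all()] and reconstructs the
#' [run_config()] that produced the run, so the run can be reproduced
#' exactly.
#'
#' @param path Path to a `manifest.json`.
#' @return A `run_config` object.
#' @export
run_config_from_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  schedules <- lapply(seq_len(nrow(m$band_schedules)), function(i)
    do.call(band_schedule, as.list(m$band_schedules[i, ])))
  ses <- m$session
  session <- session_config(
    n_trials = ses$n_trials, sampling_rate = ses$sampling_rate,
    prestim_duration = ses$prestim_duration,
    withdrawal_latency_range = ses$withdrawal_latency_range,
    poststim_duration = ses$poststim_duration,
    pad_duration = ses$pad_duration, lead_in = ses$lead_in,
    noise_exponent = ses$noise_exponent, noise_scale = ses$noise_scale,
    band_schedules = schedules, seed = ses$seed)
  beh <- m$behavior
  behavior <- behavior_design(
    groups = beh$groups, n_per_group = beh$n_per_group,
    timepoints = beh$timepoints,
    group_mean_pwt = matrix(unlist(beh$group_mean_pwt),
                            nrow = length(beh$groups),
                            dimnames = list(beh$groups, beh$timepoints)),
    pwt_sd = beh$pwt_sd, cpa_days = beh$cpa_days,
    cpa_mean_occupancy = matrix(unlist(beh$cpa_mean_occupancy),
                                nrow = length(beh$groups),
                                dimnames = list(beh$groups, beh$cpa_days)),
    occupancy_sd = beh$occupancy_sd,
    session_length_s = beh$session_length_s,
    total_active_mean = beh$total_active_mean,
    total_active_sd = beh$total_active_sd, seed = beh$seed)
  run_config(seed = m$seed, condition = m$condition, session = session,
             behavior = behavior,
             filter = filter_spec(m$filter$low_hz, m$filter$high_hz,
                                  m$filter$order),
             spectral = spectral_config(m$spectral$window_samples,
                                        m$spectral$overlap,
                                        m$spectral$freq_range_hz,
                                        m$spectral$db_floor,
                                        m$spectral$smooth_width_bins),
             alpha = m$alpha)
}

write_table <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the whole pipeline into an output directory
#'
#' Stages: simulate (LFP store, `events.csv`, `pwt.csv`, `cpa.csv`) ->
#' filter (`lfp_filtered` store) -> psd (`spectrogram.csv`) -> bandpower
#' (`band_phase.csv`) -> behavior (`pwt_scores.csv`, `cpa_scores.csv`) ->
#' stats (`anova_results.csv`, `posthoc_results.csv`, `report.txt`), plus a
#' `manifest.json` recording the configuration, seed and per-stage row
#' counts. Every stage reads its input back from disk, so each intermediate
#' is independently re-usable; a fixed config yields byte-identical outputs
#' across runs.
#'
#' The prestimulus-vs-stimulus band contrasts (one-way rm ANOVA across
#' trials, per band plus broadband 2-45 Hz) form one Bonferroni family in
#' the report; behavioral tables get mixed two-way group x time ANOVAs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the key tables and ANOVA results.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim <- stage("simulate", {
    ses <- generate_session(config$session)
    beh <- generate_behavior(config$behavior)
    write_lfp(ses$recording, file.path(out_dir, "lfp"))
    write_table(ses$events, out_dir, "events.csv")
    write_table(beh$pwt, out_dir, "pwt.csv")
    write_table(beh$cpa, out_dir, "cpa.csv")
    ses
  })

  filtered <- stage("filter", {
    rec <- read_lfp(file.path(out_dir, "lfp"))
    filt <- lfp_bandpass(rec, config$filter)
    write_lfp(filt, file.path(out_dir, "lfp_filtered"))
    filt
  })

  sg <- stage("psd", {
    filt <- read_lfp(file.path(out_dir, "lfp_filtered"))
    sg <- lfp_spectrogram(filt, config$spectral)
    write_table(spectrogram_table(sg), out_dir, "spectrogram.csv")
    sg
  })

  band_phase <- stage("bandpower", {
    events <- read_events(file.path(out_dir, "events.csv"),
                          recording_duration = filtered$duration_s)
    phases <- segment_phases(
      events, prestim_s = config$session$prestim_duration,
      poststim_s = config$session$poststim_duration,
      recording_duration = filtered$duration_s)
    broad <- rbind(config$bands,
                   data.frame(band = "broadband",
                              low_hz = min(config$bands$low_hz),
                              high_hz = max(config$bands$high_hz)))
    bp <- band_phase_means(sg, phases, broad, recording = filtered)
    write_table(bp, out_dir, "band_phase.csv")
    bp
  })

  scores <- stage("behavior", {
    pwt <- read_pwt(file.path(out_dir, "pwt.csv"))
    cpa <- read_cpa(file.path(out_dir, "cpa.csv"),
                    session_length_s = config$behavior$session_length_s)
    ps <- pwt_scores(pwt)
    cs <- cpa_scores(cpa)
    write_table(ps, out_dir, "pwt_scores.csv")
    write_table(cs, out_dir, "cpa_scores.csv")
    list(pwt = ps, cpa = cs)
  })

  results <- stage("stats", {
    bp <- read.csv(file.path(out_dir, "band_phase.csv"))
    contrast <- bp[bp$phase %in% c("prestimulus", "stimulus"), ]
    analyses <- list()
    for (b in unique(contrast$band)) {
      sub <- contrast[contrast$band == b, ]
      analyses[[paste0("band_", b)]] <- rm_anova_oneway(
        sub, subject = "trial_id", condition = "phase",
        value = "mean_psd_db")
    }
    analyses$pwt <- rm_anova_mixed(scores$pwt, subject = "subject",
                                   group = "group", time = "timepoint",
                                   value = "pwt_grams")
    analyses$cpa <- rm_anova_mixed(scores$cpa, subject = "subject",
                                   group = "group", time = "day",
                                   value = "score_s")
    analyses
  })

  stage("report", {
    effects <- do.call(rbind, lapply(names(results), function(nm) {
      data.frame(analysis = nm, results[[nm]]$effects)
    }))
    posthoc <- do.call(rbind, lapply(names(results), function(nm) {
      data.frame(analysis = nm, results[[nm]]$posthoc)
    }))
    write_table(effects, out_dir, "anova_results.csv")
    write_table(posthoc, out_dir, "posthoc_results.csv")

    # prestim-vs-stim band contrasts are one Bonferroni family
    band_nms <- grep("^band_", names(results), value = TRUE)
    fam_p <- vapply(band_nms, function(nm) results[[nm]]$effects$p,
                    numeric(1))
    fam_diff <- vapply(band_nms, function(nm) {
      ph <- results[[nm]]$posthoc
      -ph$mean_diff[1]  # stimulus minus prestimulus
    }, numeric(1))
    band_report <- data.frame(
      band = sub("^band_", "", band_nms),
      stim_minus_prestim_db = fam_diff,
      p_raw = fam_p,
      p_adjusted = bonferroni(fam_p, length(fam_p)))
    band_report$significant <- band_report$p_adjusted < config$alpha
    write_table(band_report, out_dir, "band_contrasts.csv")

    rep_lines <- c(
      sprintf("condition: %s, seed: %d, alpha: %g", config$condition,
              config$seed, config$alpha),
      "",
      "Prestimulus vs stimulus mean PSD (one-way rm ANOVA across trials,",
      sprintf("Bonferroni family of %d band contrasts):", nrow(band_report)),
      sprintf("  %-9s stim-prestim = %+7.3f dB, F = %10.3f, p_adj = %.4g%s",
              band_report$band, band_report$stim_minus_prestim_db,
              vapply(band_nms, function(nm) results[[nm]]$effects$F,
                     numeric(1)),
              band_report$p_adjusted,
              ifelse(band_report$significant, "  *", "")),
      "",
      "Behavioral mixed two-way rm ANOVAs:",
      sprintf("  pwt %s: F(%g, %g) = %.3f, p = %.4g%s",
              results$pwt$effects$effect, results$pwt$effects$df_num,
              results$pwt$effects$df_den, results$pwt$effects$F,
              results$pwt$effects$p,
              ifelse(results$pwt$effects$p < config$alpha, "  *", "")),
      sprintf("  cpa %s: F(%g, %g) = %.3f, p = %.4g%s",
              results$cpa$effects$effect, results$cpa$effects$df_num,
              results$cpa$effects$df_den, results$cpa$effects$F,
              results$cpa$effects$p,
              ifelse(results$cpa$effects$p < config$alpha, "  *", "")))
    writeLines(rep_lines, file.path(out_dir, "report.txt"))

    manifest <- list(
      package = "painlfp",
      version = as.character(utils::packageVersion("painlfp")),
      seed = config$seed,
      condition = config$condition,
      alpha = config$alpha,
      session = config$session[setdiff(names(config$session),
                                       "band_schedules")],
      band_schedules = lapply(config$session$band_schedules, unclass),
      behavior = lapply(unclass(config$behavior), function(x) {
        if (is.matrix(x)) as.data.frame(x) else x
      }),
      filter = unclass(config$filter),
      spectral = unclass(config$spectral),
      rows = list(events = nrow(sim$events),
                  band_phase = nrow(band_phase),
                  pwt_scores = nrow(scores$pwt),
                  cpa_scores = nrow(scores$cpa)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  invisible(list(band_phase = band_phase, scores = scores,
                 results = results,
                 band_contrasts = read.csv(file.path(out_dir,
                                                     "band_contrasts.csv"))))
}
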