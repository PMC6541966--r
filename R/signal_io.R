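#' Construct an LFP recording
#'
#' A uniformly sampled single-channel voltage trace with sampling-rate
#' metadata. Sample `i` (1-based) sits at time `(i - 1) / sampling_rate`
#' seconds; all time windows in the package use the half-open convention
#' `[start, end)`.
#'
#' @param samples Numeric vector of voltage values (finite).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel_id Channel label carried as metadata.
#' @param units Amplitude units carried as opaque metadata (the analysis is
#'   unit-agnostic; dB values are relative to the stored units squared per Hz).
#' @return An object of class `lfp_recording` with fields `samples`,
#'   `sampling_rate`, `channel_id`, `units` and derived `duration_s`.
#' @export
lfp_recording <- function(samples, sampling_rate, channel_id = "lfp",
                          units = "au") {
  samples <- as.double(samples)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  }
  if (anyNA(samples) || !all(is.finite(samples))) {
    stop("`samples` must be finite: NaN/Inf values are rejected",
         call. = FALSE)
  }
  structure(
    list(samples = samples,
         sampling_rate = as.double(sampling_rate),
         channel_id = as.character(channel_id),
         units = as.character(units),
         duration_s = length(samples) / sampling_rate),
    class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> channel %s: %d samples @ %g Hz (%.3f s), units %s\n",
              x$channel_id, length(x$samples), x$sampling_rate,
              x$duration_s, x$units))
  invisible(x)
}

#' Write / read an LFP recording
#'
#' The native store is a little-endian 32-bit float flat binary (`<path>.bin`)
#' with a JSON sidecar (`<path>.json`) declaring `sampling_rate`, `n_samples`,
#' `dtype`, `units`, and `channel_id`. A secondary CSV dialect
#' (`format = "csv"`) writes a two-column `sample_index,value` table plus the
#' same sidecar; it round-trips within the declared decimal precision rather
#' than bit-exactly.
#'
#' @param recording An [lfp_recording()].
#' @param path Path stem; `.bin`/`.csv` and `.json` extensions are appended.
#' @param format `"bin"` (default) or `"csv"`.
#' @param digits Decimal digits for the CSV dialect.
#' @return `write_lfp` returns `path` invisibly; `read_lfp` returns an
#'   [lfp_recording()].
#' @export
write_lfp <- function(recording, path, format = c("bin", "csv"), digits = 6L) {
  stopifnot(inherits(recording, "lfp_recording"))
  format <- match.arg(format)
  sidecar <- list(sampling_rate = recording$sampling_rate,
                  n_samples = length(recording$samples),
                  dtype = if (format == "bin") "float32le" else "csv",
                  units = recording$units,
                  channel_id = recording$channel_id)
  if (format == "bin") {
    con <- file(paste0(path, ".bin"), "wb")
    on.exit(close(con), add = TRUE)
    writeBin(as.double(recording$samples), con, size = 4L,
             endian = "little")
  } else {
    df <- data.frame(sample_index = seq_along(recording$samples) - 1L,
                     value = round(recording$samples, digits))
    write.csv(df, paste0(path, ".csv"), row.names = FALSE)
    sidecar$digits <- as.integer(digits)
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_lfp
#' @export
read_lfp <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("schema error: sidecar not found: ", sidecar_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (field in c("sampling_rate", "n_samples", "dtype")) {
    if (is.null(meta[[field]])) {
      stop("schema error: sidecar missing required field `", field, "`",
           call. = FALSE)
    }
  }
  if (identical(meta$dtype, "float32le")) {
    bin_path <- paste0(path, ".bin")
    n_bytes <- file.info(bin_path)$size
    if (is.na(n_bytes) || n_bytes != 4L * meta$n_samples) {
      stop("integrity error: payload has ", if (is.na(n_bytes)) 0 else n_bytes / 4,
           " samples but sidecar declares ", meta$n_samples, call. = FALSE)
    }
    con <- file(bin_path, "rb")
    on.exit(close(con), add = TRUE)
    samples <- readBin(con, what = "double", n = meta$n_samples, size = 4L,
                       endian = "little")
  } else if (identical(meta$dtype, "csv")) {
    df <- read.csv(paste0(path, ".csv"))
    if (nrow(df) != meta$n_samples) {
      stop("integrity error: payload has ", nrow(df),
           " samples but sidecar declares ", meta$n_samples, call. = FALSE)
    }
    samples <- df$value
  } else {
    stop("schema error: unknown dtype `", meta$dtype, "`", call. = FALSE)
  }
  lfp_recording(samples, meta$sampling_rate,
                channel_id = meta$channel_id %||% "lfp",
                units = meta$units %||% "au")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate an event table
#'
#' An event table has one `stimulus_onset` and at most one `paw_withdrawal`
#' row per trial, with the withdrawal strictly after the onset. Times are
#' seconds from recording start.
#'
#' @param events A data.frame with columns `trial_id`, `event`, `time_s`.
#'   Unknown extra columns are preserved but ignored.
#' @param recording_duration Optional duration bound in seconds; event times
#'   at or beyond it are rejected.
#' @return The validated data.frame (invisibly the same rows), ordered by
#'   time.
#' @export
event_table <- function(events, recording_duration = NULL) {
  required <- c("trial_id", "event", "time_s")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  events$trial_id <- as.character(events$trial_id)
  events$time_s <- as.double(events$time_s)
  known <- c("stimulus_onset", "paw_withdrawal")
  bad <- setdiff(unique(events$event), known)
  if (length(bad)) {
    stop("schema error: unknown event label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyNA(events$time_s) || !all(is.finite(events$time_s))) {
    stop("validation error: non-finite event times", call. = FALSE)
  }
  for (id in unique(events$trial_id)) {
    sub <- events[events$trial_id == id, ]
    onsets <- sub$time_s[sub$event == "stimulus_onset"]
    withdrawals <- sub$time_s[sub$event == "paw_withdrawal"]
    if (length(onsets) != 1L) {
      stop("validation error: trial ", id, " has ", length(onsets),
           " stimulus_onset rows (expected exactly 1)", call. = FALSE)
    }
    if (length(withdrawals) > 1L) {
      stop("validation error: trial ", id, " has multiple paw_withdrawal rows",
           call. = FALSE)
    }
    if (length(withdrawals) == 1L && withdrawals <= onsets) {
      stop("validation error: trial ", id,
           ": paw_withdrawal not strictly after stimulus_onset",
           call. = FALSE)
    }
  }
  if (!is.null(recording_duration) &&
      any(events$time_s < 0 | events$time_s > recording_duration)) {
    stop("validation error: event times outside the recording [0, ",
         recording_duration, "] s", call. = FALSE)
  }
  events[order(events$time_s), , drop = FALSE]
}

#' Read an event table from CSV
#'
#' @param path CSV file with header `trial_id,event,time_s`.
#' @param recording_duration Optional bound passed to [event_table()].
#' @return Validated event data.frame.
#' @export
read_events <- function(path, recording_duration = NULL) {
  event_table(read.csv(path), recording_duration = recording_duration)
}

#' Read behavioral tables from CSV
#'
#' `read_pwt` expects columns `subject,group,timepoint,trial_index,grams`
#' (per-reading paw-withdrawal forces, 0-50 g instrument range);
#' `read_cpa` expects `subject,group,day,compartment,occupancy_s` with
#' compartments `pain_paired` / `non_pain_paired` and per subject x day
#' occupancy summing to at most the 1800 s session length.
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
read_pwt <- function(path) {
  df <- read.csv(path)
  required <- c("subject", "group", "timepoint", "trial_index", "grams")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("schema error: pwt table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$grams)) || any(df$grams < 0 | df$grams > 50)) {
    bad <- which(!is.finite(df$grams) | df$grams < 0 | df$grams > 50)[1]
    stop("validation error: row ", bad,
         ": grams outside the instrument range [0, 50]", call. = FALSE)
  }
  dup <- duplicated(df[c("subject", "timepoint", "trial_index")])
  if (any(dup)) {
    stop("validation error: duplicate trial_index for subject ",
         df$subject[which(dup)[1]], " at timepoint ",
         df$timepoint[which(dup)[1]], call. = FALSE)
  }
  df
}

#' @rdname read_pwt
#' @param session_length_s Maximum per subject x day occupancy sum (s).
#' @export
read_cpa <- function(path, session_length_s = 1800) {
  df <- read.csv(path)
  required <- c("subject", "group", "day", "compartment", "occupancy_s")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("schema error: cpa table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$compartment), c("pain_paired", "non_pain_paired"))
  if (length(bad)) {
    stop("schema error: unknown compartment label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$occupancy_s)) || any(df$occupancy_s < 0)) {
    stop("validation error: negative or non-finite occupancy_s", call. = FALSE)
  }
  sums <- aggregate(occupancy_s ~ subject + day, df, sum)
  over <- sums$occupancy_s > session_length_s
  if (any(over)) {
    stop("validation error: subject ", sums$subject[which(over)[1]],
         " day ", sums$day[which(over)[1]], ": occupancy sum ",
         sums$occupancy_s[which(over)[1]], " s exceeds the ",
         session_length_s, " s session", call. = FALSE)
  }
  df
}
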