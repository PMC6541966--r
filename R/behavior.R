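#' Paw-withdrawal threshold from a ramp-test series
#'
#' One PWT determination is five consecutive force readings (grams) from the
#' 0-50 g / 20 s ramp; the first reading is discarded and the remaining four
#' averaged.
#'
#' @param measurements Numeric vector of exactly 5 readings in acquisition
#'   order, grams.
#' @return The threshold in grams.
#' @export
pwt_score <- function(measurements) {
  if (length(measurements) != 5L) {
    stop("input error: expected exactly 5 measurements, got ",
         length(measurements), call. = FALSE)
  }
  if (anyNA(measurements) || !all(is.finite(measurements))) {
    stop("input error: non-finite measurement", call. = FALSE)
  }
  mean(measurements[2:5])
}

#' Per-subject paw-withdrawal thresholds from a reading table
#'
#' Applies [pwt_score()] to every subject x timepoint cell of a long-format
#' reading table (see [read_pwt()] for the schema).
#'
#' @param pwt_table data.frame with columns `subject`, `group`, `timepoint`,
#'   `trial_index` (1..5), `grams`.
#' @return data.frame with columns `subject`, `group`, `timepoint`,
#'   `pwt_grams`.
#' @export
pwt_scores <- function(pwt_table) {
  key <- interaction(pwt_table$subject, pwt_table$timepoint, drop = TRUE)
  out <- lapply(split(pwt_table, key), function(cell) {
    cell <- cell[order(cell$trial_index), ]
    data.frame(subject = cell$subject[1], group = cell$group[1],
               timepoint = cell$timepoint[1],
               pwt_grams = pwt_score(cell$grams))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$subject, res$timepoint), ]
}

#' Conditioned place aversion score
#'
#' The CPA score of a subject on a test day is its pain-paired-compartment
#' occupancy on that day minus at baseline (seconds); negative scores mean
#' avoidance of the pain-paired compartment.
#'
#' @param occupancy CPA occupancy table (see [read_cpa()] for the schema).
#' @param subject Subject identifier.
#' @param day Test-day label.
#' @param baseline Baseline day label (default `"baseline"`).
#' @param compartment Compartment scored (default `"pain_paired"`; the
#'   non-pain-paired score is available by passing `"non_pain_paired"`).
#' @return Score in seconds.
#' @export
cpa_score <- function(occupancy, subject, day, baseline = "baseline",
                      compartment = "pain_paired") {
  pick <- function(d) {
    v <- occupancy$occupancy_s[occupancy$subject == subject &
                                 occupancy$day == d &
                                 occupancy$compartment == compartment]
    if (length(v) != 1L) {
      stop("data error: subject ", subject, " has ", length(v), " ",
           compartment, " row(s) for day ", d, " (expected 1)",
           call. = FALSE)
    }
    v
  }
  pick(day) - pick(baseline)
}

#' CPA scores for a whole cohort
#'
#' @param occupancy CPA occupancy table.
#' @param days Test days to score (default: every non-baseline day present).
#' @inheritParams cpa_score
#' @return data.frame with columns `subject`, `group`, `day`, `score_s`.
#' @export
cpa_scores <- function(occupancy, days = NULL, baseline = "baseline",
                       compartment = "pain_paired") {
  if (is.null(days)) {
    days <- setdiff(unique(as.character(occupancy$day)), baseline)
  }
  subjects <- unique(occupancy$subject)
  grid <- expand.grid(subject = subjects, day = days,
                      stringsAsFactors = FALSE)
  grid$group <- occupancy$group[match(grid$subject, occupancy$subject)]
  grid$score_s <- mapply(function(s, d)
    cpa_score(occupancy, s, d, baseline = baseline,
              compartment = compartment),
    grid$subject, grid$day)
  res <- grid[order(grid$subject, grid$day), c("subject", "group", "day", "score_s")]
  rownames(res) <- NULL
  res
}
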