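## Daily monitoring rules: contact a participant who has not synced for
## `sync_lapse_days` whole days or who has `noncompliance_streak_days`
## consecutive noncompliant in-window days. Flags are anchored at the day a
## threshold is first met, clear when the condition ends (a sync, a
## compliant day), and may re-raise for a new streak — mirroring the daily
## human review loop.

#' Detect a sync lapse as of a given day
#'
#' Whole calendar days since the most recent sync on or before `as_of` (or
#' since study start if none); the sync's own day is day 0. A flag is
#' returned when the count reaches `sync_lapse_days`.
#'
#' @param sync_events sorted POSIXct sync instants.
#' @param as_of local calendar `Date` of the review.
#' @param cfg a [monitoring_config()].
#' @param study_start `Date` the participant's stream begins.
#' @param tz_offset_minutes local-time offset for day arithmetic.
#' @return one-row data.frame flag, or `NULL` when below threshold.
#' @export
detect_sync_lapse <- function(sync_events, as_of, cfg = monitoring_config(),
                              study_start, tz_offset_minutes = 0) {
  as_of <- as.Date(as_of)
  study_start <- as.Date(study_start)
  if (as_of < study_start)
    stop("as_of precedes study start", call. = FALSE)
  sd_ <- local_date(sync_events, tz_offset_minutes)
  sd_ <- sd_[sd_ <= as_of]
  anchor <- if (length(sd_)) max(sd_) else study_start
  lapse <- as.integer(as_of - anchor)
  if (lapse < cfg$sync_lapse_days) return(NULL)
  data.frame(flag_type = "sync_lapse", raised_on = as_of,
             detail = sprintf("no sync for %d days (last: %s)",
                              lapse, anchor))
}

#' Detect a noncompliance streak as of a given day
#'
#' Counts the trailing run of noncompliant in-window days ending at the most
#' recent scored in-window day on or before `as_of`; flags when the run
#' reaches `noncompliance_streak_days`.
#'
#' @param day_compliance data.frame with `date` and `compliant` columns
#'   (in-window days only, as produced by [summarize_participant()]).
#' @param as_of local calendar `Date` of the review.
#' @param cfg a [monitoring_config()].
#' @return one-row data.frame flag, or `NULL`.
#' @export
detect_noncompliance_streak <- function(day_compliance, as_of,
                                        cfg = monitoring_config()) {
  as_of <- as.Date(as_of)
  d <- day_compliance[day_compliance$date <= as_of, , drop = FALSE]
  if (nrow(d) == 0L) return(NULL)
  d <- d[order(d$date), ]
  run <- 0L
  for (ok in rev(d$compliant)) {
    if (ok) break
    run <- run + 1L
  }
  if (run < cfg$noncompliance_streak_days) return(NULL)
  data.frame(flag_type = "noncompliance_streak", raised_on = as_of,
             detail = sprintf("%d consecutive noncompliant days through %s",
                              run, max(d$date)))
}

#' Scan a participant's history for monitoring flags
#'
#' Day-by-day review from study start through `through`: each condition
#' raises exactly one flag on the day its threshold is first met, clears
#' when the condition ends, and may re-raise for a fresh streak. Re-running
#' over the same history reproduces the same flags (idempotent).
#'
#' @param record a [participant_record()].
#' @param day_compliance the participant's in-window `days` table
#'   ([summarize_participant()]`$days`).
#' @param through last review `Date` (default: last epoch date).
#' @param cfg a [monitoring_config()].
#' @return data.frame `participant_id, flag_type, raised_on, detail`
#'   (zero rows when nothing fired).
#' @export
monitor_participant <- function(record, day_compliance, through = NULL,
                                cfg = monitoring_config()) {
  off <- record$tz_offset_minutes
  dates <- record_dates(record)
  start <- min(dates)
  through <- as.Date(through %||% max(dates))
  flags <- list()

  # sync lapses: flag the first day the lapse count reaches the threshold
  sync_days <- sort(unique(local_date(record$sync_events, off)))
  prev_lapse <- -1L
  review_days <- seq(start, through, by = "day")
  for (k in seq_along(review_days)) {
    d <- review_days[k]
    anchor <- c(sync_days[sync_days <= d], start)
    lapse <- as.integer(d - max(anchor))
    if (lapse == cfg$sync_lapse_days && prev_lapse < cfg$sync_lapse_days)
      flags[[length(flags) + 1L]] <-
        detect_sync_lapse(record$sync_events, d, cfg, start, off)
    prev_lapse <- lapse
  }

  # noncompliance streaks over the scored in-window days
  if (!is.null(day_compliance) && nrow(day_compliance)) {
    dc <- day_compliance[order(day_compliance$date), ]
    dc <- dc[dc$date <= through, , drop = FALSE]
    run <- 0L
    for (j in seq_len(nrow(dc))) {
      run <- if (dc$compliant[j]) 0L else run + 1L
      if (run == cfg$noncompliance_streak_days)
        flags[[length(flags) + 1L]] <-
          data.frame(flag_type = "noncompliance_streak",
                     raised_on = dc$date[j],
                     detail = sprintf(
                       "%d consecutive noncompliant days through %s",
                       run, dc$date[j]))
    }
  }

  if (!length(flags))
    return(data.frame(participant_id = character(), flag_type = character(),
                      raised_on = as.Date(character()),
                      detail = character()))
  out <- do.call(rbind, flags)
  cbind(participant_id = record$participant_id, out)
}

#' Run monitoring over a scored cohort
#'
#' @param cohort a `wear_cohort`.
#' @param scores matching [score_cohort()] result.
#' @param through last review `Date` (default: each record's last day).
#' @param cfg a [monitoring_config()].
#' @return stacked flags data.frame.
#' @export
monitor_cohort <- function(cohort, scores, through = NULL,
                           cfg = monitoring_config()) {
  flags <- lapply(cohort$records, function(rec) {
    dc <- scores$days[scores$days$participant_id == rec$participant_id, ,
                      drop = FALSE]
    monitor_participant(rec, dc, through, cfg)
  })
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}

#' Render the daily monitoring report
#'
#' A plain-text report listing, per participant, the last sync, the previous
#' day's worn minutes and day/night compliance, active flags, and the
#' cumulative compliance rate, plus a flag section. The first line carries
#' the generation timestamp; everything after it is a deterministic function
#' of the inputs.
#'
#' @param cohort a `wear_cohort`.
#' @param scores matching [score_cohort()] result.
#' @param flags flags data.frame ([monitor_cohort()]).
#' @param date report `Date` ("as of" day).
#' @param file optional path; when given the report is written there.
#' @return character vector of report lines, invisibly.
#' @export
render_daily_report <- function(cohort, scores, flags, date, file = NULL) {
  date <- as.Date(date)
  lines <- c(sprintf("generated: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             sprintf("== daily monitoring report for %s ==", date), "")
  for (rec in cohort$records) {
    id <- rec$participant_id
    s <- scores$summaries[scores$summaries$participant_id == id, , drop = FALSE]
    dd <- scores$days[scores$days$participant_id == id &
                        scores$days$date == date - 1, , drop = FALSE]
    nn <- scores$nights[scores$nights$participant_id == id &
                          scores$nights$night_date == date, , drop = FALSE]
    last_sync <- local_date(max(rec$sync_events[rec$sync_events <=
      as.POSIXct(paste(date + 1, "00:00:00"), tz = "UTC")]),
      rec$tz_offset_minutes)
    active <- flags[flags$participant_id == id & flags$raised_on <= date, ,
                    drop = FALSE]
    lines <- c(lines, sprintf(
      "%s | last sync %s | yesterday: %s worn min, day %s, night %s | cumulative day rate %s%% | flags: %d",
      id, last_sync,
      if (nrow(dd)) dd$awake_worn_minutes else "-",
      if (nrow(dd)) ifelse(dd$compliant, "OK", "MISS") else "-",
      if (nrow(nn)) ifelse(nn$compliant, "OK", "MISS") else "-",
      if (nrow(s)) format(s$day_rate_pct, nsmall = 2) else "-",
      nrow(active)))
  }
  lines <- c(lines, "", "== flags ==")
  fl <- flags[flags$raised_on <= date, , drop = FALSE]
  if (nrow(fl) == 0L) {
    lines <- c(lines, "(none)")
  } else {
    lines <- c(lines, sprintf("%s | %s | raised %s | %s",
                              fl$participant_id, fl$flag_type,
                              fl$raised_on, fl$detail))
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Write the machine-readable flag list
#'
#' @param flags flags data.frame.
#' @param path output CSV (`participant_id,flag_type,raised_on,detail`).
#' @return `path`, invisibly.
#' @export
write_flags_csv <- function(flags, path) {
  utils::write.csv(flags, path, row.names = FALSE)
  invisible(path)
}
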