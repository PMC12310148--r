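#' Infer the per-minute wear mask
#'
#' The non-wear rule: a minute counts as worn iff it carries a heart-rate
#' sample OR a step sample with value > 0. Minutes with no sample on either
#' channel — and worn sedentary minutes whose heart-rate channel is
#' suppressed (clip mode) and whose step count is 0 — are classified not
#' worn. A recorded 0 steps alone is deliberately not wear evidence, since
#' devices register zero steps while off-wrist.
#'
#' @param epochs epoch data.frame of a [participant_record()] (or the record
#'   itself).
#' @return logical vector aligned with the epoch grid.
#' @export
compute_wear_mask <- function(epochs) {
  if (inherits(epochs, "participant_record")) epochs <- epochs$epochs
  (!is.na(epochs$heart_rate)) |
    (!is.na(epochs$steps) & epochs$steps > 0)
}

# minutes of the grid covered by any sleep period: a grid minute belongs to
# a period iff at least 30 s of it lies inside [start, end)
sleep_cover_mask <- function(record) {
  ep_t <- as.numeric(record$epochs$timestamp)
  cov <- rep(FALSE, length(ep_t))
  for (j in seq_len(nrow(record$sleep))) {
    s <- as.numeric(record$sleep$start[j])
    e <- as.numeric(record$sleep$end[j])
    ov <- pmin(ep_t + 60, e) - pmax(ep_t, s)
    cov <- cov | (ov >= 30)
  }
  cov
}

#' Trim the study window
#'
#' Flags each calendar date and each logged night as in or out of the study
#' window: the first and last calendar days are excluded when partial (the
#' grid starts after 00:00 or ends before 23:59 local), and the first logged
#' night is always excluded under `trim_first_night`. A record whose every
#' day is excluded is flagged and should be dropped from summaries.
#'
#' @param record a [participant_record()].
#' @param cfg a [compliance_config()].
#' @return list with `days` (data.frame `date, partial, in_window`) and
#'   `nights` (data.frame `night_date, first_night, in_window`); attribute
#'   `no_study_days` is TRUE when nothing remains.
#' @export
trim_study_window <- function(record, cfg = compliance_config()) {
  off <- record$tz_offset_minutes
  dates <- record_dates(record)
  udays <- sort(unique(dates))
  ep <- record$epochs$timestamp
  partial <- rep(FALSE, length(udays))
  partial[1] <- local_mod(ep[1], off) != 0L
  partial[length(udays)] <- local_mod(ep[length(ep)], off) != 1439L
  in_window <- if (cfg$trim_partial_edge_days) !partial else
    rep(TRUE, length(udays))
  days <- data.frame(date = udays, partial = partial, in_window = in_window)

  nd <- record$sleep$night_date
  first <- if (length(nd)) nd == min(nd) else logical(0)
  nights <- data.frame(night_date = nd, first_night = first,
                       in_window = if (cfg$trim_first_night) !first else
                         rep(TRUE, length(nd)))
  out <- list(days = days, nights = nights)
  if (!any(days$in_window)) {
    warning("participant ", record$participant_id,
            ": no study days after trimming", call. = FALSE)
    attr(out, "no_study_days") <- TRUE
  }
  out
}

#' Score one calendar day against the daytime rule
#'
#' Worn minutes of the local calendar date that are not covered by any sleep
#' period are counted; the day is compliant when the count reaches
#' `day_threshold_min` (inclusive: exactly 600 minutes is compliant).
#' Sleep periods overlapping the date are subtracted minute-wise even when
#' attributed to a different night.
#'
#' @param record a [participant_record()].
#' @param date local calendar `Date` within the epoch range.
#' @param cfg a [compliance_config()].
#' @param mask optional precomputed wear mask ([compute_wear_mask()]).
#' @param sleep_cov optional precomputed sleep cover mask.
#' @return one-row data.frame `date, awake_worn_minutes, compliant`.
#' @export
score_day <- function(record, date, cfg = compliance_config(),
                      mask = compute_wear_mask(record),
                      sleep_cov = sleep_cover_mask(record)) {
  date <- as.Date(date)
  sel <- record_dates(record) == date
  if (!any(sel)) stop("date ", date, " outside the epoch range", call. = FALSE)
  awake_worn <- sum(mask & sel & !sleep_cov)
  data.frame(date = date, awake_worn_minutes = awake_worn,
             compliant = awake_worn >= cfg$day_threshold_min)
}

#' Score one night against the continuous-wear rule
#'
#' The longest run of consecutive worn minutes within the sleep period
#' `[start, end)` is computed; the night is compliant when it reaches
#' `night_threshold_min` (inclusive). Total worn minutes do not matter:
#' two 120-minute runs split by a gap are noncompliant at the 180 threshold.
#'
#' @param record a [participant_record()].
#' @param period one row of the record's `sleep` table (or an index into it).
#' @param cfg a [compliance_config()].
#' @param mask optional precomputed wear mask.
#' @return one-row data.frame `night_date, longest_worn_run_minutes,
#'   compliant`.
#' @export
score_night <- function(record, period, cfg = compliance_config(),
                        mask = compute_wear_mask(record)) {
  if (is.numeric(period)) period <- record$sleep[period, ]
  ep_t <- as.numeric(record$epochs$timestamp)
  s <- as.numeric(period$start[1]); e <- as.numeric(period$end[1])
  inside <- (pmin(ep_t + 60, e) - pmax(ep_t, s)) >= 30
  run <- longest_run(mask[inside])
  data.frame(night_date = as.Date(period$night_date[1]),
             longest_worn_run_minutes = run,
             compliant = run >= cfg$night_threshold_min)
}

#' Summarize a participant's compliance
#'
#' Scores every in-window day and night, then reports counts and two-decimal
#' half-up percentage rates. Nights exist only where a sleep period was
#' logged: a night without a log contributes nothing to the denominator
#' (missing sleep detection is not scored as nonwear). Participants with no
#' in-window days return `NULL` with a warning.
#'
#' @param record a [participant_record()].
#' @param cfg a [compliance_config()].
#' @return list of class `compliance_summary` with the count fields, the
#'   rates, and `$days` / `$nights` detail tables; or `NULL`.
#' @export
summarize_participant <- function(record, cfg = compliance_config()) {
  trim <- trim_study_window(record, cfg)
  if (isTRUE(attr(trim, "no_study_days"))) return(NULL)
  mask <- compute_wear_mask(record)
  sleep_cov <- sleep_cover_mask(record)

  # single tabulation pass; equivalent to per-day score_day() calls
  # (asserted by the recount-oracle tests)
  days_in <- trim$days$date[trim$days$in_window]
  dates <- record_dates(record)
  f <- factor(as.character(dates), levels = as.character(days_in))
  aw <- tapply(mask & !sleep_cov, f, sum)
  aw[is.na(aw)] <- 0L
  day_rows <- data.frame(date = days_in,
                         awake_worn_minutes = as.integer(aw),
                         compliant = as.integer(aw) >= cfg$day_threshold_min,
                         row.names = NULL)
  nights_in <- which(trim$nights$in_window)
  night_rows <- if (length(nights_in))
    do.call(rbind, lapply(nights_in, function(j)
      score_night(record, record$sleep[j, ], cfg, mask)))
  else data.frame(night_date = as.Date(character()),
                  longest_worn_run_minutes = integer(),
                  compliant = logical())

  cd <- sum(day_rows$compliant); sd_ <- nrow(day_rows)
  cn <- sum(night_rows$compliant); sn <- nrow(night_rows)
  structure(list(
    participant_id = record$participant_id, group = record$group,
    compliant_days = cd, study_days = sd_,
    compliant_nights = cn, study_nights = sn,
    day_rate_pct = round_half_up(100 * cd / sd_, 2),
    night_rate_pct = if (sn > 0) round_half_up(100 * cn / sn, 2) else NA_real_,
    days = day_rows, nights = night_rows), class = "compliance_summary")
}

#' Score a whole cohort
#'
#' @param cohort a `wear_cohort` or list of [participant_record()]s.
#' @param cfg a [compliance_config()].
#' @return object of class `cohort_scores`: `summaries` (one row per scored
#'   participant), `days` / `nights` (stacked per-day and per-night detail),
#'   and `dropped` (ids excluded for having no study days).
#' @export
score_cohort <- function(cohort, cfg = compliance_config()) {
  records <- if (inherits(cohort, "wear_cohort")) cohort$records else cohort
  res <- lapply(records, summarize_participant, cfg = cfg)
  dropped <- names(res)[vapply(res, is.null, TRUE)]
  res <- Filter(Negate(is.null), res)
  summaries <- do.call(rbind, lapply(res, function(s)
    data.frame(participant_id = s$participant_id, group = s$group,
               compliant_days = s$compliant_days, study_days = s$study_days,
               compliant_nights = s$compliant_nights,
               study_nights = s$study_nights,
               day_rate_pct = s$day_rate_pct,
               night_rate_pct = s$night_rate_pct)))
  rownames(summaries) <- NULL
  days <- do.call(rbind, lapply(res, function(s)
    cbind(participant_id = s$participant_id, s$days)))
  nights <- do.call(rbind, lapply(res, function(s)
    if (nrow(s$nights)) cbind(participant_id = s$participant_id, s$nights)))
  if (is.null(nights))
    nights <- data.frame(participant_id = character(),
                         night_date = as.Date(character()),
                         longest_worn_run_minutes = integer(),
                         compliant = logical())
  rownames(days) <- rownames(nights) <- NULL
  structure(list(summaries = summaries, days = days, nights = nights,
                 dropped = dropped, config = cfg), class = "cohort_scores")
}

#' @export
print.cohort_scores <- function(x, ...) {
  cat("<cohort_scores>", nrow(x$summaries), "participants,",
      sum(x$summaries$study_days), "study days,",
      sum(x$summaries$study_nights), "study nights\n")
  invisible(x)
}

#' Aggregate compliance over a group
#'
#' Group-level cells in the style of the feasibility tables: totals are sums
#' over participants; medians are midpoint-of-sorted (mean of the central
#' pair for even n, i.e. [stats::median()]); ranges are (min, max).
#'
#' @param summaries the `summaries` data.frame of a [score_cohort()] result
#'   (or a compatible data.frame).
#' @param groups group labels to pool, e.g. `"acute-orthopedic"` or
#'   `c("acute-orthopedic", "acute-cardiac")` for the acute total; the
#'   shorthand `"acute"` expands to that union.
#' @param what `"day"` or `"night"`.
#' @return list of class `group_compliance_stats`.
#' @export
aggregate_group <- function(summaries, groups, what = c("day", "night")) {
  what <- match.arg(what)
  if (identical(groups, "acute"))
    groups <- c("acute-orthopedic", "acute-cardiac")
  assert_group(groups)
  sub <- summaries[summaries$group %in% groups, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no participants in group(s) ", paste(groups, collapse = ", "),
         call. = FALSE)
  ccol <- paste0("compliant_", if (what == "day") "days" else "nights")
  scol <- paste0("study_", if (what == "day") "days" else "nights")
  rcol <- paste0(what, "_rate_pct")
  if (what == "night") sub <- sub[sub[[scol]] > 0, , drop = FALSE]
  comp <- sub[[ccol]]; stud <- sub[[scol]]; rate <- sub[[rcol]]
  structure(list(
    groups = groups, what = what, n = nrow(sub),
    total_compliant = sum(comp), total_study = sum(stud),
    median_compliant = stats::median(comp), range_compliant = range(comp),
    median_study = stats::median(stud), range_study = range(stud),
    median_rate = stats::median(rate), range_rate = range(rate)),
    class = "group_compliance_stats")
}

#' @export
print.group_compliance_stats <- function(x, ...) {
  cat(sprintf(
    "<group_compliance_stats> %s [%s] n=%d\n  compliant %d/%d; per-participant median rate %.2f%% (range %.2f-%.2f)\n",
    paste(x$groups, collapse = "+"), x$what, x$n,
    x$total_compliant, x$total_study,
    x$median_rate, x$range_rate[1], x$range_rate[2]))
  invisible(x)
}
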