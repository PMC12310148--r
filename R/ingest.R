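## Raw-export JSON dialect
##
## One file per participant, mirroring the shape of public intraday API
## responses. Local wall-clock times inside day/sleep entries; UTC instants
## ("...Z") for enrollment bounds and sync events.
##
##   {
##     "participant_id": "CAR-001", "group": "acute-cardiac",
##     "device_profile": "charge3", "tz_offset_minutes": 0,
##     "enrollment_start": "2024-03-01T10:00:00Z",
##     "enrollment_end":   "2024-03-22T12:00:00Z",
##     "days": [{ "date": "2024-03-01", "mode": "wrist",
##                "heart": [{"time": "10:00:00", "value": 72}, ...],
##                "steps": [{"time": "10:00:00", "value": 0},  ...],
##                "summary": {"total_steps": 812, "mean_heart_rate": 71.2,
##                            "worn_minutes": 700, "sleep_minutes": 55} }],
##     "sleep": [{ "startTime": "2024-03-01T23:05:00",
##                 "endTime":   "2024-03-02T07:05:00",
##                 "levels": [{"level": "light", "seconds": 1800}, ...] }],
##     "sync": ["2024-03-02T20:30:00Z", ...],
##     "acceptability": {"comfort": 9, "burden": 1, ...} | null
##   }

#' Write a participant's raw JSON export
#'
#' Serializes a [participant_record()] into the documented raw-export JSON
#' dialect (see the package source header of `ingest.R` and the methods
#' vignette). Unworn minutes produce no entries; worn sedentary minutes
#' produce a step entry with value 0 — absence and zero stay distinct.
#' Output is byte-deterministic for a given record.
#'
#' @param record a [participant_record()].
#' @param path output file path (`.json`).
#' @return `path`, invisibly.
#' @export
write_raw_export <- function(record, path) {
  off <- record$tz_offset_minutes
  ep <- record$epochs
  tl <- ep$timestamp + off * 60
  d <- as.Date(tl, tz = "UTC")
  tim <- format(tl, "%H:%M:%S", tz = "UTC")
  if (is.null(record$daily_summaries))
    record$daily_summaries <- build_day_summaries(record)
  ds <- record$daily_summaries
  days <- lapply(sort(unique(d)), function(dd) {
    i <- which(d == dd)
    ih <- i[!is.na(ep$heart_rate[i])]
    is <- i[!is.na(ep$steps[i])]
    srow <- ds[ds$date == dd, , drop = FALSE]
    list(date = as.character(dd),
         mode = if (any(ep$device_mode[i] == "clip")) "clip" else "wrist",
         heart = data.frame(time = tim[ih], value = ep$heart_rate[ih]),
         steps = data.frame(time = tim[is], value = ep$steps[is]),
         summary = if (nrow(srow)) list(
           total_steps = srow$total_steps[1],
           mean_heart_rate = if (is.na(srow$mean_heart_rate[1])) NULL
                             else srow$mean_heart_rate[1],
           worn_minutes = srow$worn_minutes[1],
           sleep_minutes = srow$sleep_minutes[1]) else NULL)
  })
  sleep <- lapply(seq_len(nrow(record$sleep)), function(j) {
    list(startTime = format(record$sleep$start[j] + off * 60,
                            "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
         endTime = format(record$sleep$end[j] + off * 60,
                          "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
         levels = record$sleep$stages[[j]])
  })
  obj <- list(participant_id = record$participant_id,
              group = record$group,
              device_profile = record$device_profile,
              tz_offset_minutes = off,
              enrollment_start = iso_utc(ep$timestamp[1]),
              enrollment_end = iso_utc(ep$timestamp[nrow(ep)]),
              days = days, sleep = sleep,
              sync = iso_utc(record$sync_events),
              acceptability = record$acceptability)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           null = "null", POSIXt = "ISO8601")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Write a cohort's raw exports and ground-truth wear CSV
#'
#' @param cohort a `wear_cohort`.
#' @param dir output directory (created if missing); one
#'   `<participant_id>.json` per participant plus `ground_truth.csv`
#'   (`participant_id,timestamp,worn`, ISO-8601 UTC).
#' @return `dir`, invisibly.
#' @export
write_cohort_exports <- function(cohort, dir) {
  stopifnot(inherits(cohort, "wear_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$records)
    write_raw_export(rec, file.path(dir, paste0(rec$participant_id, ".json")))
  gt <- do.call(rbind, lapply(cohort$records, function(r)
    data.frame(participant_id = r$participant_id,
               timestamp = iso_utc(r$epochs$timestamp),
               worn = r$truth_worn)))
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Parse a raw JSON export into a validated participant record
#'
#' Rebuilds the contiguous minute grid from the enrollment bounds and places
#' heart-rate and step entries on it. Duplicate timestamps are deduplicated
#' keeping the last entry; entries off the minute grid, heart rates outside
#' [25, 250], or negative steps are dropped as malformed. Sleep logs whose
#' stage records do not tile the period in 30-second multiples are dropped.
#' All drop/dedup counts are returned in `attr(, "ingest_log")`. Overlapping
#' sleep periods are an error, as is an unparseable file.
#'
#' @param path path to a `.json` raw export.
#' @param verbose emit a `message()` with the drop/dedup counts.
#' @return a [participant_record()] (without ground truth).
#' @export
parse_raw_export <- function(path, verbose = FALSE) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e)
                  stop("unparseable export file ", path, ": ",
                       conditionMessage(e), call. = FALSE))
  off <- x$tz_offset_minutes %||% 0
  snap <- function(t) as.POSIXct(round(as.numeric(t)),
                                 origin = "1970-01-01", tz = "UTC")
  t0 <- snap(parse_iso_utc(x$enrollment_start))
  t1 <- snap(parse_iso_utc(x$enrollment_end))
  if (is.na(t0) || is.na(t1) || t1 < t0)
    stop("unparseable export file ", path, ": bad enrollment bounds",
         call. = FALSE)
  grid <- seq(t0, t1, by = 60)
  n <- length(grid)
  log <- c(dedup = 0L, dropped = 0L, sleep_dropped = 0L)

  hr <- rep(NA_real_, n)
  steps <- rep(NA_integer_, n)
  mode <- rep("wrist", n)
  dates <- local_date(grid, off)

  place <- function(day, channel, valid) {
    entries <- day[[channel]]
    if (length(entries) == 0L) return(NULL)
    ts <- local_to_utc(day$date, vapply(entries, `[[`, "", "time"), off)
    # strptime-backed conversion can carry ~1e-11 s float error: snap to s
    ts <- round(as.numeric(ts))
    val <- vapply(entries, function(e) as.numeric(e$value), 0)
    dup <- duplicated(ts, fromLast = TRUE)
    log["dedup"] <<- log["dedup"] + sum(dup)
    ts <- ts[!dup]; val <- val[!dup]
    sec <- ts - round(as.numeric(t0))
    idx <- sec / 60 + 1
    ok <- sec %% 60 == 0 & idx >= 1 & idx <= n & valid(val)
    log["dropped"] <<- log["dropped"] + sum(!ok)
    list(idx = as.integer(idx[ok]), val = val[ok])
  }

  for (day in x$days) {
    h <- place(day, "heart", function(v) v >= 25 & v <= 250)
    if (!is.null(h)) hr[h$idx] <- h$val
    s <- place(day, "steps", function(v) v >= 0)
    if (!is.null(s)) steps[s$idx] <- as.integer(s$val)
    if (identical(day$mode, "clip"))
      mode[dates == as.Date(day$date)] <- "clip"
  }

  sleep_rows <- list()
  for (sl in x$sleep) {
    st <- as.POSIXct(sl$startTime, format = "%Y-%m-%dT%H:%M:%S",
                     tz = "UTC") - off * 60
    en <- as.POSIXct(sl$endTime, format = "%Y-%m-%dT%H:%M:%S",
                     tz = "UTC") - off * 60
    st <- as.POSIXct(round(as.numeric(st)), origin = "1970-01-01", tz = "UTC")
    en <- as.POSIXct(round(as.numeric(en)), origin = "1970-01-01", tz = "UTC")
    lev <- data.frame(
      level = vapply(sl$levels, `[[`, "", "level"),
      seconds = vapply(sl$levels, function(e) as.integer(e$seconds), 0L))
    ok <- !is.na(st) && !is.na(en) && en > st &&
      all(lev$level %in% c("wake", "light", "deep", "rem")) &&
      all(lev$seconds %% 30 == 0) &&
      sum(lev$seconds) == round(as.numeric(en - st, units = "secs"))
    if (!ok) { log["sleep_dropped"] <- log["sleep_dropped"] + 1L; next }
    sleep_rows[[length(sleep_rows) + 1L]] <-
      data.frame(start = st, end = en,
                 night_date = local_date(en, off), stages = I(list(lev)))
  }
  sleep <- if (length(sleep_rows)) do.call(rbind, sleep_rows) else
    data.frame(start = grid[0], end = grid[0],
               night_date = as.Date(character()), stages = I(list()))

  summaries <- do.call(rbind, lapply(x$days, function(day) {
    s <- day$summary
    if (is.null(s)) return(NULL)
    data.frame(participant_id = x$participant_id,
               date = as.Date(day$date),
               total_steps = s$total_steps %||% NA_real_,
               mean_heart_rate = s$mean_heart_rate %||% NA_real_,
               worn_minutes = s$worn_minutes %||% NA_real_,
               sleep_minutes = s$sleep_minutes %||% NA_real_)
  }))

  acc <- x$acceptability
  rec <- participant_record(
    participant_id = x$participant_id, group = x$group,
    device_profile = x$device_profile, tz_offset_minutes = off,
    epochs = data.frame(timestamp = grid, heart_rate = hr, steps = steps,
                        device_mode = mode),
    sleep = sleep, sync_events = parse_iso_utc(unlist(x$sync)),
    acceptability = acc, daily_summaries = summaries)
  attr(rec, "ingest_log") <- log
  if (verbose && sum(log) > 0)
    message(sprintf("%s: %d deduplicated, %d dropped, %d sleep logs dropped",
                    x$participant_id, log["dedup"], log["dropped"],
                    log["sleep_dropped"]))
  rec
}

#' Resample a 30-second sleep-stage log to a per-minute asleep mask
#'
#' A minute (anchored at the period start) is asleep iff at least one of its
#' two 30-second stage records is a non-wake stage. This is the reconciling
#' rule between the 30-second sleep epochs and the 1-minute activity epochs.
#'
#' @param period one row of a record's `sleep` table, or a list with
#'   `start`, `end`, `stages`.
#' @return logical vector, one element per (possibly partial) minute of
#'   `[start, end)`, with minute start instants in
#'   `attr(, "minute_starts")`.
#' @export
resample_sleep_to_minutes <- function(period) {
  stages <- if (is.data.frame(period$stages[[1]])) period$stages[[1]]
            else period$stages
  start <- if (inherits(period$start, "POSIXct")) period$start[1] else
    period$start
  sub <- rep(stages$level, stages$seconds / 30)  # 30-s subepoch labels
  n_min <- ceiling(length(sub) / 2)
  if (length(sub) %% 2 == 1L) sub <- c(sub, "wake")  # pad a trailing half
  m <- matrix(sub != "wake", nrow = 2)
  asleep <- colSums(m) >= 1
  attr(asleep, "minute_starts") <- start + 60 * (seq_len(n_min) - 1)
  asleep
}

#' Daily summaries from the epoch table
#'
#' One row per local calendar date intersecting the epoch grid: total steps,
#' mean heart rate (absent when no sample that day), inferred worn minutes,
#' and asleep minutes from the resampled sleep logs. A date with zero
#' samples yields 0 worn minutes and an absent mean — never an interpolated
#' value.
#'
#' @param record a [participant_record()].
#' @return data.frame `participant_id, date, total_steps, mean_heart_rate,
#'   worn_minutes, sleep_minutes`.
#' @export
build_day_summaries <- function(record) {
  ep <- record$epochs
  dates <- record_dates(record)
  udays <- sort(unique(dates))
  worn <- compute_wear_mask(ep)
  f <- factor(dates, levels = as.character(udays))
  tot <- tapply(ep$steps, f, function(s) sum(s, na.rm = TRUE))
  mhr <- tapply(ep$heart_rate, f, function(h)
    if (all(is.na(h))) NA_real_ else mean(h, na.rm = TRUE))
  wm <- tapply(worn, f, sum)

  slm <- setNames(rep(0L, length(udays)), as.character(udays))
  off <- record$tz_offset_minutes
  for (j in seq_len(nrow(record$sleep))) {
    asleep <- resample_sleep_to_minutes(record$sleep[j, ])
    mins <- attr(asleep, "minute_starts")[asleep]
    tb <- table(as.character(local_date(mins, off)))
    hit <- intersect(names(tb), names(slm))
    slm[hit] <- slm[hit] + as.integer(tb[hit])
  }
  data.frame(participant_id = record$participant_id, date = udays,
             total_steps = as.numeric(tot), mean_heart_rate = as.numeric(mhr),
             worn_minutes = as.integer(wm), sleep_minutes = as.integer(slm),
             row.names = NULL)
}

#' Epoch-table CSV interchange
#'
#' Schema: `participant_id,timestamp,heart_rate,steps,device_mode`, ISO-8601
#' UTC timestamps, empty field = absent sample.
#'
#' @param records a `wear_cohort`, list of records, or single record.
#' @param path output CSV path.
#' @return `path` invisibly (`write_epoch_csv`); a data.frame
#'   (`read_epoch_csv`).
#' @export
write_epoch_csv <- function(records, path) {
  if (inherits(records, "wear_cohort")) records <- records$records
  if (inherits(records, "participant_record")) records <- list(records)
  tab <- do.call(rbind, lapply(records, function(r)
    data.frame(participant_id = r$participant_id,
               timestamp = iso_utc(r$epochs$timestamp),
               heart_rate = r$epochs$heart_rate,
               steps = r$epochs$steps,
               device_mode = r$epochs$device_mode)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_epoch_csv
#' @export
read_epoch_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(participant_id = "character",
                                        timestamp = "character",
                                        heart_rate = "numeric",
                                        steps = "integer",
                                        device_mode = "character"))
  tab$timestamp <- parse_iso_utc(tab$timestamp)
  tab
}

#' Daily-summary CSV interchange
#'
#' Schema: `participant_id,date,total_steps,mean_heart_rate,worn_minutes,
#' sleep_minutes`, empty field = absent.
#'
#' @param summaries data.frame as from [build_day_summaries()] (rows from
#'   several participants may be concatenated).
#' @param path output CSV path.
#' @return `path` invisibly; `read_summary_csv` returns the data.frame.
#' @export
write_summary_csv <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
read_summary_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$date <- as.Date(tab$date)
  tab
}
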