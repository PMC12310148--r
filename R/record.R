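#' Participant record
#'
#' The canonical in-memory container for one participant: a contiguous
#' 1-minute epoch grid (heart rate and steps are `NA` when the device
#' recorded nothing that minute — absence is evidence, so `NA` and 0 steps
#' are deliberately distinct), logged sleep periods with 30-second stage
#' records stored run-length encoded, sync instants, and the acceptability
#' survey response. Simulated records additionally carry `truth_worn`, the
#' generator's per-minute ground truth, so wear inference can be scored
#' against it.
#'
#' @param participant_id opaque deidentified id.
#' @param group one of [GROUP_LABELS].
#' @param device_profile `"charge3"` or `"inspire2"`.
#' @param tz_offset_minutes fixed local-time offset for day boundaries.
#' @param epochs data.frame with columns `timestamp` (POSIXct UTC, strictly
#'   increasing, minute-aligned), `heart_rate`, `steps`, `device_mode`.
#' @param sleep data.frame with columns `start`, `end` (POSIXct UTC),
#'   `night_date` (Date of the wake-up, i.e. `end`), and list-column
#'   `stages` (each a data.frame `level`, `seconds` tiling `[start, end)`
#'   in 30-second multiples).
#' @param sync_events sorted POSIXct sync instants.
#' @param acceptability list with `comfort`, `burden`, optional
#'   `sleep_disturbance`, `adverse_reaction`, `adverse_text`; or `NULL`.
#' @param truth_worn logical ground-truth wear per epoch, or `NULL`.
#' @param daily_summaries data.frame of device daily summaries, or `NULL`.
#' @return object of class `participant_record`.
#' @export
participant_record <- function(participant_id, group, device_profile,
                               tz_offset_minutes, epochs, sleep,
                               sync_events, acceptability = NULL,
                               truth_worn = NULL, daily_summaries = NULL) {
  assert_group(group)
  stopifnot(is.data.frame(epochs),
            all(c("timestamp", "heart_rate", "steps", "device_mode") %in%
                  names(epochs)))
  if (nrow(epochs) > 1 &&
      any(diff(as.numeric(epochs$timestamp)) <= 0))
    stop("epoch timestamps must be strictly increasing", call. = FALSE)
  hr <- epochs$heart_rate
  if (any(!is.na(hr) & (hr < 25 | hr > 250)))
    stop("heart_rate out of physiologic bounds [25, 250]", call. = FALSE)
  if (any(!is.na(epochs$steps) & epochs$steps < 0))
    stop("steps must be non-negative", call. = FALSE)
  if (nrow(sleep) > 1) {
    o <- order(as.numeric(sleep$start))
    s <- sleep[o, ]
    if (any(as.numeric(s$start[-1]) < as.numeric(s$end[-nrow(s)])))
      stop("overlapping sleep periods", call. = FALSE)
    sleep <- s
  }
  if (!is.null(truth_worn) && length(truth_worn) != nrow(epochs))
    stop("truth_worn must align with the epoch grid", call. = FALSE)
  structure(list(participant_id = participant_id, group = group,
                 device_profile = device_profile,
                 tz_offset_minutes = tz_offset_minutes,
                 epochs = epochs, sleep = sleep,
                 sync_events = sync_events,
                 acceptability = acceptability,
                 truth_worn = truth_worn,
                 daily_summaries = daily_summaries),
            class = "participant_record")
}

#' @export
print.participant_record <- function(x, ...) {
  n <- nrow(x$epochs)
  cat(sprintf("<participant_record> %s (%s, %s)\n",
              x$participant_id, x$group, x$device_profile))
  cat(sprintf("  epochs : %d minutes, %s .. %s UTC\n", n,
              iso_utc(x$epochs$timestamp[1]),
              iso_utc(x$epochs$timestamp[n])))
  cat(sprintf("  sleep  : %d logged periods; syncs: %d; ground truth: %s\n",
              nrow(x$sleep), length(x$sync_events),
              if (is.null(x$truth_worn)) "no" else "yes"))
  invisible(x)
}

# minute-grid local dates, memo-free helper used throughout
record_dates <- function(record) {
  local_date(record$epochs$timestamp, record$tz_offset_minutes)
}
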