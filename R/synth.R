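## Synthetic cohort generator.
##
## Streams are generated on the participant's *local* clock (fixed offset,
## no DST) so that day boundaries, sleep schedules and charging gaps are
## stated in wall-clock terms, then stored as UTC instants.

# Realize a worn/off mask of length `len` at stationary wear probability `p`.
# "bouts": alternating geometric bouts with mean worn bout p*cycle and mean
# off bout (1-p)*cycle (stationary worn fraction = p); "iid": Bernoulli(p).
realize_wear <- function(len, p, mode, cycle) {
  if (len == 0L) return(logical(0))
  if (p >= 1) return(rep(TRUE, len))
  if (p <= 0) return(rep(FALSE, len))
  if (mode == "iid") return(stats::runif(len) < p)
  mw <- max(1, p * cycle)
  mn <- max(1, (1 - p) * cycle)
  state <- stats::runif(1) < p
  out <- logical(0)
  while (length(out) < len) {
    k <- max(2L, ceiling((len - length(out)) * 2 / (mw + mn)) + 4L)
    lens_w <- 1L + stats::rgeom(k, 1 / mw)
    lens_n <- 1L + stats::rgeom(k, 1 / mn)
    first <- if (state) lens_w else lens_n
    second <- if (state) lens_n else lens_w
    lens <- as.vector(rbind(first, second))
    vals <- rep(c(state, !state), k)
    out <- c(out, rep(vals, lens))
    # an even number of bouts was appended, so the phase is unchanged
  }
  out[seq_len(len)]
}

# Run-length encoded 30-second stage records tiling `dur_min` minutes.
make_stages <- function(dur_min) {
  units_left <- dur_min * 2L
  levels <- c("wake", "light", "deep", "rem")
  probs <- c(0.06, 0.52, 0.20, 0.22)
  lv <- character(0); ln <- integer(0)
  while (units_left > 0L) {
    l <- sample(levels, 1L, prob = probs)
    k <- min(units_left, 1L + stats::rgeom(1L, 1 / 20))
    lv <- c(lv, l); ln <- c(ln, k)
    units_left <- units_left - k
  }
  data.frame(level = lv, seconds = ln * 30L)
}

#' Generate one synthetic participant
#'
#' Builds a contiguous minute grid from a partial enrollment day through a
#' partial final day (so edge-day trimming has something to trim), one logged
#' sleep period per night attributed to its wake-up date, ground-truth wear
#' realized from the group's day/night wear propensities (geometric bouts by
#' default), weekly charging gaps, clip-mode days, sync events every 2-3
#' days, and an acceptability response drawn from the group profile.
#'
#' Channel semantics: a worn minute always yields a heart-rate sample (unless
#' the device is in clip mode) and a step sample (0 when sedentary); an
#' unworn minute yields no sample on either channel.
#'
#' @param group one of [GROUP_LABELS].
#' @param cfg a [sim_config()].
#' @param participant_index positive integer, unique within the cohort.
#' @return a [participant_record()] with `truth_worn` attached.
#' @export
generate_participant <- function(group, cfg, participant_index) {
  assert_group(group)
  stopifnot(inherits(cfg, "sim_config"), participant_index >= 1)
  seed <- substream_seed(cfg$seed, group, participant_index)
  with_seed(seed, generate_participant_impl(group, cfg, participant_index))
}

generate_participant_impl <- function(group, cfg, participant_index) {
  off <- cfg$tz_offset_minutes
  sd_days <- group_param(cfg$study_days, group)
  p_day <- group_param(cfg$wear_prob_day, group)
  p_night <- group_param(cfg$wear_prob_night, group)
  day0 <- cfg$start_date
  midnight0 <- as.POSIXct(paste(day0, "00:00:00"), tz = "UTC")

  # local grid: partial first day (start 10:00-18:00) .. partial last day
  start_l <- midnight0 + 60 * round(stats::runif(1, 600, 1080))
  end_l <- midnight0 + 86400 * (sd_days + 1) +
    60 * round(stats::runif(1, 480, 960))
  grid_l <- seq(start_l, end_l, by = 60)
  n <- length(grid_l)

  # one sleep period per night; night_date = wake-up date
  n_nights <- sd_days + 1L
  onset_min <- 23 * 60 + stats::rnorm(n_nights, 0, cfg$sleep_start_sd_minutes) +
    (cfg$sleep_start_hour - 23) * 60
  onset_min <- pmin(pmax(round(onset_min), 21.5 * 60), 25 * 60)
  dur <- round(stats::rnorm(n_nights, cfg$mean_sleep_minutes,
                            cfg$sleep_sd_minutes))
  dur <- pmin(pmax(dur, 180), 720)
  sl_start <- midnight0 + 86400 * (seq_len(n_nights) - 1L) + 60 * onset_min
  sl_end <- pmin(sl_start + 60 * dur, end_l + 60)
  keep <- sl_start >= start_l & sl_end > sl_start
  sl_start <- sl_start[keep]; sl_end <- sl_end[keep]
  stages <- lapply(as.integer((as.numeric(sl_end) - as.numeric(sl_start)) / 60),
                   make_stages)

  # regime per grid minute: inside any sleep period -> night propensity
  asleep <- rep(FALSE, n)
  for (j in seq_along(sl_start)) {
    i1 <- as.integer((as.numeric(sl_start[j]) - as.numeric(start_l)) / 60) + 1L
    i2 <- as.integer((as.numeric(sl_end[j]) - as.numeric(start_l)) / 60)
    asleep[max(1L, i1):min(n, i2)] <- TRUE
  }

  worn <- logical(n)
  seg <- rle(asleep)
  pos <- 1L
  for (k in seq_along(seg$lengths)) {
    len <- seg$lengths[k]
    p <- if (seg$values[k]) p_night else p_day
    worn[pos:(pos + len - 1L)] <-
      realize_wear(len, p, cfg$wear_mode, cfg$bout_cycle_minutes)
    pos <- pos + len
  }

  # weekly charging gap: device off-wrist at ~19:00 every charge interval
  if (cfg$charge_gap_minutes > 0 && is.finite(cfg$charge_interval_days)) {
    d <- cfg$charge_interval_days
    while (d <= sd_days + 1) {
      g1 <- midnight0 + 86400 * d + 60 * (19 * 60 + round(stats::runif(1, 0, 120)))
      i1 <- as.integer((as.numeric(g1) - as.numeric(start_l)) / 60) + 1L
      i2 <- i1 + cfg$charge_gap_minutes - 1L
      if (i2 >= 1L && i1 <= n) worn[max(1L, i1):min(n, i2)] <- FALSE
      d <- d + cfg$charge_interval_days
    }
  }

  # channels: HR bounded lognormal around a participant resting rate,
  # lower during sleep; steps zero-inflated when awake, ~0 during sleep
  hr_rest <- stats::rnorm(1, cfg$hr_rest_mean, cfg$hr_rest_sd)
  hr <- rep(NA_real_, n)
  iw <- which(worn)
  fac <- ifelse(asleep[iw], 0.88, 1.05)
  hr[iw] <- round(pmin(180, pmax(40, hr_rest * fac *
                                   stats::rlnorm(length(iw), 0, 0.08))))
  steps <- rep(NA_integer_, n)
  awake_w <- which(worn & !asleep)
  active <- stats::runif(length(awake_w)) < 0.35
  sw <- integer(length(awake_w))
  sw[active] <- stats::rpois(sum(active), 30)
  steps[awake_w] <- sw
  sleep_w <- which(worn & asleep)
  steps[sleep_w] <- ifelse(stats::runif(length(sleep_w)) < 0.02,
                           stats::rpois(length(sleep_w), 5), 0L)

  # sync every 2-3 days at 20:30 local, plus a final sync at study end
  gaps <- sample(rep(cfg$sync_interval_days, length.out = 2 * (sd_days + 2)),
                 sd_days + 2, replace = TRUE)
  sync_d <- cumsum(gaps)
  sync_d <- sync_d[sync_d <= sd_days]
  sync_l <- c(midnight0 + 86400 * sync_d + 60 * (20 * 60 + 30), end_l)

  # clip-mode days (sampled here; applied via inject_clip_mode)
  all_dates <- seq(day0, day0 + sd_days + 1, by = "day")
  clip_dates <- all_dates[stats::runif(length(all_dates)) < cfg$clip_mode_prob]

  prof <- cfg$acceptability[[group]]
  clip01 <- function(x) min(10, max(0, x))
  acc <- list(
    comfort = clip01(stats::rnorm(1, prof$comfort_mean, prof$comfort_sd)),
    burden = clip01(stats::rnorm(1, prof$burden_mean, prof$burden_sd)),
    sleep_disturbance = if (group == "chronic-IIPT")
      clip01(stats::rnorm(1, prof$sleep_disturbance_mean,
                          prof$sleep_disturbance_sd)) else NULL,
    adverse_reaction = stats::runif(1) < prof$adverse_prob)
  acc$adverse_text <- if (acc$adverse_reaction) "mild wrist irritation" else NULL

  code <- c("acute-orthopedic" = "ORT", "acute-cardiac" = "CAR",
            "chronic-IIPT" = "IIP")[[group]]
  rec <- participant_record(
    participant_id = sprintf("%s-%03d", code, participant_index),
    group = group,
    device_profile = if (group == "acute-cardiac") "charge3" else "inspire2",
    tz_offset_minutes = off,
    epochs = data.frame(timestamp = grid_l - off * 60,
                        heart_rate = hr, steps = steps,
                        device_mode = rep("wrist", n)),
    sleep = data.frame(start = sl_start - off * 60,
                       end = sl_end - off * 60,
                       night_date = as.Date(sl_end, tz = "UTC"),
                       stages = I(stages)),
    sync_events = sync_l - off * 60,
    acceptability = acc,
    truth_worn = worn)
  if (length(clip_dates)) rec <- inject_clip_mode(rec, clip_dates)
  rec
}

#' Put selected days into clip mode
#'
#' Clip mode deactivates the optical (PPG) skin sensor: on the affected local
#' calendar days heart-rate samples are removed and any sleep period touching
#' those days is suppressed from the log, while step counts are retained.
#' A suppressed night contributes nothing to the sleep denominator
#' downstream. Ground-truth wear annotations are untouched.
#'
#' @param record a [participant_record()].
#' @param days `Date` vector within the record's study window.
#' @return the modified record.
#' @export
inject_clip_mode <- function(record, days) {
  days <- as.Date(days)
  if (length(days) == 0L) return(record)
  dates <- record_dates(record)
  rng <- range(dates)
  bad <- days[days < rng[1] | days > rng[2]]
  if (length(bad))
    stop("clip-mode date outside study window: ",
         paste(bad, collapse = ", "), call. = FALSE)
  idx <- dates %in% days
  record$epochs$device_mode[idx] <- "clip"
  record$epochs$heart_rate[idx] <- NA_real_
  if (nrow(record$sleep)) {
    off <- record$tz_offset_minutes
    touches <- vapply(seq_len(nrow(record$sleep)), function(j) {
      d1 <- local_date(record$sleep$start[j], off)
      d2 <- local_date(record$sleep$end[j], off)
      any(seq(d1, d2, by = "day") %in% days)
    }, logical(1))
    record$sleep <- record$sleep[!touches, , drop = FALSE]
  }
  record
}

#' Apply on-device storage truncation
#'
#' Consumer devices retain high-resolution (minute-level) data for roughly a
#' week; data older than `storage_window_days` at the time of the sync that
#' would first transmit it is discarded, leaving only daily summaries. A
#' minute with no subsequent sync at all is likewise lost. Daily summaries
#' are computed before truncation and survive for every study day.
#'
#' @param record a [participant_record()].
#' @param sync_times sorted POSIXct sync instants (default: the record's).
#' @param storage_window_days retention window in days (default 7).
#' @return the record with unretained minute samples blanked; the number of
#'   lost minute-samples is in `attr(record, "minutes_lost")`.
#' @export
apply_storage_truncation <- function(record,
                                     sync_times = record$sync_events,
                                     storage_window_days = 7) {
  if (is.unsorted(as.numeric(sync_times)))
    stop("sync_times must be sorted ascending", call. = FALSE)
  if (is.null(record$daily_summaries))
    record$daily_summaries <- build_day_summaries(record)
  tnum <- as.numeric(record$epochs$timestamp)
  snum <- as.numeric(sync_times)
  if (length(snum) == 0L) {
    lost <- rep(TRUE, length(tnum))  # never transmitted at all
  } else {
    pos <- findInterval(tnum - 0.5, snum) + 1L  # first sync at or after t
    lost <- pos > length(snum) |
      (snum[pmin(pos, length(snum))] - tnum) > storage_window_days * 86400
  }
  had <- !is.na(record$epochs$heart_rate) | !is.na(record$epochs$steps)
  record$epochs$heart_rate[lost] <- NA_real_
  record$epochs$steps[lost] <- NA_integer_
  attr(record, "minutes_lost") <- sum(lost & had)
  record
}

#' Generate a synthetic cohort
#'
#' One record per participant per group (sizes from `cfg$n_per_group`), each
#' from an independent seeded substream, with clip-mode days and on-device
#' storage truncation applied, plus an acceptability response per
#' participant. Identical `(config, seed)` reproduces the cohort exactly.
#'
#' @param cfg a [sim_config()].
#' @return object of class `wear_cohort`: list with `records` (named list of
#'   [participant_record()]) and `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (sum(cfg$n_per_group) == 0)
    stop("n_per_group is zero for every group", call. = FALSE)
  records <- list()
  for (g in GROUP_LABELS) {
    ng <- if (g %in% names(cfg$n_per_group)) cfg$n_per_group[[g]] else 0
    for (i in seq_len(ng)) {
      rec <- generate_participant(g, cfg, i)
      rec <- apply_storage_truncation(rec, rec$sync_events,
                                      cfg$storage_window_days)
      records[[rec$participant_id]] <- rec
    }
  }
  structure(list(records = records, config = cfg), class = "wear_cohort")
}

#' @export
print.wear_cohort <- function(x, ...) {
  groups <- vapply(x$records, `[[`, "", "group")
  cat("<wear_cohort>", length(x$records), "participants:",
      paste(sprintf("%s=%d", names(table(groups)), table(groups)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Acceptability responses of a cohort as a table
#'
#' @param cohort a `wear_cohort` (or list of records).
#' @return data.frame, one row per participant with the survey items; the
#'   sleep-disturbance column is `NA` for acute participants (not assessed).
#' @export
acceptability_table <- function(cohort) {
  records <- if (inherits(cohort, "wear_cohort")) cohort$records else cohort
  rows <- lapply(records, function(r) {
    a <- r$acceptability
    data.frame(participant_id = r$participant_id, group = r$group,
               comfort = a$comfort %||% NA_real_,
               burden = a$burden %||% NA_real_,
               sleep_disturbance = a$sleep_disturbance %||% NA_real_,
               adverse_reaction = isTRUE(a$adverse_reaction))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
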