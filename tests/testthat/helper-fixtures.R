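# Toy-record builders used across the suite. Everything is constructed in
# code; no fixture files.

# A record whose epoch grid and channels are stated explicitly.
# worn: logical vector; worn minutes get HR 70 (unless clip) and steps as
# given (default 0); unworn minutes carry no sample on either channel.
toy_record <- function(worn,
                       start = "2024-01-01T00:00:00Z",
                       steps = NULL,
                       sleep = NULL,
                       sync = NULL,
                       group = "acute-cardiac",
                       id = "TOY-001",
                       tz_offset_minutes = 0) {
  n <- length(worn)
  t0 <- wearcomply:::parse_iso_utc(start)
  grid <- t0 + 60 * (seq_len(n) - 1)
  hr <- ifelse(worn, 70, NA_real_)
  st <- if (is.null(steps)) ifelse(worn, 0L, NA_integer_)
        else ifelse(worn, steps, NA_integer_)
  sleep_df <- if (is.null(sleep))
    data.frame(start = grid[0], end = grid[0],
               night_date = as.Date(character()), stages = I(list()))
  else sleep
  participant_record(
    participant_id = id, group = group, device_profile = "charge3",
    tz_offset_minutes = tz_offset_minutes,
    epochs = data.frame(timestamp = grid, heart_rate = hr,
                        steps = as.integer(st),
                        device_mode = rep("wrist", n)),
    sleep = sleep_df,
    sync_events = if (is.null(sync)) grid[n] else sync,
    truth_worn = worn)
}

# sleep table with one all-light period per (start, minutes) pair
toy_sleep <- function(starts, minutes) {
  starts <- wearcomply:::parse_iso_utc(starts)
  ends <- starts + 60 * minutes
  data.frame(start = starts, end = ends,
             night_date = as.Date(ends, tz = "UTC"),
             stages = I(lapply(minutes, function(m)
               data.frame(level = "light", seconds = m * 60L))))
}

# small fast simulation config for unit tests
tiny_cfg <- function(seed = 1, ...) {
  defaults <- list(
    n_per_group = c("acute-orthopedic" = 1, "acute-cardiac" = 1,
                    "chronic-IIPT" = 1),
    study_days = c("acute-orthopedic" = 4, "acute-cardiac" = 4,
                   "chronic-IIPT" = 4),
    seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# independent per-minute re-evaluation of the non-wear rule
oracle_wear <- function(epochs) {
  out <- logical(nrow(epochs))
  for (i in seq_len(nrow(epochs))) {
    hr <- epochs$heart_rate[i]; st <- epochs$steps[i]
    out[i] <- (!is.na(hr)) || (!is.na(st) && st > 0)
  }
  out
}

# brute-force longest run of TRUE
oracle_longest_run <- function(x) {
  best <- 0L; cur <- 0L
  for (v in x) {
    cur <- if (isTRUE(v)) cur + 1L else 0L
    best <- max(best, cur)
  }
  best
}

# exact two-sided Mann-Whitney p by full enumeration of rank labelings
oracle_mw_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  idx <- utils::combn(nx + ny, nx)
  us <- apply(idx, 2, function(ii) {
    a <- pool[ii]; b <- pool[-ii]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  })
  u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  p_lo <- mean(us <= u); p_hi <- mean(us >= u)
  min(1, 2 * min(p_lo, p_hi))
}
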