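# Parser, sleep resampling, day summaries, CSV interchange.

# a hand-written minimal export in the documented dialect, independent of
# the package's writer
write_minimal_export <- function(path, dup_heart = FALSE) {
  hr <- sprintf('{"time":"%02d:%02d:00","value":%d}',
                rep(0:23, each = 60), rep(0:59, 24), 70)
  if (dup_heart)
    hr <- c(hr, '{"time":"00:00:00","value":80}')  # duplicate, keep-last
  json <- paste0('{
    "participant_id":"MAN-001","group":"acute-cardiac",
    "device_profile":"charge3","tz_offset_minutes":0,
    "enrollment_start":"2024-05-01T00:00:00Z",
    "enrollment_end":"2024-05-01T23:59:00Z",
    "days":[{"date":"2024-05-01","mode":"wrist",
      "heart":[', paste(hr, collapse = ","), '],
      "steps":[{"time":"12:00:00","value":3},{"time":"12:01:00","value":0}],
      "summary":{"total_steps":3,"mean_heart_rate":70,
                 "worn_minutes":1440,"sleep_minutes":480}}],
    "sleep":[{"startTime":"2024-05-01T01:00:00",
              "endTime":"2024-05-01T09:00:00",
              "levels":[{"level":"light","seconds":28800}]}],
    "sync":["2024-05-01T23:59:00Z"],
    "acceptability":null}')
  writeLines(json, path)
  path
}

test_that("a minimal export maps directly onto the record", {
  f <- withr::local_tempfile(fileext = ".json")
  write_minimal_export(f)
  rec <- parse_raw_export(f)
  expect_s3_class(rec, "participant_record")
  expect_equal(nrow(rec$epochs), 1440)
  expect_true(all(rec$epochs$heart_rate == 70))
  expect_equal(nrow(rec$sleep), 1)
  expect_equal(as.numeric(rec$sleep$end - rec$sleep$start, units = "mins"),
               480)
  expect_equal(rec$sleep$night_date, as.Date("2024-05-01"))
  expect_equal(sum(rec$epochs$steps, na.rm = TRUE), 3)
  # absent vs zero steps stay distinct
  expect_equal(sum(!is.na(rec$epochs$steps)), 2)
  expect_equal(unname(attr(rec, "ingest_log")["dedup"]), 0)
})

test_that("duplicate timestamps deduplicate keep-last with a logged count", {
  f <- withr::local_tempfile(fileext = ".json")
  write_minimal_export(f, dup_heart = TRUE)
  rec <- parse_raw_export(f)
  expect_equal(unname(attr(rec, "ingest_log")["dedup"]), 1)
  expect_equal(rec$epochs$heart_rate[1], 80)  # the later entry wins
})

test_that("malformed input errors name the file; bad entries are dropped", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", f)
  expect_error(parse_raw_export(f), basename(f), fixed = TRUE)

  # heart rate outside [25, 250] dropped, not kept
  g <- withr::local_tempfile(fileext = ".json")
  json <- '{
    "participant_id":"MAN-002","group":"acute-cardiac",
    "device_profile":"charge3","tz_offset_minutes":0,
    "enrollment_start":"2024-05-01T00:00:00Z",
    "enrollment_end":"2024-05-01T00:59:00Z",
    "days":[{"date":"2024-05-01","mode":"wrist",
      "heart":[{"time":"00:00:00","value":400},
               {"time":"00:01:00","value":72}],
      "steps":[],"summary":null}],
    "sleep":[],"sync":[],"acceptability":null}'
  writeLines(json, g)
  rec <- parse_raw_export(g)
  expect_true(is.na(rec$epochs$heart_rate[1]))
  expect_equal(rec$epochs$heart_rate[2], 72)
  expect_equal(unname(attr(rec, "ingest_log")["dropped"]), 1)
})

test_that("overlapping sleep periods are an error", {
  f <- withr::local_tempfile(fileext = ".json")
  json <- '{
    "participant_id":"MAN-003","group":"acute-cardiac",
    "device_profile":"charge3","tz_offset_minutes":0,
    "enrollment_start":"2024-05-01T00:00:00Z",
    "enrollment_end":"2024-05-02T23:59:00Z",
    "days":[],
    "sleep":[{"startTime":"2024-05-01T01:00:00",
              "endTime":"2024-05-01T09:00:00",
              "levels":[{"level":"light","seconds":28800}]},
             {"startTime":"2024-05-01T08:00:00",
              "endTime":"2024-05-01T10:00:00",
              "levels":[{"level":"light","seconds":7200}]}],
    "sync":[],"acceptability":null}'
  writeLines(json, f)
  expect_error(parse_raw_export(f), "overlap")
})

test_that("a simulated cohort round-trips through write and parse", {
  co <- generate_cohort(tiny_cfg(seed = 21))
  d <- withr::local_tempdir()
  write_cohort_exports(co, d)
  for (id in names(co$records)) {
    r1 <- co$records[[id]]
    r2 <- parse_raw_export(file.path(d, paste0(id, ".json")))
    expect_equal(r2$epochs, r1$epochs, label = id)
    expect_equal(r2$sleep$start, r1$sleep$start)
    expect_equal(r2$sleep$end, r1$sleep$end)
    expect_equal(r2$sleep$night_date, r1$sleep$night_date)
    expect_equal(r2$sleep$stages, r1$sleep$stages, ignore_attr = TRUE)
    expect_equal(as.numeric(r2$sync_events), as.numeric(r1$sync_events))
    expect_equal(r2$acceptability$comfort, r1$acceptability$comfort)
    expect_identical(r2$group, r1$group)
    expect_equal(sum(attr(r2, "ingest_log")), 0)
  }
})

test_that("sleep resampling follows the >=1-subepoch rule", {
  # all-light 480-minute period: every minute asleep
  p <- toy_sleep("2024-01-01T23:00:00Z", 480)
  expect_equal(sum(resample_sleep_to_minutes(p[1, ])), 480)

  # alternating wake/light 30-s records: every minute asleep under >=1 rule
  alt <- list(start = wearcomply:::parse_iso_utc("2024-01-01T23:00:00Z"),
              end = wearcomply:::parse_iso_utc("2024-01-01T23:30:00Z"),
              stages = data.frame(level = rep(c("wake", "light"), 30),
                                  seconds = 30L))
  expect_true(all(resample_sleep_to_minutes(alt)))

  # random stage sequences match per-minute brute force
  set.seed(4)
  for (k in 1:20) {
    n_units <- sample(4:40, 1)
    labs <- sample(c("wake", "light", "deep", "rem"), n_units, replace = TRUE)
    per <- list(start = wearcomply:::parse_iso_utc("2024-01-01T22:00:00Z"),
                end = wearcomply:::parse_iso_utc("2024-01-01T22:00:00Z") +
                  30 * n_units,
                stages = data.frame(level = labs, seconds = 30L))
    got <- resample_sleep_to_minutes(per)
    want <- vapply(seq_len(ceiling(n_units / 2)), function(m) {
      sub <- labs[(2 * m - 1):min(2 * m, n_units)]
      any(sub != "wake")
    }, logical(1))
    expect_equal(as.logical(got), want)
  }
})

test_that("day summaries match an independent group-by pass and conserve steps", {
  rec <- generate_participant("chronic-IIPT", tiny_cfg(seed = 31), 1)
  ds <- build_day_summaries(rec)

  # independent recomputation: split epochs by date
  dates <- wearcomply:::record_dates(rec)
  for (d in unique(dates)) {
    i <- dates == d
    row <- ds[ds$date == d, ]
    expect_equal(row$total_steps, sum(rec$epochs$steps[i], na.rm = TRUE))
    hrs <- rec$epochs$heart_rate[i]
    if (all(is.na(hrs))) expect_true(is.na(row$mean_heart_rate))
    else expect_equal(row$mean_heart_rate, mean(hrs, na.rm = TRUE))
    expect_equal(row$worn_minutes, sum(oracle_wear(rec$epochs[i, ])))
  }
  expect_equal(sum(ds$total_steps), sum(rec$epochs$steps, na.rm = TRUE))

  # explicit tiny case: steps {3, 0, absent...} -> total 3
  worn <- c(TRUE, TRUE, rep(FALSE, 58))
  toy <- toy_record(worn, steps = c(3L, 0L, rep(NA, 58)))
  expect_equal(build_day_summaries(toy)$total_steps, 3)

  # clip-mode day: HR absent in summary, steps preserved
  cl <- inject_clip_mode(rec, sort(unique(dates))[2])
  ds_cl <- build_day_summaries(cl)
  d2 <- sort(unique(dates))[2]
  expect_true(is.na(ds_cl$mean_heart_rate[ds_cl$date == d2]))
  expect_equal(ds_cl$total_steps[ds_cl$date == d2],
               ds$total_steps[ds$date == d2])
})

test_that("epoch and summary CSV schemas round-trip", {
  co <- generate_cohort(tiny_cfg(seed = 51))
  d <- withr::local_tempdir()
  ep_path <- file.path(d, "epochs.csv")
  write_epoch_csv(co, ep_path)
  tab <- read_epoch_csv(ep_path)
  expect_named(tab, c("participant_id", "timestamp", "heart_rate", "steps",
                      "device_mode"))
  one <- co$records[[1]]
  sub <- tab[tab$participant_id == one$participant_id, ]
  expect_equal(nrow(sub), nrow(one$epochs))
  expect_equal(sub$heart_rate, one$epochs$heart_rate)
  expect_equal(sub$steps, one$epochs$steps)

  ds <- do.call(rbind, lapply(co$records, build_day_summaries))
  sm_path <- file.path(d, "summaries.csv")
  write_summary_csv(ds, sm_path)
  back <- read_summary_csv(sm_path)
  expect_equal(back$total_steps, ds$total_steps, ignore_attr = TRUE)
  expect_equal(back$worn_minutes, ds$worn_minutes, ignore_attr = TRUE)
})
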