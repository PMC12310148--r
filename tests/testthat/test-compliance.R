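# Wear inference, trimming, day/night scoring, aggregation.

test_that("the non-wear rule applies minute by minute", {
  ep <- data.frame(
    timestamp = wearcomply:::parse_iso_utc("2024-01-01T00:00:00Z") +
      60 * (0:3),
    heart_rate = c(72, NA, NA, NA),
    steps = c(NA, NA, 0L, 5L),
    device_mode = "wrist")
  expect_identical(compute_wear_mask(ep), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("wear mask equals the oracle and the simulator's ground truth", {
  # >= 10 simulated participant-days, artifact-free
  cfg <- tiny_cfg(seed = 61, clip_mode_prob = 0,
                  study_days = c("acute-orthopedic" = 4,
                                 "acute-cardiac" = 4, "chronic-IIPT" = 4))
  for (g in GROUP_LABELS) {
    rec <- generate_participant(g, cfg, 1)
    mask <- compute_wear_mask(rec)
    expect_identical(mask, oracle_wear(rec$epochs))
    expect_identical(mask, rec$truth_worn)
  }
  # with clip-mode days, disagreement is confined to worn-sedentary minutes
  rec <- generate_participant("acute-cardiac", cfg, 2)
  dates <- sort(unique(wearcomply:::record_dates(rec)))
  cl <- inject_clip_mode(rec, dates[2:3])
  mask <- compute_wear_mask(cl)
  dis <- which(mask != cl$truth_worn)
  expect_true(all(cl$truth_worn[dis]))           # only missed wear
  expect_true(all(cl$epochs$steps[dis] == 0))    # only sedentary minutes
})

test_that("edge-day trimming matches the stated rules", {
  # stream 2024-01-01 09:00 -> 2024-01-20 14:00: study days Jan 2..19
  n <- as.integer(as.numeric(
    wearcomply:::parse_iso_utc("2024-01-20T14:00:00Z") -
      wearcomply:::parse_iso_utc("2024-01-01T09:00:00Z"),
    units = "mins")) + 1L
  rec <- toy_record(rep(TRUE, n), start = "2024-01-01T09:00:00Z")
  tr <- trim_study_window(rec)
  inw <- tr$days$date[tr$days$in_window]
  expect_equal(length(inw), 18)
  expect_equal(min(inw), as.Date("2024-01-02"))
  expect_equal(max(inw), as.Date("2024-01-19"))

  # exactly 00:00 -> 23:59 spanning full days: nothing trimmed
  full <- toy_record(rep(TRUE, 2 * 1440), start = "2024-01-01T00:00:00Z")
  tr2 <- trim_study_window(full)
  expect_true(all(tr2$days$in_window))

  # 5 logged nights -> 4 study nights
  sleeps <- toy_sleep(sprintf("2024-01-%02dT23:00:00Z", 1:5), rep(300, 5))
  rec5 <- toy_record(rep(TRUE, 8 * 1440), sleep = sleeps)
  tr3 <- trim_study_window(rec5)
  expect_equal(sum(tr3$nights$in_window), 4)
  expect_false(tr3$nights$in_window[1])

  # all-partial stream flags "no study days"
  short <- toy_record(rep(TRUE, 120), start = "2024-01-01T10:00:00Z")
  expect_warning(tr4 <- trim_study_window(short), "no study days")
  expect_true(attr(tr4, "no_study_days"))
})

test_that("day scoring is inclusive at the threshold and excludes sleep", {
  day <- function(worn_min) {
    worn <- rep(FALSE, 1440)
    if (worn_min > 0) worn[seq_len(worn_min)] <- TRUE
    toy_record(worn)
  }
  expect_true(score_day(day(600), "2024-01-01")$compliant)
  expect_false(score_day(day(599), "2024-01-01")$compliant)

  # fully worn day with a 480-min sleep period: 960 awake worn minutes
  rec <- toy_record(rep(TRUE, 1440),
                    sleep = toy_sleep("2024-01-01T01:00:00Z", 480))
  sd_ <- score_day(rec, "2024-01-01")
  expect_equal(sd_$awake_worn_minutes, 960)
  expect_true(sd_$compliant)

  expect_error(score_day(day(10), "2031-01-01"), "outside")
})

test_that("night scoring demands continuity, not total minutes", {
  night <- function(worn_during_sleep) {
    worn <- rep(TRUE, 1440)
    worn[61:(60 + length(worn_during_sleep))] <- worn_during_sleep
    toy_record(worn, sleep = toy_sleep("2024-01-01T01:00:00Z",
                                       length(worn_during_sleep)))
  }
  # unbroken 180-minute run: compliant (inclusive)
  r1 <- night(rep(TRUE, 180))
  expect_true(score_night(r1, 1)$compliant)
  # 179: not
  r2 <- night(c(rep(TRUE, 179), FALSE))
  expect_false(score_night(r2, 1)$compliant)
  # two 120-min runs split by a 10-min gap: 240 total but noncompliant
  r3 <- night(c(rep(TRUE, 120), rep(FALSE, 10), rep(TRUE, 120)))
  s3 <- score_night(r3, 1)
  expect_equal(s3$longest_worn_run_minutes, 120)
  expect_false(s3$compliant)

  # random masks: longest run equals the brute-force scan
  set.seed(8)
  for (k in 1:25) {
    m <- runif(sample(50:400, 1)) < 0.7
    r <- night(m)
    expect_equal(score_night(r, 1)$longest_worn_run_minutes,
                 oracle_longest_run(m))
    expect_equal(longest_run(m), oracle_longest_run(m))
  }
})

test_that("participant summaries equal an independent per-day recount", {
  rec <- generate_participant("acute-cardiac", tiny_cfg(seed = 71), 1)
  s <- summarize_participant(rec)
  # recount with score_day() date by date
  tr <- trim_study_window(rec)
  recount <- vapply(tr$days$date[tr$days$in_window], function(d)
    score_day(rec, d)$compliant, logical(1))
  expect_equal(s$compliant_days, sum(recount))
  expect_equal(s$study_days, length(recount))
  nrecount <- vapply(which(tr$nights$in_window), function(j)
    score_night(rec, j)$compliant, logical(1))
  expect_equal(s$compliant_nights, sum(nrecount))
  expect_equal(s$study_nights, length(nrecount))
  expect_equal(s$day_rate_pct,
               round_half_up(100 * sum(recount) / length(recount), 2))
})

test_that("percentage formatting matches the two-decimal half-up convention", {
  expect_equal(round_half_up(100 * 26 / 30, 2), 86.67)
  expect_equal(round_half_up(100 * 30 / 30, 2), 100.00)
  expect_equal(round_half_up(100 * 22 / 23, 2), 95.65)
  expect_equal(round_half_up(0.125, 2), 0.13)  # half goes up, not to even
})

test_that("compliance classification is monotone in wear and threshold", {
  set.seed(12)
  for (k in 1:10) {
    worn <- runif(1440) < 0.4
    rec <- toy_record(worn)
    base <- score_day(rec, "2024-01-01")
    # adding worn minutes never flips compliant -> noncompliant
    extra <- worn
    extra[sample(which(!worn), 50)] <- TRUE
    rec2 <- toy_record(extra)
    s2 <- score_day(rec2, "2024-01-01")
    expect_gte(s2$awake_worn_minutes, base$awake_worn_minutes)
    if (base$compliant) expect_true(s2$compliant)
    # raising the threshold never increases the compliant count
    hi <- compliance_config(day_threshold_min = 700)
    if (score_day(rec, "2024-01-01", hi)$compliant)
      expect_true(base$compliant)
  }
})

test_that("toy records classify identically to exhaustive brute force", {
  # <= 3-day records: recompute every quantity from first principles
  set.seed(33)
  for (k in 1:5) {
    n <- 3 * 1440
    worn <- runif(n) < runif(1, 0.3, 0.9)
    sleeps <- toy_sleep(sprintf("2024-01-%02dT23:10:00Z", 1:2), c(400, 410))
    rec <- toy_record(worn, sleep = sleeps)
    cfg <- compliance_config()
    s <- summarize_participant(rec, cfg)

    grid <- rec$epochs$timestamp
    asleep <- rep(FALSE, n)
    for (j in 1:2) {
      asleep <- asleep | (grid >= sleeps$start[j] & grid < sleeps$end[j])
    }
    dates <- as.Date(grid, tz = "UTC")
    for (d in unique(dates)) {
      cnt <- sum(worn & !asleep & dates == d)
      expect_equal(score_day(rec, d)$awake_worn_minutes, cnt)
    }
    # second night is the only in-window one
    inside <- grid >= sleeps$start[2] & grid < sleeps$end[2]
    expect_equal(s$compliant_nights,
                 as.integer(oracle_longest_run(worn[inside]) >= 180))
  }
})

test_that("group aggregation uses sums, midpoint medians, and ranges", {
  mk <- function(group, comp, stud) data.frame(
    participant_id = sprintf("%s-%d", group, seq_along(comp)),
    group = group, compliant_days = comp, study_days = stud,
    compliant_nights = comp, study_nights = stud,
    day_rate_pct = round_half_up(100 * comp / stud, 2),
    night_rate_pct = round_half_up(100 * comp / stud, 2))
  summ <- rbind(mk("acute-orthopedic", c(10, 20, 30), c(20, 20, 30)),
                mk("acute-cardiac", c(5, 10), c(10, 30)))
  a <- aggregate_group(summ, "acute-orthopedic")
  expect_equal(a$total_compliant, 60)
  expect_equal(a$median_compliant, 20)
  expect_equal(a$range_compliant, c(10, 30))
  both <- aggregate_group(summ, "acute")
  expect_equal(both$total_compliant, 75)
  expect_equal(both$total_study, 110)
  # even n: mean of central pair
  expect_equal(aggregate_group(summ, "acute-cardiac")$median_compliant, 7.5)
  # single participant: degenerate range
  one <- aggregate_group(summ[5, ], "acute-cardiac")
  expect_equal(one$median_rate, one$range_rate[1])
  expect_equal(one$range_rate[1], one$range_rate[2])
  expect_error(aggregate_group(summ, "chronic-IIPT"), "no participants")

  # random group: median equals sort-and-index oracle
  set.seed(2)
  for (k in 1:10) {
    rates <- round(runif(sample(3:9, 1)) * 100, 2)
    summ_r <- mk("chronic-IIPT", rates, rep(100, length(rates)))
    m <- aggregate_group(summ_r, "chronic-IIPT")$median_compliant
    srt <- sort(rates); nn <- length(srt)
    want <- if (nn %% 2 == 1) srt[(nn + 1) / 2]
            else mean(srt[nn / 2 + 0:1])
    expect_equal(m, want)
  }
})

test_that("nights without sleep logs leave the denominator, not the numerator", {
  # fully worn, two nights logged over 4 days: study nights = 1 (first
  # trimmed), not 3
  rec <- toy_record(rep(TRUE, 4 * 1440),
                    sleep = toy_sleep(sprintf("2024-01-%02dT23:00:00Z", 1:2),
                                      c(300, 300)))
  s <- summarize_participant(rec)
  expect_equal(s$study_nights, 1)
  expect_equal(s$compliant_nights, 1)
})
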