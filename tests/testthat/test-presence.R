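test_that("two detections under 15 min apart score a present day", {
  det <- make_detections("A", c("10:00:00", "10:10:00"))
  dp <- daily_presence(det)
  expect_equal(dp$present, 1L)
  expect_equal(dp$occurrence_seconds, 600)
})

test_that("a single detection, or gaps of 15 min or more, score absent", {
  expect_equal(daily_presence(make_detections("A", "10:00:00"))$present, 0L)

  dp <- daily_presence(make_detections("A", c("10:00:00", "10:16:00")))
  expect_equal(dp$present, 0L)
  expect_equal(dp$occurrence_seconds, 0)

  # adding 10:29 creates a 13-min gap, flipping the day to present
  dp2 <- daily_presence(make_detections("A", c("10:00:00", "10:16:00",
                                               "10:29:00")))
  expect_equal(dp2$present, 1L)
  # brute force over consecutive gaps: only 10:16 -> 10:29 qualifies
  expect_equal(dp2$occurrence_seconds, 13 * 60)
})

test_that("occurrence seconds use a strict 15-min gap rule", {
  # second gap is 15 min exactly and must be excluded
  dp <- daily_presence(make_detections("A", c("10:00:00", "10:05:00",
                                              "10:20:00")))
  expect_equal(dp$occurrence_seconds, 300)

  # 11 stamps one minute apart: 10 gaps x 60 s
  times <- format(as.POSIXct("2017-03-01 09:00:00", tz = "UTC") +
                    60 * (0:10), "%H:%M:%S")
  expect_equal(daily_presence(make_detections("A", times))$occurrence_seconds,
               600)
})

test_that("presence is monotone under added detections", {
  set.seed(11)
  base_times <- as.POSIXct("2017-03-01", tz = "UTC") +
    sort(runif(6, 0, 86400))
  det <- tibble::tibble(tag_id = "A", receiver_id = "CP01",
                        timestamp = base_times)
  before <- daily_presence(det)
  for (rep in 1:20) {
    extra <- tibble::tibble(
      tag_id = "A", receiver_id = "CP01",
      timestamp = as.POSIXct("2017-03-01", tz = "UTC") + runif(1, 0, 86400))
    after <- daily_presence(dplyr::bind_rows(det, extra))
    expect_gte(after$present, before$present)
    expect_gte(after$occurrence_seconds, before$occurrence_seconds)
  }
})

test_that("days without detections inside the span materialize as absent", {
  det <- dplyr::bind_rows(
    make_detections("A", c("10:00:00", "10:05:00"), day = "2017-03-01"),
    make_detections("A", c("11:00:00", "11:05:00"), day = "2017-03-04")
  )
  dp <- daily_presence(det)
  expect_equal(nrow(dp), 4)
  expect_equal(dp$present, c(1L, 0L, 0L, 1L))
  expect_true(all(dp$occurrence_seconds[dp$present == 0] == 0))
})

test_that("degree of occurrence is the detected-day count over the inclusive span", {
  # full residency: present every one of 100 days
  pres <- tibble::tibble(tag_id = "A",
                         date = seq(as.Date("2016-01-01"), by = "day",
                                    length.out = 100),
                         present = 1L)
  s <- degree_of_occurrence(pres)
  expect_equal(s$degree_of_occurrence, 1)
  expect_equal(s$duration_days, 100L)

  # 30 detected days over an 82-day inclusive span
  set.seed(3)
  span <- seq(as.Date("2016-01-01"), by = "day", length.out = 82)
  present <- integer(82)
  present[c(1, 82, sample(2:81, 28))] <- 1L
  pres2 <- tibble::tibble(tag_id = "B", date = span, present = present)
  s2 <- degree_of_occurrence(pres2)
  expect_equal(s2$days_detected, 30L)
  expect_equal(s2$degree_of_occurrence, 30 / 82)

  # order of the daily rows must not matter
  expect_equal(degree_of_occurrence(pres2[sample(82), ]), s2)

  # undefined without a detected day
  pres3 <- tibble::tibble(tag_id = "C", date = span[1:5], present = 0L)
  expect_error(degree_of_occurrence(pres3), "undefined")
  expect_equal(nrow(degree_of_occurrence(dplyr::bind_rows(pres2, pres3),
                                         on_undetected = "drop")), 1)
})

test_that("tag-date anchoring extends the span back to tagging", {
  pres <- tibble::tibble(tag_id = "A",
                         date = seq(as.Date("2016-02-01"), by = "day",
                                    length.out = 10),
                         present = 1L)
  s <- degree_of_occurrence(
    pres, anchor = "tag_date",
    tag_dates = tibble::tibble(tag_id = "A", tag_date = as.Date("2016-01-22")))
  expect_equal(s$duration_days, 20L)
  expect_equal(s$degree_of_occurrence, 0.5)
})

test_that("cohort summary filters by monitoring span and matches direct stats", {
  two <- tibble::tibble(
    tag_id = c("A", "B"), first_day = as.Date("2016-01-01"),
    last_day = as.Date("2016-03-01"), days_detected = c(12L, 37L),
    duration_days = c(61L, 61L), degree_of_occurrence = c(0.2, 0.6))
  cs <- cohort_summary(two, min_duration_days = 30)
  expect_equal(cs$do_mean, 0.4)
  expect_equal(cs$n_retained, 2)

  # 50-individual cohort against a brute-force recomputation
  set.seed(21)
  coh <- tibble::tibble(
    tag_id = sprintf("S%02d", 1:50),
    first_day = as.Date("2016-01-01"),
    last_day = as.Date("2016-01-01") + sample(10:400, 50, TRUE))
  coh$duration_days <- as.integer(coh$last_day - coh$first_day) + 1L
  coh$days_detected <- vapply(coh$duration_days,
                              function(d) sample.int(d, 1), 1L)
  coh$degree_of_occurrence <- coh$days_detected / coh$duration_days
  cs2 <- cohort_summary(coh, min_duration_days = 30)
  keep <- coh$duration_days >= 30
  expect_equal(cs2$n_retained, sum(keep))
  expect_equal(cs2$do_mean, sum(coh$degree_of_occurrence[keep]) / sum(keep))
  expect_equal(cs2$do_sd, sqrt(sum((coh$degree_of_occurrence[keep] -
                                      cs2$do_mean)^2) / (sum(keep) - 1)))

  expect_error(cohort_summary(two, min_duration_days = 1e6), "No individuals")
})
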