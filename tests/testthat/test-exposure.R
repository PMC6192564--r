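rx <- function(start, days = NULL, qty = NULL, units = NULL,
               drug = "omeprazole", dose = 20) {
  data.frame(drug = drug, daily_dose_mg = dose, start_day = start,
             treatment_days = days %||% NA_real_,
             quantity = qty %||% NA_real_,
             daily_units = units %||% NA_real_)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("prescription duration: recorded days, else quantity / daily dose", {
  expect_equal(prescription_duration(quantity = 56, daily_units = 2), 28L)
  expect_equal(prescription_duration(quantity = 57, daily_units = 2), 29L)
  expect_equal(suppressWarnings(prescription_duration(
    list(treatment_days = 30, quantity = 56, daily_units = 2))), 30L)
  expect_warning(
    prescription_duration(list(treatment_days = 30, quantity = 56,
                               daily_units = 2)), "recorded")
  expect_error(prescription_duration(quantity = 10, daily_units = 0),
               "non-zero")
  expect_error(prescription_duration(list(drug = "omeprazole")), "needs")
})

test_that("dose categories follow the per-drug printed boundaries", {
  cases <- rbind(
    data.frame(drug = "omeprazole", dose = c(10, 20, 21, 40),
               cat = c("standard", "standard", "high", "high")),
    data.frame(drug = "esomeprazole", dose = c(20, 21, 40),
               cat = c("standard", "high", "high")),
    data.frame(drug = "pantoprazole", dose = c(20, 21, 40),
               cat = c("standard", "high", "high")),
    data.frame(drug = "lansoprazole", dose = c(15, 16, 30),
               cat = c("standard", "high", "high")),
    data.frame(drug = "rabeprazole", dose = c(10, 11, 20),
               cat = c("standard", "high", "high")))
  expect_equal(dose_category(cases$drug, cases$dose), cases$cat)
  # above the printed high range: still high, with a message
  expect_message(out <- dose_category("omeprazole", 80), "high")
  expect_equal(out, "high")
  expect_error(dose_category("cimetidine", 20), "unknown drug")
  expect_error(dose_category("omeprazole", 0), "positive")
})

test_that("duration categories use half-open 30-day-month bins", {
  expect_equal(as.character(duration_category(20)), "<1 month")
  expect_equal(as.character(duration_category(45)), "1-3 months")
  expect_equal(as.character(duration_category(800)), ">24 months")
  # boundaries: the category changes exactly at 30/90/180/360/720
  b <- c(30, 90, 180, 360, 720)
  below <- duration_category(b - 1e-9)
  at <- duration_category(b)
  expect_true(all(as.integer(at) == as.integer(below) + 1L))
  expect_equal(levels(duration_category(0)),
               c("<1 month", "1-3 months", "3-6 months", "6-12 months",
                 "12-24 months", ">24 months"))
  expect_equal(as.character(duration_category(c(20, 45, 100, 200),
                                              scheme = "collapsed")),
               c("<1 month", "1-3 months", "3-6 months", ">6 months"))
  expect_error(duration_category(-1), "non-negative")
})

test_that("consecutive prescriptions merge into one episode", {
  tl <- build_timeline(rbind(rx(0, days = 28), rx(28, days = 28)), 0, 1000)
  expect_equal(nrow(tl$episodes), 1L)
  expect_equal(tl$episodes$end - tl$episodes$start, 56)
  # a 60-day gap (over the default grace of 0) keeps two episodes
  tl2 <- build_timeline(rbind(rx(0, days = 28), rx(88, days = 28)), 0, 1000)
  expect_equal(nrow(tl2$episodes), 2L)
  expect_equal(tl2$cumulative_days, 56)
  # the same gap is bridged when the grace period covers it
  tl3 <- build_timeline(rbind(rx(0, days = 28), rx(88, days = 28)), 0, 1000,
                        grace_days = 60)
  expect_equal(nrow(tl3$episodes), 1L)
})

test_that("an empty prescription list is a never-user", {
  tl <- build_timeline(rx(1)[0, ], 0, 1000)
  expect_equal(tl$stratum, "never")
  expect_equal(tl$cumulative_days, 0)
  expect_equal(cumulative_exposure(tl, c(0, 500, 1000)), c(0, 0, 0))
})

test_that("episode dose is high if any constituent prescription is high", {
  tl <- build_timeline(rbind(rx(0, days = 28, dose = 20),
                             rx(28, days = 28, dose = 40)), 0, 1000)
  expect_equal(tl$episodes$dose, "high")
})

test_that("episodes are truncated at the end of follow-up", {
  tl <- build_timeline(rx(90, days = 60), 0, 120)
  expect_equal(tl$episodes$end, 120)
  expect_equal(tl$cumulative_days, 30)
  # an episode entirely after censoring disappears
  tl2 <- build_timeline(rx(200, days = 30), 0, 120)
  expect_equal(nrow(tl2$episodes), 0L)
})

test_that("user strata distinguish baseline from follow-up-only use", {
  expect_equal(build_timeline(rx(100, days = 30), 0, 3000)$stratum, "baseline")
  expect_equal(build_timeline(rx(400, days = 30), 0, 3000)$stratum,
               "follow-up")
  # the window is relative to the participant's own entry
  expect_equal(build_timeline(rx(400, days = 30), 300, 3000)$stratum,
               "baseline")
})

test_that("merging is idempotent and order-invariant (property)", {
  set.seed(21)
  for (r in 1:30) {
    n <- sample(2:8, 1)
    scripts <- do.call(rbind, lapply(seq_len(n), function(i)
      rx(sample(0:400, 1), days = sample(c(7, 28, 30, 90), 1),
         dose = sample(c(20, 40), 1))))
    tl <- build_timeline(scripts, 0, 2000)
    tl_perm <- build_timeline(scripts[sample(n), ], 0, 2000)
    expect_equal(tl$episodes, tl_perm$episodes)
    # re-feeding the merged episodes reproduces them (idempotence)
    again <- build_timeline(
      data.frame(drug = "omeprazole",
                 daily_dose_mg = ifelse(tl$episodes$dose == "high", 40, 20),
                 start_day = tl$episodes$start,
                 treatment_days = tl$episodes$end - tl$episodes$start,
                 quantity = NA_real_, daily_units = NA_real_), 0, 2000)
    expect_equal(again$episodes$start, tl$episodes$start)
    expect_equal(again$episodes$end, tl$episodes$end)
    # cumulative exposure never exceeds the raw sum of durations
    expect_lte(tl$cumulative_days, sum(scripts$treatment_days))
    # cumulative-exposure function is non-decreasing with slope <= 1
    days <- seq(0, 2000, by = 50)
    cum <- cumulative_exposure(tl, days)
    expect_true(all(diff(cum) >= 0))
    expect_true(all(diff(cum) <= diff(days) + 1e-9))
  }
})

test_that("cumulative-exposure threshold days invert the exposure function", {
  set.seed(22)
  for (r in 1:20) {
    scripts <- do.call(rbind, lapply(1:4, function(i)
      rx(sample(0:600, 1), days = sample(20:120, 1))))
    tl <- build_timeline(scripts, 0, 2000)
    thr <- ppickd:::exposure_threshold_days(tl, c(30, 90, 180))
    if (nrow(thr)) {
      expect_equal(cumulative_exposure(tl, thr$day),
                   c(30, 90, 180)[thr$index], tolerance = 1e-9)
    }
    expect_true(all(c(30, 90, 180)[-thr$index] >= tl$cumulative_days))
  }
})
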