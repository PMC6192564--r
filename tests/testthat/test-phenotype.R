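labs1 <- function(days, egfr = NULL, uacr = NULL) {
  data.frame(pid = rep(1L, length(days)), day = days,
             egfr = egfr %||% rep(NA_real_, length(days)),
             uacr = uacr %||% rep(NA_real_, length(days)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the 90-day confirmation rule defines incident CKD", {
  # two sub-threshold eGFR 90 days apart: incident, dated at confirmation
  st <- detect_incident_ckd(labs1(c(0, 90), egfr = c(55, 55)), 0, 3000)
  expect_true(st$incident)
  expect_equal(st$event_day, 90)
  # 89 days and nothing after: not incident
  st <- detect_incident_ckd(labs1(c(0, 89), egfr = c(55, 55)), 0, 3000)
  expect_false(st$incident)
  expect_equal(st$censor_reason, "end of follow-up")
  # a single determination is never incident
  st <- detect_incident_ckd(labs1(10, egfr = 40), 0, 3000)
  expect_false(st$incident)
  expect_equal(st$n_qualifying, 1L)
})

test_that("the UACR arm of the and/or rule triggers on its own", {
  st <- detect_incident_ckd(
    labs1(c(10, 70, 130), egfr = c(80, 85, 90), uacr = c(35, 10, 40)),
    0, 3000)
  expect_true(st$incident)
  expect_equal(st$event_day, 130)  # 130 - 10 >= 90; day 70 does not qualify
})

test_that("intervening normal determinations do not reset the clock", {
  st <- detect_incident_ckd(labs1(c(0, 40, 95), egfr = c(55, 80, 50)), 0, 3000)
  expect_true(st$incident)
  expect_equal(st$event_day, 95)
})

test_that("the event-date rule switch moves the date to the first qualifying", {
  labs <- labs1(c(5, 120), egfr = c(55, 52))
  expect_equal(detect_incident_ckd(labs, 0, 3000)$event_day, 120)
  expect_equal(detect_incident_ckd(labs, 0, 3000,
                                   event_date_rule = "first")$event_day, 5)
})

test_that("labs outside the follow-up window are ignored", {
  labs <- labs1(c(-50, 10, 100), egfr = c(50, 55, 55))
  st <- detect_incident_ckd(labs, 0, 3000)
  expect_equal(st$first_qualifying_day, 10)
  st2 <- detect_incident_ckd(labs1(c(10, 100, 400), egfr = c(55, 55, 50)),
                             0, 99)
  expect_false(st2$incident)
})

test_that("no labs yields a censored status, never an error", {
  st <- detect_incident_ckd(labs1(numeric(0)), 0, 3000)
  expect_equal(nrow(st), 0L)
  st <- detect_incident_ckd(data.frame(pid = 1L, day = 5, egfr = NA_real_,
                                       uacr = NA_real_), 0, 3000)
  expect_false(st$incident)
  expect_equal(st$censor_reason, "no labs")
})

test_that("CKD status is invariant to lab record order (property)", {
  set.seed(11)
  for (r in 1:25) {
    n <- sample(3:12, 1)
    labs <- data.frame(pid = 1L, day = sort(sample(0:1000, n)),
                       egfr = runif(n, 40, 90), uacr = runif(n, 5, 45))
    ref <- detect_incident_ckd(labs, 0, 1200)
    per <- detect_incident_ckd(labs[sample(n), ], 0, 1200)
    expect_identical(ref, per)
  }
})

test_that("removing a lab record never creates an incident case (property)", {
  set.seed(12)
  for (r in 1:25) {
    n <- sample(3:10, 1)
    labs <- data.frame(pid = 1L, day = sort(sample(0:800, n)),
                       egfr = runif(n, 45, 80), uacr = rep(NA_real_, n))
    full <- detect_incident_ckd(labs, 0, 1000)
    for (drop in seq_len(n)) {
      sub <- detect_incident_ckd(labs[-drop, ], 0, 1000)
      expect_true(full$incident | !sub$incident)
      if (full$incident && sub$incident) {
        expect_gte(sub$event_day, full$event_day)
      }
    }
  }
})

test_that("prevalent CKD in the first year is excluded by the same rule", {
  participants <- data.frame(pid = 1:3)
  labs <- rbind(
    data.frame(pid = 1L, day = c(30, 130), egfr = c(50, 50), uacr = NA),
    data.frame(pid = 2L, day = 100, egfr = 50, uacr = NA),
    data.frame(pid = 3L, day = c(30, 130), egfr = c(80, 85), uacr = NA))
  ex <- exclude_prevalent_ckd(participants, labs, 0)
  expect_equal(ex$excluded_ids, 1L)
  expect_equal(ex$cohort$pid, c(2L, 3L))
  expect_equal(ex$incidence_start, 365)
  # the single-determination alternative also removes participant 2
  ex1 <- exclude_prevalent_ckd(participants, labs, 0, rule = "single")
  expect_setequal(ex1$excluded_ids, c(1L, 2L))
  # a qualifying pair straddling the window boundary does not exclude
  labs4 <- data.frame(pid = 4L, day = c(300, 400), egfr = c(50, 50),
                      uacr = NA)
  ex2 <- exclude_prevalent_ckd(data.frame(pid = 4L), labs4, 0)
  expect_equal(ex2$n_excluded, 0L)
  # empty first-year labs: retained
  ex3 <- exclude_prevalent_ckd(data.frame(pid = 5L),
                               labs1(numeric(0)), 0)
  expect_equal(ex3$n_excluded, 0L)
})

test_that("exclusion and incidence are disjoint on a simulated cohort", {
  sim <- simulate_cohort(sim_config(n = 250, seed = 7))
  labs <- sim$labs
  labs$egfr <- ckd_epi_egfr(
    labs$creatinine,
    sim$participants$age_entry[labs$pid] +
      (labs$day - sim$participants$entry_day[labs$pid]) / 365.25,
    sim$participants$sex[labs$pid])
  ex <- exclude_prevalent_ckd(sim$participants, labs, 0)
  kept <- labs[!(labs$pid %in% ex$excluded_ids), ]
  st <- detect_incident_ckd(kept, 365, max(labs$day))
  expect_length(intersect(ex$excluded_ids, st$pid[st$incident]), 0)
})
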