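null_hr <- c(ppi = 0, ppi_high = 0, age70 = 0, female = 0, hypertension = 0,
             diabetes = 0, obesity = 0, nsaid = 0, cardiovascular_disease = 0)
no_conf <- list(coef = c(age70 = 0, hypertension = 0, diabetes = 0,
                         obesity = 0, nsaid = 0))

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- sim_config(n = 200, seed = 33)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$participants, b$participants)
  expect_identical(a$prescriptions, b$prescriptions)
  expect_identical(a$labs, b$labs)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$labs, simulate_cohort(cfg, seed = 34)$labs))
})

test_that("n = 0 yields empty tables and empty truth", {
  sim <- simulate_cohort(sim_config(n = 0))
  expect_equal(nrow(sim$participants), 0L)
  expect_equal(nrow(sim$prescriptions), 0L)
  expect_equal(nrow(sim$labs), 0L)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("a non-finite baseline hazard is rejected with a diagnostic", {
  cfg <- sim_config(n = 10)
  cfg$baseline_log_hazard[2] <- Inf
  expect_error(simulate_cohort(cfg), "finite")
})

test_that("event times never precede entry and respect censoring", {
  sim <- simulate_cohort(sim_config(n = 400, seed = 3))
  tr <- sim$truth
  ev <- !is.na(tr$event_day)
  expect_true(all(tr$event_day[ev] > tr$entry_day[ev]))
  expect_true(all(tr$exit_day <= tr$censor_day + 1e-9))
  expect_true(all(tr$exit_day[tr$status == 1] == tr$event_day[tr$status == 1]))
})

test_that("with a null PPI effect the crude incidence-rate ratio is about 1", {
  cfg <- sim_config(n = 3000, true_log_hr = null_hr, frailty_sd = 0,
                    spatial = list(sd = 0), exposure_model = no_conf,
                    seed = 17)
  sim <- simulate_cohort(cfg)
  cp <- truth_counting_table(sim)
  ev1 <- sum(cp$status[cp$ppi == 1]); pt1 <- sum((cp$stop - cp$start)[cp$ppi == 1])
  ev0 <- sum(cp$status[cp$ppi == 0]); pt0 <- sum((cp$stop - cp$start)[cp$ppi == 0])
  log_irr <- log((ev1 / pt1) / (ev0 / pt0))
  se <- sqrt(1 / ev1 + 1 / ev0)
  expect_lt(abs(log_irr), 3.5 * se)
})

test_that("event times match an independent discrete-time simulator", {
  # same exposure realisations and the same rates; the oracle redraws the
  # event process day by day (1-day Bernoulli steps)
  lam <- log(2.5e-4)
  b_ppi <- log(1.5)
  cfg <- sim_config(n = 3000, true_log_hr = null_hr, frailty_sd = 0,
                    spatial = list(sd = 0), exposure_model = no_conf,
                    baseline_log_hazard = rep(lam, 8), seed = 91)
  cfg$true_log_hr[["ppi"]] <- b_ppi
  sim <- simulate_cohort(cfg)
  cp <- truth_counting_table(sim)
  rate <- function(cpp) {
    ev1 <- sum(cpp$status[cpp$ppi == 1])
    pt1 <- sum((cpp$stop - cpp$start)[cpp$ppi == 1])
    ev0 <- sum(cpp$status[cpp$ppi == 0])
    pt0 <- sum((cpp$stop - cpp$start)[cpp$ppi == 0])
    c(irr = log((ev1 / pt1) / (ev0 / pt0)), se = sqrt(1 / ev1 + 1 / ev0))
  }
  pkg <- rate(cp)

  set.seed(4242)
  tr <- sim$truth; rx <- sim$prescriptions
  ev1 <- pt1 <- ev0 <- pt0 <- 0
  for (i in seq_len(nrow(tr))) {
    entry <- tr$entry_day[i]; cens <- tr$censor_day[i]
    days <- seq(floor(entry), ceiling(cens) - 1)
    ri <- rx[rx$pid == tr$pid[i], ]
    exposed <- rep(FALSE, length(days))
    if (nrow(ri)) {
      dur <- ifelse(!is.na(ri$treatment_days), ri$treatment_days,
                    ceiling(ri$quantity / ri$daily_units))
      for (k in seq_len(nrow(ri))) {
        exposed <- exposed | (days >= ri$start_day[k] &
                                days < ri$start_day[k] + dur[k])
      }
    }
    p <- exp(lam + b_ppi * exposed)
    hit <- which(runif(length(days)) < p)
    stopday <- if (length(hit)) hit[1] else length(days)
    pt1 <- pt1 + sum(exposed[seq_len(stopday)])
    pt0 <- pt0 + stopday - sum(exposed[seq_len(stopday)])
    if (length(hit)) {
      if (exposed[stopday]) ev1 <- ev1 + 1 else ev0 <- ev0 + 1
    }
  }
  orc <- c(irr = log((ev1 / pt1) / (ev0 / pt0)), se = sqrt(1 / ev1 + 1 / ev0))
  expect_lt(abs(pkg["irr"] - orc["irr"]),
            3.5 * sqrt(pkg["se"]^2 + orc["se"]^2))
})

test_that("simulated survival matches the analytic piecewise-exponential", {
  # no covariate effects, no random effects, no exposure: the true
  # survival from study start is exp(-Lambda0(t))
  cfg <- sim_config(n = 2500, true_log_hr = null_hr, frailty_sd = 0,
                    spatial = list(sd = 0),
                    exposure_model = c(no_conf, list(
                      baseline_intercept = -30, followup_log_rate = -30)),
                    frac_entry_first_year = 1, loss_rate = 0, seed = 55)
  sim <- simulate_cohort(cfg)
  tr <- sim$truth
  km <- kalbfleisch_prentice(data.frame(entry = tr$entry_day,
                                        exit = tr$exit_day,
                                        status = tr$status))
  breaks <- seq(0, cfg$study_days, length.out = 9)
  h <- exp(cfg$baseline_log_hazard)
  cumh <- approxfun(breaks, c(0, cumsum(h * diff(breaks))))
  analytic <- exp(-cumh(km$time))
  expect_lt(max(abs(km$surv - analytic)), 0.03)
})

test_that("phenotyping recovers latent events at the first opportunity", {
  sim <- simulate_cohort(sim_config(n = 800, seed = 19))
  pa <- sim$participants
  labs <- sim$labs
  labs$egfr <- ckd_epi_egfr(
    labs$creatinine,
    pa$age_entry[labs$pid] + (labs$day - pa$entry_day[labs$pid]) / 365.25,
    pa$sex[labs$pid])
  st <- detect_incident_ckd(labs, 0, max(labs$day) + 1,
                            event_date_rule = "first")
  tr <- sim$truth
  # never earlier: no qualifying determination precedes the true event
  first_q <- setNames(st$first_qualifying_day, st$pid)[as.character(tr$pid)]
  ev <- !is.na(tr$event_day)
  expect_true(all(first_q[ev] >= tr$event_day[ev] - 0.011, na.rm = TRUE))
  expect_true(all(is.na(first_q[!ev])))
  # recovery: among events with a later lab visit, the first qualifying
  # determination is that first post-event visit for >= 95%
  hit <- total <- 0
  for (i in which(ev)) {
    vis <- labs$day[labs$pid == tr$pid[i]]
    after <- vis[vis >= tr$event_day[i]]
    if (!length(after)) next
    total <- total + 1
    if (!is.na(first_q[i]) && abs(first_q[i] - min(after)) < 1e-6) {
      hit <- hit + 1
    }
  }
  expect_gt(total, 50)
  expect_gte(hit / total, 0.95)
})
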