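two_group_data <- function(n = 120, seed = 1) {
  set.seed(seed)
  data.frame(pid = seq_len(n), start = 0,
             stop = round(rexp(n, 0.1), 3) + 0.05,
             status = rbinom(n, 1, 0.7), x = rep(0:1, length.out = n))
}

test_that("poisson expansion splits rows at bin boundaries exactly", {
  ex <- poisson_expand(data.frame(start = 0, stop = 100, status = 1),
                       c(0, 50, 100))
  expect_equal(nrow(ex), 2L)
  expect_equal(ex$exposure, c(50, 50))
  expect_equal(ex$d, c(0L, 1L))
  expect_equal(ex$bin, 1:2)
  # a row inside one bin is returned unchanged
  ex2 <- poisson_expand(data.frame(start = 12, stop = 37, status = 1),
                        c(0, 50, 100))
  expect_equal(nrow(ex2), 1L)
  expect_equal(ex2$exposure, 25)
  expect_equal(ex2$d, 1L)
  expect_error(poisson_expand(data.frame(start = -1, stop = 10, status = 0),
                              c(0, 50)), "outside")
})

test_that("expansion conserves exposure and matches a per-day oracle", {
  set.seed(41)
  breaks <- c(0, 13, 40, 77, 120)
  for (r in 1:5) {
    tab <- random_counting_table(40, tmax = 110)
    ex <- poisson_expand(tab, breaks)
    expect_equal(sum(ex$exposure), sum(tab$stop - tab$start),
                 tolerance = 1e-12)
    expect_equal(sum(ex$d), sum(tab$status))
    # per-source-row exposure is conserved too
    per_row <- tapply(ex$exposure, attr(ex, "row"), sum)
    expect_equal(as.numeric(per_row[as.character(seq_len(nrow(tab)))]),
                 tab$stop - tab$start, tolerance = 1e-12)
  }
  # fine-grained oracle on a handful of rows
  for (r in 1:10) {
    s <- runif(1, 0, 60); e <- s + runif(1, 1, 50)
    ex <- poisson_expand(data.frame(start = s, stop = e, status = 0), breaks)
    want <- oracle_bin_exposure(s, e, breaks, step = 1 / 64)
    got <- setNames(ex$exposure, ex$bin)
    for (bn in names(want)) {
      expect_lt(abs((if (bn %in% names(got)) unname(got[bn]) else 0) -
                      want[[bn]]), 1 / 16)
    }
  }
})

test_that("the one-bin log joint is maximised at log(d/T)", {
  dd <- two_group_data(seed = 2)
  breaks <- c(0, max(dd$stop))
  ex <- poisson_expand(dd[, c("start", "stop", "status")], breaks)
  stack <- ppickd:::build_stack(ex, NULL, breaks, smooth = FALSE)
  Q <- ppickd:::build_Q(stack, list())$Q
  lam_hat <- optimize(function(l) ppickd:::log_joint(l, stack, Q),
                      c(-10, 2), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(lam_hat, log(sum(dd$status) / sum(dd$stop)), tolerance = 1e-6)
  # with no events the joint is decreasing in lambda
  ex0 <- ex; ex0$d <- 0L
  stack0 <- ppickd:::build_stack(ex0, NULL, breaks, smooth = FALSE)
  grid <- seq(-8, 0, length.out = 20)
  vals <- vapply(grid, function(l) ppickd:::log_joint(l, stack0, Q),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("one-bin fits reproduce the closed-form exponential MLEs", {
  dd <- two_group_data(seed = 3)
  f <- bpeh(Surv(start, stop, status) ~ x, dd, bins = 1)
  d1 <- sum(dd$status[dd$x == 1]); t1 <- sum(dd$stop[dd$x == 1])
  d0 <- sum(dd$status[dd$x == 0]); t0 <- sum(dd$stop[dd$x == 0])
  expect_equal(unname(coef(f)[["x"]]), log((d1 / t1) / (d0 / t0)),
               tolerance = 1e-6)
  expect_equal(f$lambda, log(d0 / t0), tolerance = 1e-6)
  # Wald interval of the log rate ratio
  hr <- hazard_ratio(f, "x")
  se <- sqrt(1 / d1 + 1 / d0)
  expect_equal(log(hr$hr), log((d1 / t1) / (d0 / t0)), tolerance = 1e-6)
  expect_equal(log(hr$upper) - log(hr$lower), 2 * 1.96 * se,
               tolerance = 1e-3)
})

test_that("fixed effects match a Poisson GLM oracle on random data", {
  for (seed in 1:10) {
    set.seed(seed + 100)
    n <- 500
    dd <- data.frame(pid = 1:n, start = 0,
                     stop = round(rexp(n, 0.08), 3) + 0.05,
                     status = rbinom(n, 1, 0.6),
                     x = rbinom(n, 1, 0.4), z = rnorm(n))
    f <- bpeh(Surv(start, stop, status) ~ x + z, dd, bins = 4,
              smooth = FALSE)
    ex <- poisson_expand(dd[, c("start", "stop", "status", "x", "z")],
                         f$breaks)
    gl <- glm(d ~ 0 + factor(bin) + x + z + offset(log(exposure)),
              family = poisson, data = ex)
    expect_equal(unname(coef(f)), unname(coef(gl)[c("x", "z")]),
                 tolerance = 1e-6)
    # bins without events have no finite MLE; compare the others
    with_ev <- sort(unique(ex$bin[ex$d > 0]))
    expect_equal(unname(f$lambda[with_ev]),
                 unname(coef(gl)[with_ev]), tolerance = 1e-5)
    # posterior SDs agree with the GLM standard errors (flat priors)
    expect_equal(unname(f$beta_sd),
                 unname(sqrt(diag(vcov(gl))[c("x", "z")])), tolerance = 1e-4)
  }
})

test_that("Newton restarted at the solution stays put", {
  dd <- two_group_data(seed = 4)
  breaks <- c(0, max(dd$stop))
  ex <- poisson_expand(dd[, c("start", "stop", "status", "x")], breaks)
  stack <- ppickd:::build_stack(ex, as.matrix(ex[, "x", drop = FALSE]),
                                breaks, smooth = FALSE)
  Q <- ppickd:::build_Q(stack, list())$Q
  fit1 <- ppickd:::fit_latent(stack, Q)
  fit2 <- ppickd:::fit_latent(stack, Q, x0 = fit1$x)
  expect_lte(fit2$iterations, 1L)
  expect_equal(fit2$x, fit1$x, tolerance = 1e-9)
})

test_that("PC prior on an SD puts mass alpha above sigma0", {
  for (ps in list(c(1, 0.01), c(0.5, 0.05), c(2, 0.1))) {
    dens <- function(s) exp(ppickd:::pc_sd_logprior(s, ps[1], ps[2]))
    expect_equal(integrate(dens, 0, Inf)$value, 1, tolerance = 1e-5)
    expect_equal(integrate(dens, ps[1], Inf)$value, ps[2], tolerance = 1e-5)
  }
  # range prior: P(rho < rho0) = alpha
  dens_r <- function(r) exp(ppickd:::pc_range_logprior(r, 0.2, 0.05))
  expect_equal(integrate(dens_r, 1e-9, 0.2)$value, 0.05, tolerance = 1e-4)
})

test_that("frailty SD collapses towards zero when the truth has none", {
  cfg <- sim_config(n = 3000, frailty_sd = 0, spatial = list(sd = 0),
                    seed = 77)
  sim <- simulate_cohort(cfg)
  cp <- truth_counting_table(sim)
  f <- bpeh(Surv(start, stop, status) ~ ppi + age70 + hypertension +
              diabetes, cp, id = "pid", frailty = TRUE, bins = 12)
  expect_lt(unname(f$hyper["sigma_u"]), 0.1)
})

test_that("stronger RW1 smoothing monotonically flattens the baseline", {
  dd <- two_group_data(n = 300, seed = 6)
  vars <- vapply(c(1, 0.1, 0.01), function(s) {
    f <- bpeh(Surv(start, stop, status) ~ x, dd, bins = 8,
              fixed = list(sigma_rw = s))
    var(f$lambda)
  }, numeric(1))
  expect_true(all(diff(vars) < 0))
})

test_that("hazard_ratio handles degenerate and unknown inputs", {
  dd <- two_group_data(seed = 7)
  f <- bpeh(Surv(start, stop, status) ~ x, dd, bins = 1)
  expect_error(hazard_ratio(f, "nope"), "unknown covariate")
  f0 <- f
  f0$coefficients[] <- 0
  hr <- hazard_ratio(f0, "x")
  expect_equal(hr$hr, 1)
  expect_equal(hr$lower * hr$upper, 1, tolerance = 1e-9)
  f0$beta_sd[] <- 0
  hr0 <- hazard_ratio(f0, "x")
  expect_equal(c(hr0$hr, hr0$lower, hr0$upper), c(1, 1, 1))
})

test_that("predictions integrate the baseline steps correctly", {
  dd <- two_group_data(seed = 8)
  f <- bpeh(Surv(start, stop, status) ~ x, dd, bins = 4, smooth = FALSE)
  br <- f$breaks
  h <- exp(f$lambda)
  t <- br[2] + 0.5 * (br[3] - br[2])
  want <- h[1] * (br[2] - br[1]) + h[2] * (t - br[2])
  expect_equal(predict(f, t, type = "cumhaz")$value, want, tolerance = 1e-9)
  expect_equal(predict(f, t, type = "survival")$value, exp(-want),
               tolerance = 1e-9)
  # covariate profile scales the hazard by exp(beta)
  s1 <- predict(f, t, newdata = data.frame(x = 1), type = "cumhaz")$value
  expect_equal(s1, want * exp(coef(f)[["x"]]), tolerance = 1e-9)
  # martingale residuals sum to ~0 at an unpenalised MLE
  r <- residuals(f, dd)
  expect_equal(sum(r), 0, tolerance = 1e-6)
})

test_that("counting-process input with multiple events per id is rejected", {
  dd <- data.frame(pid = c(1, 1), start = c(0, 2), stop = c(2, 4),
                   status = c(1, 1), x = 0:1)
  expect_error(bpeh(Surv(start, stop, status) ~ x, dd, id = "pid"),
               "more than one event")
})
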