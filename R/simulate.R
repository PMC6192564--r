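#' Configuration for the synthetic EHR cohort generator
#'
#' Assembles and validates the data-generating parameters for
#' [simulate_cohort()].  Defaults emulate an 8-year (2005--2012)
#' primary-care cohort: staggered entry, PPI prescription episodes
#' whose initiation depends on age and comorbidity (confounding by
#' indication, giving roughly a quarter baseline users and 7 per cent
#' follow-up initiators), piecewise-exponential event times for
#' incident CKD with individual frailty and a spatially structured
#' unobserved confounder, laboratory visits whose eGFR/UACR values
#' cross the CKD thresholds at the latent event time, and
#' administrative censoring plus random loss to follow-up.
#'
#' @param n number of participants.
#' @param study_start,study_end study window dates (ISO strings or
#'   `Date`); the analysis time scale is days since `study_start`.
#' @param frac_entry_first_year fraction entering during the first
#'   study year (uniformly); the rest enter uniformly over the
#'   remaining window, leaving at least 180 days of potential
#'   follow-up.
#' @param visit_rate mean laboratory visits per participant-year.
#' @param age_mean,age_sd age-at-entry distribution (normal, truncated
#'   to \[15, 95\] years).
#' @param covariate_prevalences named probabilities for the binary
#'   comorbidity/treatment indicators.
#' @param frac_onset_at_entry probability that a present comorbidity is
#'   already present at entry; otherwise its onset is uniform over the
#'   participant's follow-up.
#' @param exposure_model list: `baseline_intercept` (logit of baseline
#'   PPI use at reference covariates), `coef` (named log-odds/log-rate
#'   increments for initiation), `followup_log_rate` (log daily
#'   initiation rate after the first follow-up year), `spatial_coef`
#'   (loading of the spatial confounder on initiation),
#'   `dose_high_prob`, `episode_meanlog`/`episode_sdlog` (log-normal
#'   episode length, days), `gap_mean` (mean between-episode gap,
#'   days), `drug_probs` (named sampling weights for the five PPIs),
#'   `frac_recorded_days` (prescriptions carrying recorded treatment
#'   days rather than quantity/daily dose), `chunk_days` (episodes are
#'   dispensed as consecutive prescriptions of this length).
#' @param true_log_hr named true log hazard ratios; names among
#'   `ppi`, `ppi_high`, `age70`, `female` and the comorbidity names.
#' @param baseline_log_hazard vector of log baseline-hazard values
#'   (per day) on `baseline_bins` equal-width time bins.
#' @param frailty_sd standard deviation of the individual log-normal
#'   frailty (0 disables it).
#' @param spatial list `sd`, `range`, `nu`, `n_areas`: participants are
#'   assigned to `n_areas` area centroids drawn uniformly on the unit
#'   square, and the confounder is a Matern field over the centroids
#'   entering the hazard with loading 1 (`sd = 0` disables it).
#' @param loss_rate daily rate of random loss to follow-up.
#' @param labs list of laboratory-trajectory parameters: pre-event eGFR
#'   plateau mean/SD, measurement noise SD, post-event starting eGFR
#'   and annual decline, `uacr_event_frac` (fraction of events that
#'   manifest through UACR rather than eGFR), and UACR baseline
#'   log-normal parameters.
#' @param seed default seed used by [simulate_cohort()].
#' @return validated object of class `"sim_config"`.
#' @export
sim_config <- function(n = 5000,
                       study_start = "2005-01-01", study_end = "2012-12-31",
                       frac_entry_first_year = 0.6,
                       visit_rate = 1.5,
                       age_mean = 52, age_sd = 18,
                       covariate_prevalences = c(female = 0.5,
                         hypertension = 0.20, diabetes = 0.15, obesity = 0.20,
                         nsaid = 0.25, cardiovascular_disease = 0.10),
                       frac_onset_at_entry = 0.7,
                       exposure_model = list(),
                       true_log_hr = c(ppi = log(1.5), ppi_high = log(1.3),
                         age70 = log(2.2), female = 0, hypertension = log(1.3),
                         diabetes = log(1.4), obesity = log(1.2), nsaid = 0,
                         cardiovascular_disease = log(1.1)),
                       baseline_log_hazard = seq(-9.1, -8.7, length.out = 8),
                       frailty_sd = 0.3,
                       spatial = list(),
                       loss_rate = 0.02 / 365,
                       labs = list(),
                       seed = 1L) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (study_end <= study_start) stop("study_end must be after study_start")
  exposure_model <- modifyList(list(
    baseline_intercept = -1.6,
    coef = c(age70 = 0.8, hypertension = 0.5, diabetes = 0.4,
             obesity = 0.4, nsaid = 0.6),
    followup_log_rate = -10,
    spatial_coef = 1.0,
    dose_high_prob = 0.2,
    episode_meanlog = log(60), episode_sdlog = 1.0,
    gap_mean = 240,
    drug_probs = c(omeprazole = 0.65, pantoprazole = 0.15,
                   esomeprazole = 0.10, lansoprazole = 0.07,
                   rabeprazole = 0.03),
    frac_recorded_days = 0.7,
    chunk_days = 30), exposure_model)
  spatial <- modifyList(list(sd = 0, range = 0.3, nu = 1, n_areas = 100),
                        spatial)
  labs <- modifyList(list(
    egfr_pre_mean = 85, egfr_pre_sd = 8, egfr_noise_sd = 3,
    egfr_post_start = 57, egfr_post_decline = 4,
    uacr_event_frac = 0.15,
    uacr_meanlog = log(8), uacr_sdlog = 0.5), labs)
  cfg <- structure(list(
    n = as.integer(n), study_start = study_start, study_end = study_end,
    study_days = as.numeric(study_end - study_start) + 1,
    frac_entry_first_year = frac_entry_first_year,
    visit_rate = visit_rate, age_mean = age_mean, age_sd = age_sd,
    covariate_prevalences = covariate_prevalences,
    frac_onset_at_entry = frac_onset_at_entry,
    exposure_model = exposure_model, true_log_hr = true_log_hr,
    baseline_log_hazard = baseline_log_hazard,
    frailty_sd = frailty_sd, spatial = spatial, loss_rate = loss_rate,
    labs = labs, seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n >= 0,
            cfg$frac_entry_first_year >= 0, cfg$frac_entry_first_year <= 1,
            all(cfg$covariate_prevalences >= 0),
            all(cfg$covariate_prevalences <= 1),
            cfg$frailty_sd >= 0, cfg$spatial$sd >= 0, cfg$spatial$range > 0,
            cfg$loss_rate >= 0, cfg$visit_rate >= 0)
  if (any(!is.finite(cfg$baseline_log_hazard))) {
    stop("baseline_log_hazard must be finite")
  }
  invisible(cfg)
}

# Exact inversion of a piecewise-constant cumulative hazard.
# seg_start: K+1 boundaries; rate: K per-day rates; target: Exp(1) draw.
# Returns the event time, or Inf if the total hazard is exhausted.
piecewise_event_time <- function(seg_start, rate, target) {
  len <- diff(seg_start)
  cum <- cumsum(len * rate)
  k <- which(cum >= target)[1]
  if (is.na(k)) return(Inf)
  before <- if (k == 1) 0 else cum[k - 1]
  seg_start[k] + (target - before) / rate[k]
}

#' Simulate a synthetic EHR cohort with known ground truth
#'
#' Generates the four raw tables the analysis pipeline consumes
#' (participants, prescriptions, laboratory records, diagnoses) plus a
#' ground-truth sidecar for parameter-recovery testing.  Event times
#' are drawn exactly, by inversion of the piecewise-exponential
#' cumulative hazard \eqn{\exp(\lambda_{bin}(t) + x(t)'\beta + u_i +
#' s_i)}; laboratory eGFR values sit on a plateau above 60 before the
#' latent event (never below it) and descend linearly below 60 from the
#' event onwards (analogously above 30 mg/g for UACR-manifesting
#' events), so the phenotyping rules can recover the event but never
#' date it earlier.  Byte-identical output for identical config and
#' seed.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; defaults to `config$seed`.
#' @return list of class `"sim_cohort"` with data frames
#'   `participants`, `prescriptions`, `labs`, `diagnoses`, `truth`, and
#'   the `config`.  `truth` holds per-participant frailty, spatial
#'   effect, true event day (`NA` if none before censoring), censor
#'   day, and exit/status on the analysis time scale.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  validate_sim_config(config)
  n <- config$n
  empty <- function() list(
    participants = data.frame(pid = integer(), sex = character(),
      age_entry = numeric(), entry_day = numeric(), left_day = numeric(),
      country_spain = integer(), area = integer(), loc_x = numeric(),
      loc_y = numeric()),
    prescriptions = data.frame(pid = integer(), drug = character(),
      daily_dose_mg = numeric(), start_day = numeric(),
      treatment_days = numeric(), quantity = numeric(),
      daily_units = numeric()),
    labs = data.frame(pid = integer(), day = numeric(),
      creatinine = numeric(), uacr = numeric()),
    diagnoses = data.frame(pid = integer(), condition = character(),
      onset_day = numeric()),
    truth = data.frame(pid = integer(), u = numeric(), s = numeric(),
      event_day = numeric(), censor_day = numeric(), exit_day = numeric(),
      status = integer(), entry_day = numeric()),
    config = config)
  if (n == 0L) return(structure(empty(), class = "sim_cohort"))

  em <- config$exposure_model
  lb <- config$labs
  T_end <- config$study_days
  bins <- seq(0, T_end, length.out = length(config$baseline_log_hazard) + 1)

  out <- with_seed(seed, {
    ## --- participants -------------------------------------------------
    pid <- seq_len(n)
    first_year <- runif(n) < config$frac_entry_first_year
    entry <- ifelse(first_year, runif(n, 0, 365),
                    runif(n, 365, max(365, T_end - 180)))
    age <- pmin(pmax(rnorm(n, config$age_mean, config$age_sd), 15), 95)
    prev <- config$covariate_prevalences
    female <- rbinom(n, 1, prev[["female"]])
    country_spain <- rbinom(n, 1, 0.9)
    areas <- cbind(x = runif(config$spatial$n_areas),
                   y = runif(config$spatial$n_areas))
    area <- sample.int(config$spatial$n_areas, n, replace = TRUE)
    s_area <- if (config$spatial$sd > 0) {
      simulate_matern_field(areas, config$spatial$sd, config$spatial$range,
                            config$spatial$nu)
    } else rep(0, config$spatial$n_areas)
    s <- s_area[area]
    u <- if (config$frailty_sd > 0) rnorm(n, 0, config$frailty_sd) else
      rep(0, n)

    ## --- comorbidities with onset dates ------------------------------
    conds <- setdiff(names(prev), "female")
    has <- matrix(FALSE, n, length(conds), dimnames = list(NULL, conds))
    for (cc in conds) has[, cc] <- rbinom(n, 1, prev[[cc]]) == 1
    loss <- entry + rexp(n, max(config$loss_rate, 1e-12))
    censor_admin <- pmin(T_end, loss)
    onset <- matrix(Inf, n, length(conds), dimnames = list(NULL, conds))
    for (j in seq_along(conds)) {
      at_entry <- runif(n) < config$frac_onset_at_entry
      o <- ifelse(at_entry, entry,
                  entry + runif(n) * pmax(censor_admin - entry, 0))
      onset[, j] <- ifelse(has[, j], o, Inf)
    }
    diagnoses <- do.call(rbind, lapply(seq_along(conds), function(j) {
      sel <- is.finite(onset[, j])
      data.frame(pid = pid[sel], condition = conds[j],
                 onset_day = round(onset[sel, j], 2))
    }))
    if (is.null(diagnoses)) diagnoses <- empty()$diagnoses

    ## --- PPI exposure episodes (confounded initiation) ----------------
    # initiation depends on the covariate state at entry (the state the
    # time-varying adjustment carries at that moment), not on later onsets
    xb_init <- rep(0, n)
    for (v in names(em$coef)) {
      xv <- if (v == "age70") as.numeric(age >= 70) else
        if (v %in% conds) as.numeric(onset[, v] <= entry) else 0
      xb_init <- xb_init + em$coef[[v]] * xv
    }
    xb_init <- xb_init + em$spatial_coef * s
    p_base <- plogis(em$baseline_intercept + xb_init)
    is_base_user <- runif(n) < p_base
    init_rate <- exp(em$followup_log_rate + xb_init)

    episodes <- vector("list", n)
    for (i in pid) {
      eps <- NULL
      t0 <- NA_real_
      if (is_base_user[i]) {
        t0 <- entry[i] + runif(1, 0, 300)
      } else {
        gap <- rexp(1, init_rate[i])
        cand <- entry[i] + 365 + gap
        if (cand < censor_admin[i]) t0 <- cand
      }
      while (!is.na(t0) && t0 < censor_admin[i]) {
        len <- max(7, round(rlnorm(1, em$episode_meanlog, em$episode_sdlog)))
        high <- runif(1) < em$dose_high_prob
        eps <- rbind(eps, data.frame(start = t0, len = len, high = high))
        t0 <- t0 + len + rexp(1, 1 / em$gap_mean)
        if (runif(1) < 0.5) t0 <- NA_real_  # about half have one episode
      }
      episodes[i] <- list(eps)
    }

    ## --- prescriptions realised from episodes -------------------------
    rx_pid <- rx_drug <- rx_dose <- rx_start <- rx_dur <- list()
    for (i in pid) {
      eps <- episodes[[i]]
      if (is.null(eps)) next
      for (k in seq_len(nrow(eps))) {
        drug <- sample(names(em$drug_probs), 1, prob = em$drug_probs)
        dose <- if (eps$high[k]) PPI_HIGH_MAX_MG[[drug]] else
          PPI_STANDARD_MG[[drug]]
        nchunk <- ceiling(eps$len[k] / em$chunk_days)
        starts <- eps$start[k] + em$chunk_days * (seq_len(nchunk) - 1L)
        durs <- rep(em$chunk_days, nchunk)
        durs[nchunk] <- eps$len[k] - em$chunk_days * (nchunk - 1L)
        j <- length(rx_pid) + 1L
        rx_pid[[j]] <- rep(i, nchunk); rx_drug[[j]] <- rep(drug, nchunk)
        rx_dose[[j]] <- rep(dose, nchunk); rx_start[[j]] <- starts
        rx_dur[[j]] <- durs
      }
    }
    if (length(rx_pid)) {
      dur <- unlist(rx_dur)
      nrx <- length(dur)
      recorded <- runif(nrx) < em$frac_recorded_days
      units <- sample(1:2, nrx, replace = TRUE)
      prescriptions <- data.frame(
        pid = unlist(rx_pid), drug = unlist(rx_drug),
        daily_dose_mg = unlist(rx_dose),
        start_day = round(unlist(rx_start), 2),
        treatment_days = ifelse(recorded, dur, NA_real_),
        quantity = ifelse(recorded, NA_real_, dur * units),
        daily_units = ifelse(recorded, NA_real_, units))
    } else prescriptions <- empty()$prescriptions

    ## --- event times: piecewise-exponential inversion ----------------
    blh <- config$baseline_log_hazard
    beta <- config$true_log_hr
    event <- rep(NA_real_, n)
    for (i in pid) {
      eps <- episodes[[i]]
      cuts <- c(entry[i], bins[bins > entry[i] & bins < censor_admin[i]])
      if (!is.null(eps)) {
        cuts <- c(cuts, eps$start, eps$start + eps$len)
      }
      ons <- onset[i, ]
      cuts <- c(cuts, ons[is.finite(ons)])
      if (age[i] < 70) cuts <- c(cuts, entry[i] + (70 - age[i]) * 365.25)
      cuts <- sort(unique(pmin(pmax(cuts, entry[i]), censor_admin[i])))
      cuts <- c(cuts[cuts < censor_admin[i]], censor_admin[i])
      if (length(cuts) < 2) next
      mid <- head(cuts, -1) + diff(cuts) / 2
      binid <- findInterval(mid, bins, rightmost.closed = TRUE)
      lp <- blh[binid] + u[i] + s[i]
      if (!is.null(eps)) {
        on_ppi <- vapply(mid, function(t)
          any(t >= eps$start & t < eps$start + eps$len), logical(1))
        on_high <- vapply(mid, function(t)
          any(t >= eps$start & t < eps$start + eps$len & eps$high),
          logical(1))
        lp <- lp + beta[["ppi"]] * on_ppi +
          (beta[["ppi_high"]] %||% 0) * on_high
      }
      lp <- lp + (beta[["female"]] %||% 0) * female[i]
      if (!is.null(beta[["age70"]])) {
        age_t <- age[i] + (mid - entry[i]) / 365.25
        lp <- lp + beta[["age70"]] * (age_t >= 70)
      }
      for (v in conds) {
        b <- beta[[v]]
        if (!is.null(b) && b != 0) lp <- lp + b * (mid >= onset[i, v])
      }
      if (any(!is.finite(lp))) {
        stop("non-finite hazard for participant ", i,
             " (check baseline_log_hazard / true_log_hr / random effects)")
      }
      tev <- piecewise_event_time(cuts, exp(lp), rexp(1))
      if (is.finite(tev)) event[i] <- tev
    }
    status <- as.integer(!is.na(event) & event <= censor_admin)
    exit <- ifelse(status == 1, event, censor_admin)

    ## --- laboratory visits encoding the latent event ------------------
    uacr_type <- runif(n) < lb$uacr_event_frac
    lab_pid <- lab_day <- lab_egfr <- lab_uacr <- lab_age <- lab_fem <-
      vector("list", n)
    for (i in pid) {
      span <- censor_admin[i] - entry[i]
      nv <- rpois(1, config$visit_rate * span / 365.25)
      if (nv == 0) next
      days <- sort(runif(nv, entry[i], censor_admin[i]))
      pre_egfr <- max(rnorm(1, lb$egfr_pre_mean, lb$egfr_pre_sd), 68)
      uacr_base <- pmin(rlnorm(nv, lb$uacr_meanlog, lb$uacr_sdlog), 28)
      ev <- event[i]
      post <- !is.na(ev) & days >= ev
      egfr_val <- pmax(pre_egfr + rnorm(nv, 0, lb$egfr_noise_sd), 61)
      uacr_val <- uacr_base
      if (any(post)) {
        if (uacr_type[i]) {
          uacr_val[post] <- pmax(35 + 10 * (days[post] - ev) / 365.25 +
                                   rnorm(sum(post), 0, 2), 31)
        } else {
          egfr_val[post] <- pmin(lb$egfr_post_start -
            lb$egfr_post_decline * (days[post] - ev) / 365.25 +
            rnorm(sum(post), 0, 2), 59)
          egfr_val[post] <- pmax(egfr_val[post], 5)
        }
      }
      lab_pid[[i]] <- rep(i, nv)
      lab_day[[i]] <- days
      lab_egfr[[i]] <- egfr_val
      lab_uacr[[i]] <- uacr_val
      lab_age[[i]] <- age[i] + (days - entry[i]) / 365.25
      lab_fem[[i]] <- rep(female[i] == 1, nv)
    }
    if (length(unlist(lab_pid))) {
      labs <- data.frame(
        pid = unlist(lab_pid), day = round(unlist(lab_day), 2),
        creatinine = round(creatinine_for_egfr(unlist(lab_egfr),
                                               unlist(lab_age),
                                               unlist(lab_fem)), 4),
        uacr = round(unlist(lab_uacr), 2))
    } else labs <- empty()$labs

    participants <- data.frame(
      pid = pid, sex = ifelse(female == 1, "female", "male"),
      age_entry = round(age, 2), entry_day = round(entry, 2),
      left_day = round(censor_admin, 2),
      country_spain = country_spain, area = area,
      loc_x = round(areas[area, 1], 6), loc_y = round(areas[area, 2], 6))
    truth <- data.frame(
      pid = pid, u = u, s = s, event_day = event,
      censor_day = censor_admin, exit_day = exit, status = status,
      entry_day = entry)
    list(participants = participants, prescriptions = prescriptions,
         labs = labs, diagnoses = diagnoses, truth = truth, config = config)
  })
  rownames(out$prescriptions) <- NULL
  rownames(out$labs) <- NULL
  rownames(out$diagnoses) <- NULL
  structure(out, class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$participants), "participants,",
      nrow(x$prescriptions), "prescriptions,", nrow(x$labs), "lab records;",
      sum(x$truth$status), "true incident events\n")
  invisible(x)
}
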