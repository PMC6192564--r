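# ---------------------------------------------------------------------
# Pipeline orchestration: simulate -> phenotype -> exposure -> split ->
# fit -> report, communicating only via provenance-headed delimited
# text files inside a run directory.
# ---------------------------------------------------------------------

# tiny polynomial hash for provenance headers (no external digest
# dependency; collisions are harmless here)
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_stage_table <- function(df, path, stage, config_hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ppickd stage=%s config=%s seed=%s version=%s",
                     stage, config_hash, seed,
                     as.character(utils::packageVersion("ppickd"))), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
}

read_stage_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             na.strings = "", stringsAsFactors = FALSE)
}

#' Assemble (or load) a pipeline configuration
#'
#' @param out_dir run directory for stage outputs.
#' @param seed global seed; recorded in every output's provenance
#'   header.
#' @param simulate `NULL` to consume existing input tables, or a list
#'   of [sim_config()] arguments for the synthetic generator.
#' @param inputs named paths (`participants`, `prescriptions`, `labs`,
#'   `diagnoses`) used when `simulate` is `NULL`.
#' @param phenotype list: `event_date_rule` (`"confirmation"`/
#'   `"first"`), `exclusion_rule` (`"two_determinations"`/`"single"`),
#'   `exclude_first_year` (logical), `min_span_days`.
#' @param exposure list: `grace_days`, `baseline_window_days`.
#' @param model list: `covariates` (character), `bins`, `frailty`,
#'   `spatial` (logical: use participant coordinates), `smooth`,
#'   `fixed` (named list of fixed hyperparameters).
#' @param report list: `strata_by` (`"stratum"` default).
#' @param file optional YAML file; when given, its keys are read first
#'   and the remaining arguments override them.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = tempfile("ppickd_run_"), seed = 1L,
                            simulate = list(), inputs = list(),
                            phenotype = list(), exposure = list(),
                            model = list(), report = list(), file = NULL) {
  base <- list()
  if (!is.null(file)) base <- yaml::read_yaml(file)
  merge2 <- function(nm, val) modifyList(base[[nm]] %||% list(), val)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              simulate = merge2("simulate", simulate),
              inputs = merge2("inputs", inputs),
              phenotype = merge2("phenotype", phenotype),
              exposure = merge2("exposure", exposure),
              model = merge2("model", model),
              report = merge2("report", report))
  cfg$phenotype <- modifyList(list(event_date_rule = "confirmation",
    exclusion_rule = "two_determinations", exclude_first_year = TRUE,
    min_span_days = 90), cfg$phenotype)
  cfg$exposure <- modifyList(list(grace_days = 0,
    baseline_window_days = 365), cfg$exposure)
  cfg$model <- modifyList(list(
    covariates = c("ppi", "ppi_high", "age70", "hypertension", "diabetes",
                   "obesity", "nsaid", "cardiovascular_disease"),
    bins = 24, frailty = FALSE, spatial = FALSE, smooth = TRUE,
    fixed = list()), cfg$model)
  cfg$report <- modifyList(list(strata_by = "stratum"), cfg$report)
  structure(cfg, class = "pipeline_config")
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the analysis pipeline end to end
#'
#' Executes the stages `simulate` (optional), `phenotype`, `exposure`,
#' `split`, `fit` and `report` in order, reading and writing
#' tab-separated tables with a provenance header (configuration hash,
#' seed, package version) in `config$out_dir`.  No stage mutates its
#' inputs; re-running with an identical configuration reproduces the
#' outputs byte-for-byte (the log file carries the only timestamps).
#'
#' @param config a [pipeline_config()] object.
#' @param stages subset of stages to run; default all.
#' @return invisibly, the run directory path.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "phenotype", "exposure",
                                    "split", "fit", "report")) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- fnv1a(unclass(config)[setdiff(names(config), "out_dir")])
  logf <- file(file.path(config$out_dir, "run.log"), "a")
  on.exit(close(logf))
  tab <- function(name) file.path(config$out_dir, paste0(name, ".tsv"))
  wr <- function(df, name, stage) write_stage_table(df, tab(name), stage, h,
                                                    config$seed)
  need <- function(name, what) {
    path <- if (!is.null(config$inputs[[name]]) &&
                !file.exists(tab(name))) config$inputs[[name]] else tab(name)
    if (!file.exists(path)) {
      stop("stage ", what, ": required table '", name, "' not found at ",
           path, call. = FALSE)
    }
    read_stage_table(path)
  }

  if ("simulate" %in% stages && length(config$simulate)) {
    log_line(logf, "simulate: generating synthetic cohort")
    sc <- do.call(sim_config, c(config$simulate,
                                list(seed = config$seed)))
    sim <- simulate_cohort(sc)
    wr(sim$participants, "participants", "simulate")
    wr(sim$prescriptions, "prescriptions", "simulate")
    wr(sim$labs, "labs", "simulate")
    wr(sim$diagnoses, "diagnoses", "simulate")
    wr(sim$truth, "truth", "simulate")
    cfg_out <- unclass(sc)
    cfg_out$study_start <- as.character(cfg_out$study_start)
    cfg_out$study_end <- as.character(cfg_out$study_end)
    yaml::write_yaml(cfg_out, file.path(config$out_dir, "sim_config.yaml"))
  }

  study_days <- NULL
  if ("phenotype" %in% stages) {
    log_line(logf, "phenotype: eGFR, incident CKD, prevalent exclusion")
    participants <- need("participants", "phenotype")
    labs <- need("labs", "phenotype")
    study_days <- max(participants$left_day %||% labs$day, labs$day)
    entry <- setNames(participants$entry_day, participants$pid)
    ageent <- setNames(participants$age_entry, participants$pid)
    female <- setNames(parse_sex(participants$sex), participants$pid)
    pidc <- as.character(labs$pid)
    age_at <- ageent[pidc] + (labs$day - entry[pidc]) / 365.25
    labs$egfr <- ckd_epi_egfr(labs$creatinine, age_at, female[pidc])
    fu_end <- setNames(participants$left_day %||%
                         rep(study_days, nrow(participants)),
                       participants$pid)
    ph <- config$phenotype
    excl_ids <- integer()
    inc_start <- 0
    if (isTRUE(ph$exclude_first_year)) {
      ex <- exclude_prevalent_ckd(participants, labs, 0,
                                  rule = ph$exclusion_rule,
                                  min_span_days = ph$min_span_days)
      excl_ids <- ex$excluded_ids
      inc_start <- ex$incidence_start
      participants <- ex$cohort
      labs <- labs[!(labs$pid %in% excl_ids), , drop = FALSE]
    }
    st <- detect_incident_ckd(labs,
      followup_start = pmax(entry[as.character(participants$pid)], inc_start),
      followup_end = fu_end[as.character(participants$pid)],
      min_span_days = ph$min_span_days,
      event_date_rule = ph$event_date_rule)
    st <- merge(data.frame(pid = participants$pid), st, all.x = TRUE)
    # participants without any lab row: censored, reason "no labs"
    miss <- is.na(st$incident)
    st$incident[miss] <- FALSE
    st$censor_day[miss] <- fu_end[as.character(st$pid[miss])]
    st$censor_reason[miss] <- "no labs"
    st$entry <- pmax(entry[as.character(st$pid)], inc_start)
    st$exit <- ifelse(st$incident, st$event_day, st$censor_day)
    st$status <- as.integer(st$incident)
    # participants censored before their incidence window opens carry no
    # at-risk time
    st <- st[st$exit > st$entry, , drop = FALSE]
    wr(st, "ckd_status", "phenotype")
    wr(data.frame(pid = excl_ids), "excluded_prevalent", "phenotype")
  }

  if ("exposure" %in% stages) {
    log_line(logf, "exposure: building PPI episode timelines")
    ckd <- need("ckd_status", "exposure")
    rx <- need("prescriptions", "exposure")
    ep <- config$exposure
    rx_by <- split(rx, as.character(rx$pid))
    tls <- lapply(seq_len(nrow(ckd)), function(i) {
      p <- as.character(ckd$pid[i])
      build_timeline(rx_by[[p]],
                     followup_start = ckd$entry[i],
                     followup_end = ckd$exit[i],
                     grace_days = ep$grace_days,
                     baseline_window_days = ep$baseline_window_days)
    })
    names(tls) <- ckd$pid
    epi <- do.call(rbind, lapply(names(tls), function(p) {
      e <- tls[[p]]$episodes
      if (nrow(e) == 0) return(NULL)
      cbind(pid = as.integer(p), e)
    }))
    if (is.null(epi)) {
      epi <- data.frame(pid = integer(), start = numeric(), end = numeric(),
                        dose = character(), n_rx = integer())
    }
    wr(epi, "exposure_episodes", "exposure")
    wr(data.frame(pid = as.integer(names(tls)),
                  stratum = vapply(tls, `[[`, "", "stratum"),
                  cumulative_days = vapply(tls, `[[`, 0, "cumulative_days")),
       "exposure_strata", "exposure")
  }

  if ("split" %in% stages) {
    log_line(logf, "split: Andersen-Gill counting-process table")
    ckd <- need("ckd_status", "split")
    participants <- need("participants", "split")
    epi <- need("exposure_episodes", "split")
    diagnoses <- tryCatch(need("diagnoses", "split"), error = function(e) NULL)
    fu <- data.frame(pid = ckd$pid, entry = ckd$entry, exit = ckd$exit,
                     status = ckd$status)
    fu <- fu[fu$exit > fu$entry, , drop = FALSE]
    tls <- rebuild_timelines(epi, fu)
    ageent <- setNames(participants$age_entry, participants$pid)
    onsets <- if (!is.null(diagnoses) && nrow(diagnoses)) {
      data.frame(pid = diagnoses$pid, var = diagnoses$condition,
                 day = diagnoses$onset_day)
    } else NULL
    cp <- build_counting_table(fu, tls, age_at_entry = ageent,
                               onsets = onsets)
    viol <- validate_counting_table(cp)
    if (length(viol)) stop("invalid counting-process table: ",
                           paste(viol, collapse = "; "))
    wr(cp, "counting", "split")
  }

  fit <- NULL
  if ("fit" %in% stages) {
    log_line(logf, "fit: Bayesian piecewise-exponential hazard model")
    cp <- need("counting", "fit")
    md <- config$model
    covs <- intersect(md$covariates, names(cp))
    constant <- vapply(covs, function(v) stats::var(cp[[v]]) == 0, logical(1))
    if (any(constant)) {
      log_line(logf, "fit: dropping constant covariate(s): ",
               paste(covs[constant], collapse = ", "))
      covs <- covs[!constant]
    }
    fml <- stats::as.formula(paste(
      "survival::Surv(start, stop, status) ~",
      paste(covs, collapse = " + ")))
    coords <- NULL
    if (isTRUE(md$spatial)) {
      participants <- need("participants", "fit")
      loc <- participants[match(cp$pid, participants$pid),
                          c("loc_x", "loc_y")]
      cp$loc_x <- loc$loc_x; cp$loc_y <- loc$loc_y
      coords <- c("loc_x", "loc_y")
    }
    fit <- bpeh(fml, cp, id = "pid", frailty = isTRUE(md$frailty),
                coords = coords, bins = md$bins, smooth = md$smooth,
                fixed = md$fixed)
    sm <- summary(fit)$coefficients
    coeft <- data.frame(name = rownames(sm), mode = sm$mode, sd = sm$sd,
                        hr = sm$hr, lower = sm$lower, upper = sm$upper)
    wr(coeft, "coefficients", "fit")
    wr(data.frame(bin = seq_along(fit$lambda),
                  t_start = head(fit$breaks, -1), t_end = fit$breaks[-1],
                  log_hazard = fit$lambda, sd = fit$lambda_sd),
       "baseline_hazard", "fit")
    jsonlite::write_json(list(
      coefficients = as.list(setNames(coeft$hr, coeft$name)),
      hyper = as.list(fit$hyper), logml = fit$logml,
      n = fit$n, n_events = fit$n_events, seed = config$seed),
      file.path(config$out_dir, "fit.json"), auto_unbox = TRUE, digits = 10)
    log_line(logf, "fit: done (", fit$n_events, " events)")
  }

  if ("report" %in% stages) {
    log_line(logf, "report: survival curves, log-rank, baseline tables")
    ckd <- need("ckd_status", "report")
    strata <- need("exposure_strata", "report")
    surv <- data.frame(entry = ckd$entry, exit = ckd$exit,
                       status = ckd$status)
    lab <- strata$stratum[match(ckd$pid, strata$pid)]
    curves <- kalbfleisch_prentice(surv, strata = lab)
    wr(as.data.frame(curves), "survival_curves", "report")
    if (length(unique(lab)) >= 2) {
      lr <- log_rank(surv, lab)
      wr(data.frame(chisq = lr$chisq, df = lr$df, p = lr$p_value),
         "logrank", "report")
    }
    participants <- need("participants", "report")
    desc <- data.frame(
      age = participants$age_entry[match(ckd$pid, participants$pid)],
      female = as.integer(parse_sex(
        participants$sex[match(ckd$pid, participants$pid)])),
      ckd = ckd$status)
    bt <- baseline_tables(desc, lab)
    wr(bt$cells, "baseline_table", "report")
    if (!is.null(bt$tests)) wr(bt$tests, "baseline_tests", "report")
  }
  log_line(logf, "pipeline complete")
  invisible(config$out_dir)
}

# Reconstitute exposure_timeline objects from the episodes table
rebuild_timelines <- function(epi, fu) {
  epi_by <- split(epi[, c("start", "end", "dose", "n_rx")],
                  as.character(epi$pid))
  empty <- data.frame(start = numeric(), end = numeric(),
                      dose = character(), n_rx = integer())
  tls <- list()
  for (i in seq_len(nrow(fu))) {
    p <- fu$pid[i]
    e <- epi_by[[as.character(p)]] %||% empty
    rownames(e) <- NULL
    e$end <- pmin(e$end, fu$exit[i])
    e <- e[e$end > e$start, , drop = FALSE]
    tls[[as.character(p)]] <- structure(
      list(episodes = e,
           stratum = if (nrow(e) == 0) "never" else
             if (any(e$start < fu$entry[i] + 365)) "baseline" else
               "follow-up",
           cumulative_days = sum(e$end - e$start),
           followup_start = fu$entry[i], followup_end = fu$exit[i]),
      class = "exposure_timeline")
  }
  tls
}

#' Counting-process table from simulation ground truth
#'
#' Builds the Andersen-Gill table directly from a simulated cohort's
#' latent truth (true event/censoring times and true exposure
#' episodes), bypassing laboratory-based phenotyping.  This isolates
#' the estimator in parameter-recovery studies: the model sees exactly
#' the data-generating risk intervals.
#'
#' @param sim a [simulate_cohort()] result.
#' @param grace_days episode-merging grace period; default 0.
#' @param covariates which time-varying covariates to include, as in
#'   [build_counting_table()].
#' @return counting-process data frame with `loc_x`/`loc_y` columns
#'   appended for spatial fits.
#' @export
truth_counting_table <- function(sim, grace_days = 0,
                                 covariates = NULL) {
  tr <- sim$truth
  fu <- data.frame(pid = tr$pid, entry = tr$entry_day, exit = tr$exit_day,
                   status = tr$status)
  fu <- fu[fu$exit > fu$entry, , drop = FALSE]
  rx_by <- split(sim$prescriptions, as.character(sim$prescriptions$pid))
  tls <- list()
  for (i in seq_len(nrow(fu))) {
    p <- fu$pid[i]
    tls[[as.character(p)]] <- build_timeline(
      rx_by[[as.character(p)]], fu$entry[i], fu$exit[i],
      grace_days = grace_days)
  }
  ageent <- setNames(sim$participants$age_entry, sim$participants$pid)
  dg <- sim$diagnoses
  onsets <- if (nrow(dg)) data.frame(pid = dg$pid, var = dg$condition,
                                     day = dg$onset_day) else NULL
  cp <- build_counting_table(fu, tls, age_at_entry = ageent, onsets = onsets)
  loc <- sim$participants[match(cp$pid, sim$participants$pid),
                          c("loc_x", "loc_y")]
  cp$loc_x <- loc$loc_x
  cp$loc_y <- loc$loc_y
  if (!is.null(covariates)) {
    keep <- c("pid", "start", "stop", "status", covariates,
              "loc_x", "loc_y")
    cp <- cp[, intersect(keep, names(cp)), drop = FALSE]
  }
  cp
}
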