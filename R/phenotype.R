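#' Detect incident chronic kidney disease from longitudinal labs
#'
#' A participant becomes an incident CKD case when two or more
#' determinations qualify — eGFR < 60 mL/min/1.73m2 and/or
#' UACR >= 30 mg/g, either criterion per determination — and the span
#' from the first qualifying determination to a confirming one is at
#' least 90 days ("a minimum of 3 months", with a month fixed at 30
#' days), all within the follow-up window.  Qualifying determinations
#' need not be consecutive: intervening normal values do not reset the
#' clock.  A day with both analytes measured counts as one
#' determination.
#'
#' The event date is, by default, the date of the earliest determination
#' that completes the 90-day confirmation (chronicity is only
#' established then); `event_date_rule = "first"` switches to the first
#' qualifying date.
#'
#' @param labs data frame of laboratory determinations with columns
#'   `day` (numeric, days on the analysis time scale) and at least one
#'   of `egfr`, `uacr`; an optional `pid` column processes several
#'   participants at once.  Missing analyte values are `NA`.
#' @param followup_start,followup_end follow-up window (days, closed on
#'   both sides); scalars, or vectors named by participant id.
#' @param egfr_threshold,uacr_threshold qualifying thresholds;
#'   defaults 60 mL/min/1.73m2 and 30 mg/g.
#' @param min_span_days minimum first-to-confirming span; default 90.
#' @param event_date_rule `"confirmation"` (default) or `"first"`.
#' @return data frame, one row per participant: `pid`, `incident`,
#'   `event_day` (`NA` when censored), `first_qualifying_day`,
#'   `n_qualifying`, `censor_day`, `censor_reason` (`"end of follow-up"`
#'   or `"no labs"`).  A censored participant never raises an error.
#' @export
detect_incident_ckd <- function(labs, followup_start, followup_end,
                                egfr_threshold = 60, uacr_threshold = 30,
                                min_span_days = 90,
                                event_date_rule = c("confirmation", "first")) {
  event_date_rule <- match.arg(event_date_rule)
  if (is.null(labs$pid)) labs$pid <- 1L
  pids <- sort(unique(labs$pid))
  if (length(pids) == 0L) {
    return(data.frame(pid = integer(), incident = logical(),
                      event_day = numeric(), first_qualifying_day = numeric(),
                      n_qualifying = integer(), censor_day = numeric(),
                      censor_reason = character()))
  }
  win_start <- lookup_window(followup_start, pids)
  win_end <- lookup_window(followup_end, pids)

  egfr <- if (!is.null(labs$egfr)) labs$egfr else rep(NA_real_, nrow(labs))
  uacr <- if (!is.null(labs$uacr)) labs$uacr else rep(NA_real_, nrow(labs))
  qual <- (!is.na(egfr) & egfr < egfr_threshold) |
    (!is.na(uacr) & uacr >= uacr_threshold)

  res <- lapply(seq_along(pids), function(i) {
    p <- pids[i]
    sel <- labs$pid == p & labs$day >= win_start[i] & labs$day <= win_end[i]
    has_value <- sel & (!is.na(egfr) | !is.na(uacr))
    qdays <- sort(unique(labs$day[sel & qual]))
    first_q <- if (length(qdays)) qdays[1] else NA_real_
    confirm <- NA_real_
    if (length(qdays) >= 2) {
      ok <- qdays >= first_q + min_span_days
      if (any(ok)) confirm <- qdays[ok][1]
    }
    incident <- !is.na(confirm)
    event_day <- if (!incident) NA_real_ else
      if (event_date_rule == "confirmation") confirm else first_q
    data.frame(pid = p, incident = incident, event_day = event_day,
               first_qualifying_day = first_q,
               n_qualifying = length(qdays),
               censor_day = if (incident) event_day else win_end[i],
               censor_reason = if (incident) NA_character_
                 else if (!any(has_value)) "no labs" else "end of follow-up",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

lookup_window <- function(x, pids) {
  if (length(x) == 1L && is.null(names(x))) return(rep(x, length(pids)))
  if (!is.null(names(x))) {
    out <- x[as.character(pids)]
    if (anyNA(out)) stop("follow-up window missing for some participants")
    return(as.numeric(out))
  }
  if (length(x) != length(pids)) stop("window length does not match participants")
  as.numeric(x)
}

#' Exclude participants with pre-existing CKD in the first year
#'
#' Applies the incident-CKD definition (the same two-determination,
#' 90-day rule by default) to determinations in the first year of
#' follow-up, `[study_start, study_start + 365)`, and removes
#' participants who meet it.  Survivors' at-risk time for incidence
#' starts after the first year.  `rule = "single"` instead excludes on
#' any single abnormal first-year determination.
#'
#' @param participants data frame with a `pid` column.
#' @param labs laboratory determinations as in [detect_incident_ckd()].
#' @param study_start start of the study window (days).
#' @param window_days length of the screening window; default 365.
#' @param rule `"two_determinations"` (default) or `"single"`.
#' @inheritParams detect_incident_ckd
#' @return list with `cohort` (filtered participants), `excluded_ids`,
#'   `n_excluded`, and `incidence_start` (= `study_start + window_days`).
#' @export
exclude_prevalent_ckd <- function(participants, labs, study_start,
                                  window_days = 365,
                                  rule = c("two_determinations", "single"),
                                  egfr_threshold = 60, uacr_threshold = 30,
                                  min_span_days = 90) {
  rule <- match.arg(rule)
  if (is.null(labs$pid)) labs$pid <- 1L
  window_end <- study_start + window_days - 1e-9
  if (rule == "two_determinations") {
    st <- detect_incident_ckd(labs, study_start, window_end,
                              egfr_threshold, uacr_threshold, min_span_days)
    excluded <- st$pid[st$incident]
  } else {
    egfr <- if (!is.null(labs$egfr)) labs$egfr else rep(NA_real_, nrow(labs))
    uacr <- if (!is.null(labs$uacr)) labs$uacr else rep(NA_real_, nrow(labs))
    qual <- (!is.na(egfr) & egfr < egfr_threshold) |
      (!is.na(uacr) & uacr >= uacr_threshold)
    inwin <- labs$day >= study_start & labs$day <= window_end
    excluded <- unique(labs$pid[inwin & qual])
  }
  keep <- !(participants$pid %in% excluded)
  list(cohort = participants[keep, , drop = FALSE],
       excluded_ids = sort(excluded),
       n_excluded = length(unique(excluded)),
       incidence_start = study_start + window_days)
}
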