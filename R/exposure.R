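PPI_DRUGS <- c("omeprazole", "esomeprazole", "lansoprazole",
               "pantoprazole", "rabeprazole")

# standard-dose upper limits (mg/day); anything above is "high"
PPI_STANDARD_MG <- c(omeprazole = 20, esomeprazole = 20, pantoprazole = 20,
                     lansoprazole = 15, rabeprazole = 10)
# printed upper bounds of the high-dose ranges; doses above are still
# classified high (open upper bound) but flagged
PPI_HIGH_MAX_MG <- c(omeprazole = 40, esomeprazole = 40, pantoprazole = 40,
                     lansoprazole = 30, rabeprazole = 20)

#' Duration of a single prescription in days
#'
#' Uses the number of treatment days recorded by the prescriber when
#' present; otherwise divides the total quantity dispensed by the
#' numeric daily dose (units/day), rounding up.  When both sources are
#' present and disagree, the recorded days take precedence and a
#' warning is issued.
#'
#' @param p a prescription: a list or one-row data frame with any of
#'   `treatment_days`, `quantity`, `daily_units`; alternatively pass
#'   the three fields directly as vectors.
#' @param quantity,daily_units used when `p` is missing; vectorised.
#' @return duration in whole days (positive integer).
#' @export
prescription_duration <- function(p = NULL, quantity = NULL,
                                  daily_units = NULL) {
  if (!is.null(p)) {
    treatment_days <- p$treatment_days %||% NA_real_
    quantity <- p$quantity %||% NA_real_
    daily_units <- p$daily_units %||% NA_real_
  } else {
    treatment_days <- NA_real_
  }
  n <- max(length(treatment_days), length(quantity), length(daily_units))
  treatment_days <- rep_len(treatment_days, n)
  quantity <- rep_len(quantity, n)
  daily_units <- rep_len(daily_units, n)

  from_qty <- rep(NA_real_, n)
  have_qty <- !is.na(quantity) & !is.na(daily_units)
  if (any(have_qty & daily_units == 0)) {
    stop("daily_units must be non-zero when duration is derived from quantity")
  }
  from_qty[have_qty] <- ceiling(quantity[have_qty] / daily_units[have_qty])
  have_days <- !is.na(treatment_days)
  if (any(!have_days & !have_qty)) {
    stop("prescription needs treatment_days or (quantity and daily_units)")
  }
  disagree <- have_days & have_qty & treatment_days != from_qty
  if (any(disagree)) {
    warning(sprintf(
      "%d prescription(s): recorded treatment days disagree with quantity/daily dose; using recorded days",
      sum(disagree)))
  }
  out <- ifelse(have_days, treatment_days, from_qty)
  if (any(out <= 0)) stop("prescription duration must be positive")
  as.integer(out)
}

#' Dose category of a PPI prescription
#'
#' Standard daily doses are 20 mg for omeprazole, esomeprazole and
#' pantoprazole, 15 mg for lansoprazole and 10 mg for rabeprazole;
#' doses above the standard are high (21--40, 16--30 and 11--20 mg
#' respectively).  Doses above the printed high ranges are still
#' classified high (open upper bound) and reported via a message.
#'
#' @param drug character vector among `r paste(PPI_DRUGS, collapse=", ")`.
#' @param daily_dose_mg positive daily dose in mg.
#' @return character vector, `"standard"` or `"high"`.
#' @export
dose_category <- function(drug, daily_dose_mg) {
  drug <- tolower(as.character(drug))
  if (any(!drug %in% PPI_DRUGS)) {
    stop("unknown drug: ", paste(setdiff(drug, PPI_DRUGS), collapse = ", "))
  }
  if (any(daily_dose_mg <= 0)) stop("daily dose must be positive")
  std <- PPI_STANDARD_MG[drug]
  over <- daily_dose_mg > PPI_HIGH_MAX_MG[drug]
  if (any(over)) {
    message(sum(over), " dose(s) above the usual high-dose range; classified high")
  }
  unname(ifelse(daily_dose_mg <= std, "standard", "high"))
}

AEMPS_BREAKS <- c(0, 30, 90, 180, 360, 720, Inf)
AEMPS_LABELS <- c("<1 month", "1-3 months", "3-6 months", "6-12 months",
                  "12-24 months", ">24 months")
COLLAPSED_BREAKS <- c(0, 30, 90, 180, Inf)
COLLAPSED_LABELS <- c("<1 month", "1-3 months", "3-6 months", ">6 months")

#' Cumulative PPI exposure duration category
#'
#' Categorises cumulative exposure days into the AEMPS duration classes
#' (<1, 1--3, 3--6, 6--12, 12--24, >24 months) or the collapsed
#' four-class scheme (<1, 1--3, 3--6, >6 months).  A month is 30 days;
#' intervals are half-open `[lower, upper)`.
#'
#' @param cumulative_days non-negative exposure days.
#' @param scheme `"aemps"` (six classes, default) or `"collapsed"`.
#' @return factor with the scheme's labels in increasing order.
#' @export
duration_category <- function(cumulative_days, scheme = c("aemps", "collapsed")) {
  scheme <- match.arg(scheme)
  if (any(cumulative_days < 0)) stop("cumulative_days must be non-negative")
  breaks <- if (scheme == "aemps") AEMPS_BREAKS else COLLAPSED_BREAKS
  labels <- if (scheme == "aemps") AEMPS_LABELS else COLLAPSED_LABELS
  cut(cumulative_days, breaks = breaks, labels = labels, right = FALSE)
}

#' Build a participant's PPI exposure timeline
#'
#' Turns a participant's raw prescriptions into merged exposure
#' episodes: each prescription covers `[start, start + duration)`;
#' prescriptions that overlap, or whose gap is at most `grace_days`,
#' are merged into one episode ("consecutive prescriptions").  A merged
#' episode is high-dose if any constituent prescription is.  Episodes
#' are clipped to the follow-up window; exposure accrued before entry
#' still counts towards cumulative duration if `count_pre_entry` is
#' TRUE (default FALSE: the exposure time of interest is that during
#' follow-up).
#'
#' The user stratum is `"baseline"` when any episode intersects the
#' first year of the participant's follow-up (`[followup_start,
#' followup_start + 365)`), `"follow-up"` when exposure exists but
#' starts later, and `"never"` otherwise.
#'
#' @param prescriptions data frame for one participant with columns
#'   `drug`, `daily_dose_mg`, `start_day` and duration fields as in
#'   [prescription_duration()].  May have zero rows.
#' @param followup_start,followup_end follow-up window in days; episodes
#'   are truncated at `followup_end` (the participant's event or censor
#'   date).
#' @param grace_days maximal gap between prescriptions still merged into
#'   one episode; default 0 (strict contiguity).
#' @param baseline_window_days length of the window defining baseline
#'   use; default 365.
#' @return object of class `"exposure_timeline"`: list with `episodes`
#'   (data frame `start`, `end`, `dose`, `n_rx`), `stratum`,
#'   `cumulative_days`, and the follow-up window.
#' @export
build_timeline <- function(prescriptions, followup_start, followup_end,
                           grace_days = 0, baseline_window_days = 365) {
  if (followup_end < followup_start) stop("followup_end before followup_start")
  epi <- data.frame(start = numeric(), end = numeric(), dose = character(),
                    n_rx = integer(), stringsAsFactors = FALSE)
  if (!is.null(prescriptions) && nrow(prescriptions) > 0) {
    dur <- prescription_duration(prescriptions)
    dose <- dose_category(prescriptions$drug, prescriptions$daily_dose_mg)
    s <- prescriptions$start_day
    e <- s + dur
    o <- order(s, e)
    s <- s[o]; e <- e[o]; dose <- dose[o]
    cs <- s[1]; ce <- e[1]; chigh <- dose[1] == "high"; cn <- 1L
    for (i in seq_along(s)[-1]) {
      # the 1e-6-day slack keeps exactly-contiguous prescriptions merged
      # in the face of floating-point date arithmetic
      if (s[i] <= ce + grace_days + 1e-6) {
        ce <- max(ce, e[i]); chigh <- chigh || dose[i] == "high"; cn <- cn + 1L
      } else {
        epi <- rbind(epi, data.frame(start = cs, end = ce,
          dose = if (chigh) "high" else "standard", n_rx = cn))
        cs <- s[i]; ce <- e[i]; chigh <- dose[i] == "high"; cn <- 1L
      }
    }
    epi <- rbind(epi, data.frame(start = cs, end = ce,
      dose = if (chigh) "high" else "standard", n_rx = cn))
    # clip to follow-up
    epi$start <- pmax(epi$start, followup_start)
    epi$end <- pmin(epi$end, followup_end)
    epi <- epi[epi$end > epi$start, , drop = FALSE]
    rownames(epi) <- NULL
  }
  stratum <- "never"
  if (nrow(epi) > 0) {
    baseline_end <- followup_start + baseline_window_days
    stratum <- if (any(epi$start < baseline_end)) "baseline" else "follow-up"
  }
  structure(list(episodes = epi, stratum = stratum,
                 cumulative_days = sum(epi$end - epi$start),
                 followup_start = followup_start,
                 followup_end = followup_end),
            class = "exposure_timeline")
}

#' Cumulative exposure accrued by given days
#'
#' Evaluates the timeline's cumulative-exposure function (piecewise
#' linear, slope 1 inside episodes, 0 outside) at `days`.
#'
#' @param timeline an [build_timeline()] object.
#' @param days evaluation times (days on the analysis scale).
#' @return numeric vector of cumulative exposure days.
#' @export
cumulative_exposure <- function(timeline, days) {
  epi <- timeline$episodes
  vapply(days, function(t) {
    if (nrow(epi) == 0) return(0)
    sum(pmax(0, pmin(t, epi$end) - epi$start))
  }, numeric(1))
}

# Days at which cumulative exposure crosses the given thresholds
# (used as covariate change points).  Inverts the piecewise-linear
# cumulative-exposure function exactly.  Returns a data frame with the
# 1-based index of each crossed threshold and its crossing day;
# thresholds never reached are omitted.
exposure_threshold_days <- function(timeline, thresholds = AEMPS_BREAKS[2:6]) {
  epi <- timeline$episodes
  if (nrow(epi) == 0) {
    return(data.frame(index = integer(), day = numeric()))
  }
  len <- epi$end - epi$start
  cum_at_start <- cumsum(c(0, head(len, -1)))
  total <- sum(len)
  day <- vapply(thresholds, function(th) {
    if (th >= total) return(NA_real_)
    i <- which(cum_at_start <= th & th < cum_at_start + len)[1]
    epi$start[i] + (th - cum_at_start[i])
  }, numeric(1))
  ok <- !is.na(day)
  data.frame(index = which(ok), day = day[ok])
}

#' @export
print.exposure_timeline <- function(x, ...) {
  cat("PPI exposure timeline:", nrow(x$episodes), "episode(s),",
      x$cumulative_days, "cumulative days, stratum:", x$stratum, "\n")
  if (nrow(x$episodes)) print(x$episodes)
  invisible(x)
}
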