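#' Split a participant's follow-up into Andersen-Gill risk intervals
#'
#' Restructures one participant's follow-up `[entry, exit]` into
#' counting-process (start-stop) risk intervals on which all covariates
#' are constant.  Covariate changes are applied left-closed: a change
#' at day `t` is in force from `t` onwards, so an event coinciding with
#' a change date is attributed to the covariate state in force just
#' before the change.  Delayed entry is preserved: the first interval
#' starts at `entry`, which may be positive.
#'
#' @param entry,exit follow-up bounds in days on the analysis time
#'   scale; `entry < exit`.
#' @param status 0 (censored) or 1 (event at `exit`).
#' @param baseline named list (or 1-row data frame) of covariate values
#'   in force at entry.
#' @param changes data frame of covariate change points with columns
#'   `day`, `var`, `value`; may be `NULL` or empty.  Changes dated at
#'   or before `entry` update the entry state; changes at or after
#'   `exit` are ignored (with a warning when `warn = TRUE`).
#' @param warn warn on ignored change points; default TRUE.
#' @return data frame of intervals: `start`, `stop`, `status`, then one
#'   column per covariate.  The number of rows is the number of change
#'   points strictly inside `(entry, exit)` plus one.
#' @export
split_intervals <- function(entry, exit, status, baseline = list(),
                            changes = NULL, warn = TRUE) {
  if (!(entry < exit)) stop("entry must be strictly before exit")
  if (!status %in% c(0, 1)) stop("status must be 0 or 1")
  state <- as.list(baseline)
  if (is.null(changes) || nrow(changes) == 0L) {
    changes <- data.frame(day = numeric(), var = character(),
                          value = numeric(), stringsAsFactors = FALSE)
  }
  changes <- changes[order(changes$day), , drop = FALSE]
  pre <- changes$day <= entry
  for (i in which(pre)) state[[as.character(changes$var[i])]] <- changes$value[i]
  post <- changes$day >= exit
  if (warn && any(post & changes$day > exit)) {
    warning(sum(post & changes$day > exit),
            " covariate change(s) after exit ignored")
  }
  inner <- changes[!pre & !post, , drop = FALSE]
  cuts <- c(entry, unique(inner$day), exit)
  out <- vector("list", length(cuts) - 1L)
  for (k in seq_len(length(cuts) - 1L)) {
    for (i in which(inner$day == cuts[k])) {
      state[[as.character(inner$var[i])]] <- inner$value[i]
    }
    row <- data.frame(start = cuts[k], stop = cuts[k + 1L],
                      status = if (k == length(cuts) - 1L) status else 0)
    for (v in names(state)) row[[v]] <- state[[v]]
    out[[k]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Validate a counting-process table
#'
#' Checks the structural invariants of an Andersen-Gill start-stop
#' table: positive-length intervals, status coded 0/1, per-participant
#' intervals contiguous and non-overlapping, events only on a
#' participant's final interval, and finite covariate values.
#'
#' @param tab data frame with columns `pid`, `start`, `stop`, `status`
#'   and covariate columns.
#' @return character vector of violations; empty when the table is
#'   valid.
#' @export
validate_counting_table <- function(tab) {
  v <- character()
  need <- c("pid", "start", "stop", "status")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  if (any(tab$stop <= tab$start)) {
    v <- c(v, sprintf("%d interval(s) with stop <= start",
                      sum(tab$stop <= tab$start)))
  }
  if (any(!tab$status %in% c(0, 1))) v <- c(v, "status not in {0,1}")
  covcols <- setdiff(names(tab), need)
  for (cc in covcols) {
    x <- tab[[cc]]
    if (is.numeric(x) && any(!is.finite(x))) {
      v <- c(v, paste("non-finite covariate:", cc))
    }
  }
  for (p in unique(tab$pid)) {
    rows <- tab[tab$pid == p, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    n <- nrow(rows)
    if (n > 1L && any(abs(rows$start[-1] - rows$stop[-n]) > 1e-9)) {
      v <- c(v, sprintf("participant %s: intervals not contiguous", p))
    }
    if (any(rows$status[-n] == 1)) {
      v <- c(v, sprintf("participant %s: event on a non-final interval", p))
    }
    if (sum(rows$status) > 1) {
      v <- c(v, sprintf("participant %s: multiple events", p))
    }
  }
  v
}

# Merge adjacent intervals of one participant whose covariates are
# identical (inverse of splitting at a spurious change point).
merge_intervals <- function(tab) {
  covcols <- setdiff(names(tab), c("pid", "start", "stop", "status"))
  out <- lapply(split(tab, tab$pid), function(rows) {
    rows <- rows[order(rows$start), , drop = FALSE]
    keep <- rep(TRUE, nrow(rows))
    for (i in seq_len(nrow(rows))[-1]) {
      same <- all(vapply(covcols, function(cc)
        identical(rows[[cc]][i], rows[[cc]][i - 1L]), logical(1)))
      if (same && abs(rows$start[i] - rows$stop[i - 1L]) < 1e-9) {
        j <- max(which(keep[seq_len(i - 1L)]))
        rows$stop[j] <- rows$stop[i]
        rows$status[j] <- rows$status[i]
        keep[i] <- FALSE
      }
    }
    rows[keep, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the cohort counting-process table
#'
#' Applies [split_intervals()] across a cohort: each participant's
#' follow-up is split at their PPI exposure change points (episode
#' starts and ends, cumulative-duration category boundary crossings at
#' 30/90/180/360/720 accumulated days, dose-category changes), their
#' 70th birthday, and any recorded comorbidity or treatment onset
#' dates.
#'
#' @param followup data frame with one row per participant: `pid`,
#'   `entry`, `exit`, `status` (days; `status` 1 = incident CKD at
#'   `exit`).
#' @param timelines named list of [build_timeline()] objects keyed by
#'   participant id; participants absent from the list are treated as
#'   never-users.
#' @param age_at_entry optional named vector (by pid) of ages in years
#'   at `entry`; adds the time-varying `age70` indicator.
#' @param onsets optional data frame `pid`, `var`, `day` of recorded
#'   comorbidity/treatment onsets; each `var` becomes a 0/1 covariate
#'   switching on at `day`.
#' @param duration_breaks cumulative-exposure category boundaries in
#'   days; default `c(30, 90, 180, 360, 720)`.  Set to `NULL` to skip
#'   the `ppi_months` covariate.
#' @return counting-process data frame: `pid`, `start`, `stop`,
#'   `status`, `ppi` (currently exposed), `ppi_high` (currently on a
#'   high dose), `ppi_months` (ordinal index of the cumulative-duration
#'   category, 0 = no exposure yet), optional `age70`, and one 0/1
#'   column per onset variable.
#' @export
build_counting_table <- function(followup, timelines, age_at_entry = NULL,
                                 onsets = NULL,
                                 duration_breaks = AEMPS_BREAKS[2:6]) {
  n <- nrow(followup)
  onset_vars <- if (!is.null(onsets)) sort(unique(as.character(onsets$var)))
    else character()
  vars <- c("ppi", "ppi_high",
            if (!is.null(duration_breaks)) c("ppi_months", "ppi_ever"),
            if (!is.null(age_at_entry)) "age70",
            onset_vars)
  onset_by_pid <- if (!is.null(onsets)) {
    split(onsets[, c("var", "day")], as.character(onsets$pid))
  } else list()

  pid_out <- start_out <- stop_out <- status_out <- vector("list", n)
  cov_out <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- followup$pid[i]
    entry <- followup$entry[i]
    exit <- followup$exit[i]
    status <- followup$status[i]
    base <- setNames(numeric(length(vars)), vars)
    cd <- cv <- numeric(0); cn <- character(0)
    add <- function(day, var, val) {
      cd <<- c(cd, day); cn <<- c(cn, var); cv <<- c(cv, val)
    }
    tl <- timelines[[as.character(pid)]]
    if (!is.null(tl) && nrow(tl$episodes)) {
      epi <- tl$episodes
      add(epi$start, rep("ppi", nrow(epi)), rep(1, nrow(epi)))
      add(epi$end, rep("ppi", nrow(epi)), rep(0, nrow(epi)))
      add(epi$start, rep("ppi_high", nrow(epi)),
          as.numeric(epi$dose == "high"))
      add(epi$end, rep("ppi_high", nrow(epi)), rep(0, nrow(epi)))
      if (!is.null(duration_breaks)) {
        thr <- exposure_threshold_days(tl, duration_breaks)
        if (nrow(thr)) add(thr$day, rep("ppi_months", nrow(thr)), thr$index)
        add(min(epi$start), "ppi_ever", 1)
      }
    }
    if (!is.null(age_at_entry)) {
      age <- age_at_entry[[as.character(pid)]]
      base[["age70"]] <- as.numeric(age >= 70)
      cross <- entry + (70 - age) * 365.25
      if (cross > entry && cross < exit) add(cross, "age70", 1)
    }
    ob <- onset_by_pid[[as.character(pid)]]
    if (!is.null(ob)) {
      agg <- tapply(ob$day, as.character(ob$var), min)
      for (v in names(agg)) {
        if (agg[[v]] <= entry) base[[v]] <- 1 else add(agg[[v]], v, 1)
      }
    }
    # snap change days to a 1e-6-day grid so cut points that differ only
    # by floating-point error (e.g. a duration threshold falling exactly
    # on an episode end) coincide instead of creating zero-length
    # intervals; changes within the same tolerance of entry or exit are
    # folded into the boundary (a change at the exit tie never starts a
    # new interval: the event keeps the covariate state in force before)
    cd <- round(cd, 6)
    if (length(cd)) {
      o <- order(cd)
      cd <- cd[o]; cn <- cn[o]; cv <- cv[o]
      pre <- cd <= entry + 1e-6
      for (j in which(pre)) base[[cn[j]]] <- cv[j]
      keep <- !pre & cd < exit - 1e-6
      cd <- cd[keep]; cn <- cn[keep]; cv <- cv[keep]
    }
    cuts <- unique(cd)
    starts <- c(entry, cuts)
    stops <- c(cuts, exit)
    k <- length(starts)
    covm <- matrix(rep(base, each = k), k, length(vars),
                   dimnames = list(NULL, vars))
    for (v in unique(cn)) {
      sel <- cn == v
      covm[, v] <- c(base[[v]], cv[sel])[findInterval(starts, cd[sel]) + 1L]
    }
    pid_out[[i]] <- rep(pid, k)
    start_out[[i]] <- starts
    stop_out[[i]] <- stops
    status_out[[i]] <- c(rep(0, k - 1L), status)
    cov_out[[i]] <- covm
  }
  res <- data.frame(pid = unlist(pid_out), start = unlist(start_out),
                    stop = unlist(stop_out), status = unlist(status_out))
  covall <- do.call(rbind, cov_out)
  for (v in vars) res[[v]] <- covall[, v]
  res
}
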