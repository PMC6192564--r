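#' Expand a counting-process table over baseline-hazard bins
#'
#' Splits each Andersen-Gill risk interval at the baseline-hazard bin
#' boundaries, producing the piecewise-exponential (Poisson) data
#' layout: one piece per (interval x bin) overlap, carrying its
#' exposure time and an event indicator on the piece that contains the
#' event time.  Total exposure and event counts are conserved exactly.
#'
#' @param tab counting-process data frame with columns `start`, `stop`,
#'   `status` (and anything else, carried through).
#' @param breaks increasing vector of bin boundaries covering the
#'   table's time range (`breaks[1] <= min(start)`,
#'   `max(stop) <= breaks[last]`); rows outside the range are an error.
#' @return data frame: the original columns (minus `start`, `stop`,
#'   `status`) plus `bin` (1-based), `tstart`, `tstop`, `exposure`
#'   (`tstop - tstart`) and event indicator `d`; attribute `"row"`
#'   maps each piece back to its source row.
#' @export
poisson_expand <- function(tab, breaks) {
  if (is.unsorted(breaks, strictly = TRUE)) stop("breaks must be increasing")
  if (nrow(tab) == 0L) {
    out <- tab[, setdiff(names(tab), c("start", "stop", "status")), drop = FALSE]
    out$bin <- integer(); out$tstart <- out$tstop <- out$exposure <- numeric()
    out$d <- integer()
    attr(out, "row") <- integer()
    return(out)
  }
  s <- tab$start; e <- tab$stop
  if (any(s < breaks[1] - 1e-9) || any(e > breaks[length(breaks)] + 1e-9)) {
    stop("interval outside bin range")
  }
  # bin of the piece just after s (right-open) and the bin containing e
  # (left-open), so boundaries never create zero-length pieces
  ks <- pmin(findInterval(s, breaks), length(breaks) - 1L)
  ke <- findInterval(e, breaks, left.open = TRUE)
  nper <- ke - ks + 1L
  row <- rep(seq_along(s), nper)
  binid <- ks[row] + sequence(nper) - 1L
  tstart <- pmax(s[row], breaks[binid])
  tstop <- pmin(e[row], breaks[binid + 1L])
  last <- binid == ke[row]
  keep <- setdiff(names(tab), c("start", "stop", "status"))
  out <- tab[row, keep, drop = FALSE]
  out$bin <- binid
  out$tstart <- tstart
  out$tstop <- tstop
  out$exposure <- tstop - tstart
  out$d <- as.integer(tab$status[row] * last)
  rownames(out) <- NULL
  attr(out, "row") <- row
  out
}
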