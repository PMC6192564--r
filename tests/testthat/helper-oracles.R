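# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths.

# Published CKD-EPI 2009 creatinine equation, written out directly.
oracle_ckdepi <- function(scr, age, female, black = FALSE) {
  k <- if (female) 0.7 else 0.9
  a <- if (female) -0.329 else -0.411
  v <- 141 * min(scr / k, 1)^a * max(scr / k, 1)^(-1.209) * 0.993^age
  if (female) v <- v * 1.018
  if (black) v <- v * 1.159
  v
}

# Hand product-limit estimator with delayed entry (one stratum).
oracle_km <- function(entry, exit, status) {
  times <- sort(unique(exit[status == 1]))
  s <- 1
  out <- numeric(length(times))
  for (i in seq_along(times)) {
    t <- times[i]
    y <- sum(entry < t & exit >= t)
    d <- sum(exit == t & status == 1)
    s <- s * (1 - d / y)
    out[i] <- s
  }
  data.frame(time = times, surv = out)
}

# Brute-force two-group log-rank O-E tabulation over event times.
oracle_logrank_2g <- function(entry, exit, status, group) {
  times <- sort(unique(exit[status == 1]))
  O1 <- E1 <- V <- 0
  for (t in times) {
    at <- entry < t & exit >= t
    y <- sum(at); y1 <- sum(at & group == 1)
    d <- sum(exit == t & status == 1)
    d1 <- sum(exit == t & status == 1 & group == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * y1 / y
    if (y > 1) V <- V + d * (y - d) / (y - 1) * (y1 / y) * (1 - y1 / y)
  }
  chisq <- (O1 - E1)^2 / V
  list(chisq = chisq, O1 = O1, E1 = E1)
}

# Daily brute-force accumulation of exposure per bin for one interval.
oracle_bin_exposure <- function(start, stop, breaks, step = 0.25) {
  grid <- seq(start, stop, by = step)
  mids <- head(grid, -1) + step / 2
  mids <- mids[mids < stop]
  tapply(rep(step, length(mids)),
         findInterval(mids, breaks, rightmost.closed = TRUE), sum)
}

# Random small counting-process dataset with optional delayed entry.
random_survdata <- function(n, truncated = TRUE) {
  entry <- if (truncated) round(runif(n, 0, 3), 1) else rep(0, n)
  # snap to one decimal so tied event times are exactly equal doubles
  exit <- round(entry + round(runif(n, 0.2, 6), 1), 1)
  data.frame(entry = entry, exit = exit, status = rbinom(n, 1, 0.6))
}

# Random valid counting-process table for conservation tests.
random_counting_table <- function(n_subj, tmax = 100) {
  rows <- lapply(seq_len(n_subj), function(i) {
    entry <- runif(1, 0, tmax / 2)
    exit <- entry + runif(1, 1, tmax / 2)
    ncut <- sample(0:3, 1)
    cuts <- sort(runif(ncut, entry, exit))
    starts <- c(entry, cuts); stops <- c(cuts, exit)
    data.frame(pid = i, start = starts, stop = stops,
               status = c(rep(0, ncut), rbinom(1, 1, 0.5)),
               x = round(runif(ncut + 1)))
  })
  do.call(rbind, rows)
}
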