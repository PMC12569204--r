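# Independent brute-force oracles, written against the definitions only --
# plain loops, no reuse of the package's staged implementation.

# Wrap a dF/F0 vector as a normalized trace for stage-level tests.
norm_from_dff <- function(dff, roi_id = "roi", dt = 1) {
  structure(list(roi_id = roi_id, dff = as.numeric(dff), f0 = 1,
                 sampling_interval = dt),
            class = "normalized_trace")
}

# Brute-force transient detector: enumerate every difference triple,
# filter by threshold, then group by scanning every inter-event gap.
oracle_detect <- function(raw, mad_multiplier = 2, floor = 0.1,
                          f0_pct = 0.05) {
  n <- length(raw)
  f0 <- as.numeric(quantile(raw, f0_pct, type = 7))
  dff <- (raw - f0) / f0
  med <- median(dff)
  mad0 <- median(abs(dff - med))
  thr <- max(mad_multiplier * mad0, floor)

  cands <- integer(0)
  for (t in seq_len(n)) {
    if (t < 2 || t > n - 2) next
    d1 <- dff[t] - dff[t - 1]
    d2 <- dff[t + 1] - dff[t]
    d3 <- dff[t + 2] - dff[t + 1]
    if (d1 > 0 && d2 <= 0 && d3 < 0) cands <- c(cands, t)
  }
  kept <- integer(0)
  for (t in cands) if (dff[t] > thr) kept <- c(kept, t)

  groups <- list()
  for (e in kept) {
    if (length(groups) == 0) {
      groups <- list(e)
    } else {
      g <- groups[[length(groups)]]
      prev <- g[length(g)]
      dips <- FALSE
      if (e - prev > 1) {
        for (j in (prev + 1):(e - 1)) if (dff[j] < thr) dips <- TRUE
      }
      if (dips) groups[[length(groups) + 1]] <- e
      else groups[[length(groups)]] <- c(g, e)
    }
  }
  events <- integer(0)
  for (g in groups) {
    best <- g[1]
    for (e in g) if (dff[e] > dff[best]) best <- e
    events <- c(events, best)
  }
  list(events = events, threshold = thr, dff = dff)
}

# Random positive trace: uniform noise around a baseline plus occasional
# injected bumps, for the detector-vs-oracle equivalence property.
random_bumpy_trace <- function(len, baseline = 10) {
  x <- baseline + runif(len, -0.5, 0.5)
  n_bumps <- sample(0:3, 1)
  for (b in seq_len(n_bumps)) {
    at <- sample(seq_len(len), 1)
    amp <- runif(1, 0.5, 6)
    span <- at:min(len, at + 4)
    x[span] <- x[span] + amp * exp(-(span - at) / 1.5)
  }
  pmax(x, 0.1)
}

# Analytic digestion oracle: surviving fraction under the sensitive digest.
oracle_survival <- function(m, cut_eff) m + (1 - m) * (1 - cut_eff)
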