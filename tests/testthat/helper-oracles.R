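## Independent oracles used by the tests. These deliberately re-derive
## results by brute force or closed form, with code paths separate from the
## package implementation.

# brute-force sliding-window hysteresis detector: enumerates every window
# with an explicit sum, walks the hysteresis by hand
bruteForceBursts <- function(counts, bin_width = 0.1, t_start = 0,
                             window = 0.5, on_rate = 8, off_rate = 4,
                             edge_method = "spikes",
                             class_threshold = 1.5) {
  wb <- round(window / bin_width)
  n <- length(counts)
  out <- data.frame(onset = numeric(0), offset = numeric(0),
                    duration = numeric(0), klass = character(0))
  if (n < wb) return(out)
  nw <- n - wb + 1
  wrate <- numeric(nw)
  for (i in 1:nw) {
    s <- 0
    for (j in i:(i + wb - 1)) s <- s + counts[j]
    wrate[i] <- s / window
  }
  i <- 1
  ons <- offs <- numeric(0)
  while (i <= nw) {
    if (wrate[i] > on_rate) {
      j <- i
      repeat {
        if (j + 1 > nw || wrate[j + 1] < off_rate) break
        j <- j + 1
      }
      if (edge_method == "window") {
        ons <- c(ons, t_start + (i - 1) * bin_width)
        offs <- c(offs, t_start + (j - 1) * bin_width + window)
      } else {
        lo <- i
        hi <- min(j + wb - 1, n)
        # first bin opening a run (>=2 spikes, or non-empty with non-empty
        # successor); last bin closing a run (>=2, or non-empty with
        # non-empty predecessor); all within the hysteresis span
        f <- NA
        for (k in lo:hi) {
          if (counts[k] >= 2 ||
              (counts[k] >= 1 && k + 1 <= n && k + 1 <= hi &&
               counts[k + 1] >= 1)) { f <- k; break }
        }
        l <- NA
        for (k in hi:lo) {
          if (counts[k] >= 2 ||
              (counts[k] >= 1 && k - 1 >= lo && counts[k - 1] >= 1)) {
            l <- k; break
          }
        }
        if (is.na(f) || is.na(l)) { f <- lo; l <- hi }
        ons <- c(ons, t_start + (f - 1) * bin_width)
        offs <- c(offs, t_start + l * bin_width)
      }
      i <- j + 2
    } else i <- i + 1
  }
  if (length(ons) > 1) {
    for (k in 1:(length(ons) - 1)) {
      if (offs[k] > ons[k + 1]) offs[k] <- ons[k + 1]
    }
  }
  dur <- offs - ons
  data.frame(onset = ons, offset = offs, duration = dur,
             klass = if (length(dur))
               ifelse(dur >= class_threshold, "long", "short")
             else character(0))
}

# brute-force two-sided Fisher p-value: direct products of binomial
# coefficients, no logs
bruteForceFisher <- function(tb) {
  a <- tb[1, 1]
  r1 <- sum(tb[1, ]); r2 <- sum(tb[2, ])
  c1 <- sum(tb[, 1]); n <- sum(tb)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  denom <- choose(n, c1)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / denom
  pobs <- choose(r1, a) * choose(r2, c1 - a) / denom
  sum(probs[probs <= pobs * (1 + 1e-9)])
}

# exhaustive integer-shift search maximizing overlap correlation
exhaustiveShift <- function(ref, img, max_shift = 6) {
  best <- c(0, 0); best_v <- -Inf
  d <- dim(ref)
  for (dx in -max_shift:max_shift) {
    for (dy in -max_shift:max_shift) {
      xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
      ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
      v <- sum(ref[xs - dx, ys - dy] * img[xs, ys])
      if (v > best_v) { best_v <- v; best <- c(dx, dy) }
    }
  }
  best
}

# analytic initial-slope oracle: least-squares slope of the closed-form
# waveform over its exact 20-80% falling segment, at fine resolution
analyticSlope <- function(stim_ms = 5, amplitude_mV = 0.3, tau_rise_ms = 2,
                          tau_decay_ms = 8, onset_delay_ms = 2,
                          frac = c(0.2, 0.8), dt = 1e-4) {
  t <- seq(0, 40, by = dt)
  v <- fepspWaveform(t, stim_ms, amplitude_mV, tau_rise_ms, tau_decay_ms,
                     onset_delay_ms)
  ipk <- which.min(v)
  peak <- v[ipk]
  i20 <- which(v[1:ipk] <= frac[1] * peak)[1]
  i80 <- which(v[1:ipk] <= frac[2] * peak)[1]
  idx <- i20:i80
  unname(coef(lm(v[idx] ~ t[idx]))[2])
}

# match detected events to true intervals by overlap; greedy in order
matchEvents <- function(events, truth) {
  nt <- nrow(truth)
  matched_true <- rep(NA_integer_, nt)
  matched_det <- rep(FALSE, nrow(events))
  for (i in seq_len(nt)) {
    ov <- which(!matched_det & events$onset < truth[i, 2] &
                  events$offset > truth[i, 1])
    if (length(ov)) {
      matched_true[i] <- ov[1]
      matched_det[ov[1]] <- TRUE
    }
  }
  list(matched_true = matched_true, matched_det = matched_det)
}

# quick constructor for binned counts
makeBinned <- function(counts, bin_width = 0.1, t_start = 0) {
  structure(list(counts = counts, bin_width = bin_width, t_start = t_start),
            class = "BinnedCounts")
}
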