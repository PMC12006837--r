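#' Detector configuration for CA3 epileptiform burst analysis
#'
#' Bundles all constants of the burst-detection chain. Defaults follow the
#' analysis conventions of the emulated study: 300--1000 Hz Butterworth
#' band-pass applied zero-phase, decimation by 10, spike threshold at
#' 5 x MAD, 100-ms bins, a 500-ms sliding window stepped by one bin, burst
#' onset when the window rate strictly exceeds 8 Hz, termination when it
#' falls strictly below 4 Hz, and a 1.5-s short/long classification boundary.
#'
#' @param band band-pass corner frequencies (Hz).
#' @param filter_order Butterworth order (applied forward-backward, so the
#'   effective order is doubled and the phase is zero).
#' @param downsample_factor integer decimation factor applied after
#'   filtering.
#' @param mad_factor spike threshold as a multiple of the MAD.
#' @param mad_constant scale constant of the MAD. The default 1.4826 makes
#'   the MAD a consistent estimator of the Gaussian noise SD (as in
#'   \code{stats::mad} and standard practice for extracellular spike
#'   thresholds), so the threshold sits at ~5 SD of the noise. Set to 1 for a
#'   raw, unscaled MAD.
#' @param bin_width spike-count bin width (s).
#' @param window sliding-window length (s); must be a multiple of
#'   \code{bin_width}.
#' @param on_rate window rate (Hz) that must be strictly exceeded to open a
#'   burst.
#' @param off_rate window rate (Hz) strictly below which a burst terminates;
#'   must be below \code{on_rate}.
#' @param class_threshold duration (s) at and above which an event is
#'   classified "long".
#' @param refractory spike-detection dead time (s) suppressing secondary
#'   threshold crossings within one spike waveform.
#' @param edge_method how event onset/offset are placed within the
#'   hysteresis span: \code{"spikes"} (default) refines boundaries to the
#'   first/last occupied bin run (a bin with >= 2 spikes, or two consecutive
#'   non-empty bins), which localizes the event to its spike support;
#'   \code{"window"} uses the raw window convention (onset = start of the
#'   first window above \code{on_rate}, offset = end of the last window at or
#'   above \code{off_rate}), which pads each edge by up to half a window.
#' @param analysis_span optional c(start, end) seconds restricting the
#'   analyzed span (e.g. 5--60 min after the baseline period).
#' @return A list of class \code{"DetectorConfig"}.
#' @examples
#' cfg <- detectorConfig()
#' cfg$on_rate
#' @export
detectorConfig <- function(band = c(300, 1000), filter_order = 4,
                           downsample_factor = 10, mad_factor = 5,
                           mad_constant = 1.4826, bin_width = 0.1,
                           window = 0.5, on_rate = 8, off_rate = 4,
                           class_threshold = 1.5, refractory = 0.002,
                           edge_method = c("spikes", "window"),
                           analysis_span = NULL) {
  edge_method <- match.arg(edge_method)
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1],
            filter_order >= 1, downsample_factor >= 1,
            mad_factor > 0, mad_constant > 0, bin_width > 0,
            window >= bin_width, class_threshold > 0, refractory >= 0)
  if (on_rate <= off_rate)
    stop("'on_rate' must exceed 'off_rate'")
  wb <- window / bin_width
  if (abs(wb - round(wb)) > 1e-9)
    stop("'window' must be an integer multiple of 'bin_width'")
  structure(list(band = band, filter_order = filter_order,
                 downsample_factor = as.integer(downsample_factor),
                 mad_factor = mad_factor, mad_constant = mad_constant,
                 bin_width = bin_width, window = window, on_rate = on_rate,
                 off_rate = off_rate, class_threshold = class_threshold,
                 refractory = refractory, edge_method = edge_method,
                 analysis_span = analysis_span),
            class = "DetectorConfig")
}

#' Band-pass filter and decimate an extracellular trace
#'
#' Applies the configured Butterworth band-pass forward and backward
#' (zero phase, so spike times are not skewed) and then decimates by the
#' configured factor. Because the pass-band upper edge lies below the
#' decimated Nyquist frequency, the band-pass itself serves as the
#' anti-aliasing filter.
#'
#' @param trace a \linkS4class{VoltageTrace}.
#' @param cfg a \code{\link{detectorConfig}}.
#' @return A \linkS4class{VoltageTrace} sampled at
#'   \code{fs / downsample_factor} with \code{ceiling(n / factor)} samples.
#' @examples
#' tr <- VoltageTrace(rnorm(25000), fs = 25000)
#' preprocessTrace(tr, detectorConfig())
#' @export
preprocessTrace <- function(trace, cfg = detectorConfig()) {
  stopifnot(is(trace, "VoltageTrace"))
  fs <- samplingRate(trace)
  fs_out <- fs / cfg$downsample_factor
  if (cfg$band[2] >= fs_out / 2)
    stop(sprintf(paste("band upper edge (%g Hz) is not below the Nyquist",
                       "frequency of the decimated trace (%g Hz); reduce",
                       "'downsample_factor' or the band"),
                 cfg$band[2], fs_out / 2))
  if (cfg$band[2] >= fs / 2)
    stop("band upper edge must be below the input Nyquist frequency")
  x <- samples(trace)
  bf <- signal::butter(cfg$filter_order, cfg$band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  y <- y[seq(1, length(y), by = cfg$downsample_factor)]
  VoltageTrace(y, fs = fs_out, t0 = startTime(trace))
}

#' Detect spikes by MAD thresholding of downward crossings
#'
#' The threshold is \code{mad_factor * mad(x, constant = mad_constant)}; a
#' spike is registered at each downward crossing of
#' \code{median(x) - threshold}, and subsequent crossings within the
#' refractory window are suppressed (extracellular spikes are
#' negative-dominant, so only negative-going crossings are counted).
#'
#' @param trace a preprocessed \linkS4class{VoltageTrace}.
#' @param cfg a \code{\link{detectorConfig}}.
#' @return Sorted numeric vector of spike times (s). A constant trace
#'   (MAD = 0) yields no spikes, with a warning about the degenerate
#'   threshold.
#' @examples
#' tr <- VoltageTrace(rnorm(5000), fs = 2500)
#' detectSpikes(tr, detectorConfig())
#' @export
detectSpikes <- function(trace, cfg = detectorConfig()) {
  stopifnot(is(trace, "VoltageTrace"))
  x <- samples(trace)
  if (length(x) < 2L) return(numeric(0))
  med <- median(x)
  thr <- cfg$mad_factor * mad(x, constant = cfg$mad_constant)
  if (thr == 0) {
    warning("degenerate spike threshold (MAD = 0); no spikes detected")
    return(numeric(0))
  }
  level <- med - thr
  idx <- which(x[-1L] < level & x[-length(x)] >= level) + 1L
  if (!length(idx)) return(numeric(0))
  fs <- samplingRate(trace)
  refr <- cfg$refractory * fs
  if (refr > 0 && length(idx) > 1L) {
    keep <- logical(length(idx))
    last <- -Inf
    for (k in seq_along(idx)) {
      if (idx[k] - last > refr) {
        keep[k] <- TRUE
        last <- idx[k]
      }
    }
    idx <- idx[keep]
  }
  startTime(trace) + (idx - 1L) / fs
}

#' Sum spike times into fixed-width bins
#'
#' Bins are half-open intervals \code{[t, t + bin_width)} so a spike exactly
#' on a bin edge is counted in the later bin.
#'
#' @param spikes sorted numeric vector of spike times (s).
#' @param span c(start, end) seconds to bin over; spikes outside are dropped.
#' @param cfg a \code{\link{detectorConfig}} (supplies \code{bin_width}).
#' @return A list of class \code{"BinnedCounts"} with \code{counts} (integer
#'   spikes per bin), \code{bin_width} and \code{t_start}.
#' @examples
#' binSpikes(c(0.05, 0.12, 0.13), span = c(0, 0.2))
#' @export
binSpikes <- function(spikes, span, cfg = detectorConfig()) {
  stopifnot(length(span) == 2, span[2] > span[1])
  bw <- cfg$bin_width
  n_bins <- floor((span[2] - span[1]) / bw + 1e-9)
  inb <- spikes >= span[1] & spikes < span[1] + n_bins * bw
  idx <- floor((spikes[inb] - span[1]) / bw) + 1L
  idx <- idx[idx >= 1L & idx <= n_bins]
  structure(list(counts = tabulate(idx, nbins = n_bins), bin_width = bw,
                 t_start = span[1]),
            class = "BinnedCounts")
}

#' Detect epileptiform bursts by sliding-window hysteresis
#'
#' A window of \code{window / bin_width} consecutive bins is stepped one bin
#' at a time across the binned counts. A burst opens at the first window
#' whose spike rate (window count / window length) strictly exceeds
#' \code{on_rate}; it persists through windows at or above \code{off_rate}
#' and terminates at the first window strictly below \code{off_rate} (or at
#' the end of the record). Event boundaries are then placed according to
#' \code{cfg$edge_method} (see \code{\link{detectorConfig}}). Events are
#' non-overlapping and ordered; each is classified short or long at
#' \code{class_threshold} (long iff duration >= threshold).
#'
#' @param binned a \code{"BinnedCounts"} object from \code{\link{binSpikes}}.
#' @param cfg a \code{\link{detectorConfig}}.
#' @return data.frame(onset, offset, duration, klass) with one row per
#'   event; zero rows if fewer bins than one window, or no window exceeds
#'   the onset rate.
#' @examples
#' b <- structure(list(counts = c(rep(0, 5), rep(2, 10), rep(0, 5)),
#'                     bin_width = 0.1, t_start = 0), class = "BinnedCounts")
#' detectBursts(b, detectorConfig(edge_method = "window"))
#' @export
detectBursts <- function(binned, cfg = detectorConfig()) {
  stopifnot(inherits(binned, "BinnedCounts"))
  counts <- binned$counts
  bw <- binned$bin_width
  wb <- as.integer(round(cfg$window / bw))
  n <- length(counts)
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0), klass = character(0))
  if (n < wb) return(empty)
  nw <- n - wb + 1L
  cs <- c(0, cumsum(counts))
  wsum <- cs[(wb + 1L):(n + 1L)] - cs[1:nw]
  rate <- wsum / cfg$window

  on_thr <- cfg$on_rate
  off_thr <- cfg$off_rate
  events <- list()
  i <- 1L
  while (i <= nw) {
    if (rate[i] > on_thr) {
      j <- i
      while (j < nw && rate[j + 1L] >= off_thr) j <- j + 1L
      # windows i..j are part of the burst (j = last window >= off_rate)
      events[[length(events) + 1L]] <- c(i, j)
      i <- j + 2L # skip the terminating window
    } else {
      i <- i + 1L
    }
  }
  if (!length(events)) return(empty)

  t0 <- binned$t_start
  res <- lapply(events, function(ev) {
    i_on <- ev[1]; i_last <- ev[2]
    if (cfg$edge_method == "window") {
      onset <- t0 + (i_on - 1L) * bw
      offset <- t0 + (i_last - 1L) * bw + cfg$window
    } else {
      span <- i_on:min(i_last + wb - 1L, n)
      occ <- occupiedBins(counts, span)
      onset <- t0 + (occ[1] - 1L) * bw
      offset <- t0 + occ[2] * bw
    }
    c(onset, offset)
  })
  onset <- vapply(res, `[`, 0, 1)
  offset <- vapply(res, `[`, 0, 2)
  # enforce non-overlap (possible when a new onset window directly follows a
  # terminating window): clip the earlier offset at the next onset
  if (length(onset) > 1L) {
    over <- which(offset[-length(offset)] > onset[-1L])
    offset[over] <- onset[over + 1L]
  }
  duration <- offset - onset
  data.frame(onset = onset, offset = offset, duration = duration,
             klass = ifelse(duration >= cfg$class_threshold, "long",
                            "short"))
}

# first/last "occupied" bin inside span: a bin with >= 2 spikes or two
# consecutive non-empty bins; a window above the onset rate always contains
# one (5 isolated singletons cannot reach > 8 Hz in 0.5 s)
occupiedBins <- function(counts, span) {
  cw <- counts[span]
  nb <- length(cw)
  nxt <- c(cw[-1L], 0)
  prv <- c(0, cw[-nb])
  ok_f <- cw >= 2 | (cw >= 1 & nxt >= 1)
  ok_l <- cw >= 2 | (cw >= 1 & prv >= 1)
  f <- which(ok_f)[1L]
  l <- which(ok_l)
  l <- l[length(l)]
  if (is.na(f) || !length(l)) {
    # fall back to the raw window span (degenerate, should not occur for
    # windows that satisfied the onset criterion)
    return(c(span[1L], span[length(span)]))
  }
  c(span[f], span[l])
}

#' Summarize detected burst events
#'
#' Counts events by class at the configured threshold (long iff duration >=
#' \code{class_threshold}), and reports mean +/- SEM duration over all events
#' and the event rate per analyzed minute.
#'
#' @param bursts data.frame from \code{\link{detectBursts}}.
#' @param analyzed_minutes length of the analyzed span in minutes.
#' @param cfg a \code{\link{detectorConfig}}.
#' @return list(n_short, n_long, n, mean_duration, sem_duration,
#'   burst_frequency). With no events the mean and SEM are \code{NA}.
#' @export
summarizeBursts <- function(bursts, analyzed_minutes,
                            cfg = detectorConfig()) {
  n <- nrow(bursts)
  n_long <- sum(bursts$duration >= cfg$class_threshold)
  ms <- if (n > 0) meanSem(bursts$duration) else list(mean = NA_real_,
                                                      sem = NA_real_)
  list(n_short = n - n_long, n_long = n_long, n = n,
       mean_duration = ms$mean, sem_duration = ms$sem,
       burst_frequency = n / analyzed_minutes)
}

#' Run the full burst-detection chain on a raw trace
#'
#' Convenience wrapper: \code{\link{preprocessTrace}} ->
#' \code{\link{detectSpikes}} -> \code{\link{binSpikes}} ->
#' \code{\link{detectBursts}} -> \code{\link{summarizeBursts}}.
#'
#' @param trace a raw \linkS4class{VoltageTrace}.
#' @param cfg a \code{\link{detectorConfig}}; its \code{analysis_span}
#'   (default: the full trace) delimits binning and summary.
#' @return list(events, summary, spikes, binned).
#' @export
detectBurstsFromTrace <- function(trace, cfg = detectorConfig()) {
  pre <- preprocessTrace(trace, cfg)
  spikes <- detectSpikes(pre, cfg)
  span <- cfg$analysis_span %||%
    c(startTime(trace),
      startTime(trace) + length(samples(trace)) / samplingRate(trace))
  binned <- binSpikes(spikes, span, cfg)
  events <- detectBursts(binned, cfg)
  list(events = events,
       summary = summarizeBursts(events, (span[2] - span[1]) / 60, cfg),
       spikes = spikes, binned = binned)
}
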