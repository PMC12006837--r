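#' Measure the initial slope of a field EPSP sweep
#'
#' The initial slope indexes synaptic strength. The stimulus artifact is
#' blanked for \code{blank_ms} after the stimulus; the peak negativity is
#' located within \code{search_ms}; the slope is the least-squares slope of
#' voltage against time over the samples between \code{frac[1]} and
#' \code{frac[2]} of the peak negativity on the initial falling phase
#' (conventionally 20--80\%). The sign is preserved (negative for an fEPSP).
#'
#' @param voltage numeric vector (mV) of one sweep.
#' @param time numeric vector of sample times (ms), uniform.
#' @param stim_ms stimulus time (ms).
#' @param blank_ms artifact blanking interval after the stimulus (ms).
#' @param frac c(low, high) fractions of peak negativity delimiting the fit.
#' @param search_ms window after blanking within which the peak is sought.
#' @param noise_mult deflection detection threshold: the peak must exceed
#'   \code{noise_mult} x the pre-stimulus SD, otherwise the sweep is flagged
#'   missing (returns \code{NA}).
#' @return Slope in mV/ms (negative for a downward fEPSP), or \code{NA} if
#'   no deflection beyond the noise floor is found.
#' @examples
#' t <- seq(0, 50, by = 0.1)
#' v <- fepspWaveform(t)
#' measureSlope(v, t, stim_ms = 5)
#' @export
measureSlope <- function(voltage, time, stim_ms, blank_ms = 1,
                         frac = c(0.2, 0.8), search_ms = 30,
                         noise_mult = 4) {
  stopifnot(length(voltage) == length(time), frac[1] >= 0,
            frac[2] > frac[1], frac[2] <= 1)
  pre <- time < stim_ms
  base <- if (any(pre)) mean(voltage[pre]) else 0
  noise <- if (sum(pre) > 2) sd(voltage[pre]) else 0
  t_on <- stim_ms + blank_ms
  seg <- which(time >= t_on & time <= t_on + search_ms)
  if (!length(seg)) stop("no samples after the blanking interval")
  ipk <- seg[which.min(voltage[seg])]
  peak_amp <- voltage[ipk] - base # negative
  if (-peak_amp <= noise_mult * noise)
    return(NA_real_)
  ## initial falling phase: from blank end to the peak
  fall <- seg[seg <= ipk]
  v20 <- base + frac[1] * peak_amp
  v80 <- base + frac[2] * peak_amp
  i20 <- fall[which(voltage[fall] <= v20)[1L]]
  i80 <- fall[which(voltage[fall] <= v80)[1L]]
  if (is.na(i20) || is.na(i80) || i80 <= i20)
    return(NA_real_)
  idx <- i20:i80
  unname(coef(lm(voltage[idx] ~ time[idx]))[2L])
}

#' Measure initial slopes for every sweep of a session
#'
#' @param sweeps a \linkS4class{SweepSeries}.
#' @param ... passed to \code{\link{measureSlope}}.
#' @return Numeric vector of slopes (mV/ms), one per sweep.
#' @export
measureSlopes <- function(sweeps, ...) {
  stopifnot(is(sweeps, "SweepSeries"))
  apply(sweeps@voltage, 2, measureSlope, time = sweeps@time,
        stim_ms = sweeps@stimTime, ...)
}

#' Normalize a slope series to its baseline
#'
#' Each slope is divided by the mean slope within the baseline window and
#' expressed in percent, so the baseline mean is 100\% by construction.
#' Normalizing an already-normalized series is the identity.
#'
#' @param slopes numeric vector of slopes.
#' @param timestamps sweep times in minutes.
#' @param baseline_window c(start, end) minutes, inclusive start, exclusive
#'   end (e.g. \code{c(20, 30)} for the last 10 min of a 30-min baseline).
#' @return data.frame(time_min, slope, normalized) with the baseline window
#'   attached as attribute \code{"baseline_window"}.
#' @export
normalizeSlopes <- function(slopes, timestamps, baseline_window) {
  stopifnot(length(slopes) == length(timestamps), length(baseline_window) == 2)
  ib <- timestamps >= baseline_window[1] & timestamps < baseline_window[2]
  if (!any(ib)) stop("empty baseline window")
  bmean <- mean(slopes[ib], na.rm = TRUE)
  if (!is.finite(bmean) || bmean == 0)
    stop("baseline mean slope is zero or undefined; cannot normalize")
  out <- data.frame(time_min = timestamps, slope = slopes,
                    normalized = slopes / bmean * 100)
  attr(out, "baseline_window") <- baseline_window
  out
}

#' Plasticity (LTD) magnitude from a normalized slope series
#'
#' Mean normalized slope over the post-induction window, reported as percent
#' of baseline (e.g. the average response 50--60 min after induction versus
#' the last 10 min of baseline).
#'
#' @param series data.frame from \code{\link{normalizeSlopes}}.
#' @param post_window c(start, end) minutes, inclusive.
#' @return list(magnitude = percent of baseline, window, n_sweeps).
#' @export
plasticityMagnitude <- function(series, post_window) {
  stopifnot(all(c("time_min", "normalized") %in% names(series)),
            length(post_window) == 2)
  iw <- series$time_min >= post_window[1] & series$time_min <= post_window[2]
  if (!any(iw)) stop("post window outside the recording")
  list(magnitude = mean(series$normalized[iw], na.rm = TRUE),
       window = post_window, n_sweeps = sum(iw))
}

#' Percent block of a pharmacologically isolated response
#'
#' @param control_mean mean response under control conditions (> 0).
#' @param drug_mean mean response in the drug.
#' @return \code{(1 - drug_mean / control_mean) * 100}.
#' @examples
#' percentBlock(100, 34) # 66
#' percentBlock(100, 53) # 47
#' @export
percentBlock <- function(control_mean, drug_mean) {
  if (any(control_mean <= 0)) stop("control mean must be > 0")
  (1 - drug_mean / control_mean) * 100
}
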