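#' VoltageTrace: a uniformly sampled extracellular voltage trace
#'
#' Container for a single extracellular recording, in microvolts, together
#' with its sampling rate and start time. This is the input carrier for the
#' burst-detection chain.
#'
#' @slot samples numeric vector of voltages (uV), finite.
#' @slot fs sampling rate in Hz (> 0).
#' @slot t0 time of the first sample in seconds.
#'
#' @seealso \code{\link{preprocessTrace}}, \code{\link{simulateTrace}}
#' @exportClass VoltageTrace
setClass("VoltageTrace",
  representation(samples = "numeric", fs = "numeric", t0 = "numeric"),
  prototype(samples = numeric(0), fs = 25000, t0 = 0)
)

setValidity("VoltageTrace", function(object) {
  msg <- character(0)
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "'t0' must be a single finite number")
  if (length(object@samples) && !all(is.finite(object@samples)))
    msg <- c(msg, "'samples' must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a VoltageTrace
#'
#' @param samples numeric vector of voltages in uV.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds (default 0).
#' @return A \linkS4class{VoltageTrace} object.
#' @examples
#' tr <- VoltageTrace(rnorm(2500), fs = 2500)
#' samplingRate(tr)
#' @export
VoltageTrace <- function(samples, fs, t0 = 0) {
  new("VoltageTrace", samples = as.numeric(samples), fs = as.numeric(fs),
      t0 = as.numeric(t0))
}

#' SweepSeries: per-stimulus fEPSP sweeps
#'
#' Holds one voltage sweep per stimulus as columns of a matrix, with a common
#' time base (ms), the stimulus time within each sweep, and the experiment
#' time of each sweep in minutes.
#'
#' @slot voltage numeric matrix, rows = time samples, columns = sweeps (mV).
#' @slot time numeric vector of within-sweep sample times (ms).
#' @slot stimTime stimulus time within a sweep (ms).
#' @slot timestamps experiment time of each sweep (minutes), ascending.
#'
#' @seealso \code{\link{measureSlope}}, \code{\link{simulateFepspSession}}
#' @exportClass SweepSeries
setClass("SweepSeries",
  representation(voltage = "matrix", time = "numeric", stimTime = "numeric",
                 timestamps = "numeric")
)

setValidity("SweepSeries", function(object) {
  msg <- character(0)
  if (nrow(object@voltage) != length(object@time))
    msg <- c(msg, "nrow(voltage) must equal length(time)")
  if (ncol(object@voltage) != length(object@timestamps))
    msg <- c(msg, "ncol(voltage) must equal length(timestamps)")
  if (length(object@time) > 1L) {
    dt <- diff(object@time)
    if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt))
      msg <- c(msg, "'time' must be uniformly increasing")
  }
  if (length(object@stimTime) != 1L ||
      object@stimTime < min(object@time) || object@stimTime > max(object@time))
    msg <- c(msg, "'stimTime' must lie inside the sweep time base")
  if (is.unsorted(object@timestamps))
    msg <- c(msg, "'timestamps' must be ascending")
  if (length(msg)) msg else TRUE
})

#' Construct a SweepSeries
#'
#' @param voltage matrix of voltages (mV), time samples x sweeps.
#' @param time within-sweep time base in ms.
#' @param stimTime stimulus time within each sweep (ms).
#' @param timestamps experiment time of each sweep in minutes.
#' @return A \linkS4class{SweepSeries} object.
#' @export
SweepSeries <- function(voltage, time, stimTime, timestamps) {
  new("SweepSeries", voltage = as.matrix(voltage), time = as.numeric(time),
      stimTime = as.numeric(stimTime), timestamps = as.numeric(timestamps))
}

#' StackSeries: time-lapse fluorescence z-series
#'
#' An ordered list of 3-D intensity arrays (x, y, z), one per imaging
#' timepoint, with acquisition timestamps in minutes. All stacks must share
#' one frame shape.
#'
#' @slot stacks list of 3-D numeric arrays.
#' @slot timestamps acquisition times in minutes, ascending.
#' @slot pixelSize nominal pixel size in um (metadata only).
#' @slot zStep nominal z step in um (metadata only).
#'
#' @seealso \code{\link{projectZSeries}}, \code{\link{simulateSpineStacks}}
#' @exportClass StackSeries
setClass("StackSeries",
  representation(stacks = "list", timestamps = "numeric",
                 pixelSize = "numeric", zStep = "numeric"),
  prototype(pixelSize = 0.1, zStep = 1)
)

setValidity("StackSeries", function(object) {
  msg <- character(0)
  if (length(object@stacks) != length(object@timestamps))
    msg <- c(msg, "one timestamp per stack required")
  if (is.unsorted(object@timestamps))
    msg <- c(msg, "'timestamps' must be ascending")
  dims <- lapply(object@stacks, dim)
  if (length(dims)) {
    if (any(vapply(dims, length, 1L) != 3L))
      msg <- c(msg, "each stack must be a 3-D array")
    else if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
      msg <- c(msg, "all stacks must share one frame shape")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StackSeries
#'
#' @param stacks list of 3-D numeric arrays (x, y, z).
#' @param timestamps acquisition times in minutes.
#' @param pixelSize nominal pixel size in um.
#' @param zStep nominal z step in um.
#' @return A \linkS4class{StackSeries} object.
#' @export
StackSeries <- function(stacks, timestamps, pixelSize = 0.1, zStep = 1) {
  new("StackSeries", stacks = stacks, timestamps = as.numeric(timestamps),
      pixelSize = pixelSize, zStep = zStep)
}

## ------------------------------------------------------------------ generics

#' Accessors for spineburst data classes
#'
#' \code{samples} returns the raw sample vector of a trace;
#' \code{samplingRate} its sampling rate (Hz); \code{startTime} its start
#' time (s); \code{timeStamps} the per-timepoint/per-sweep experiment times
#' (minutes); \code{nTimepoints} the number of timepoints/sweeps.
#'
#' @param x a \linkS4class{VoltageTrace}, \linkS4class{SweepSeries} or
#'   \linkS4class{StackSeries}.
#' @return An atomic vector (see details per generic).
#' @name accessors
#' @aliases samples samplingRate startTime timeStamps nTimepoints
#' @examples
#' tr <- VoltageTrace(rnorm(100), fs = 1000)
#' samplingRate(tr)
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))
#' @rdname accessors
#' @export
setGeneric("timeStamps", function(x) standardGeneric("timeStamps"))
#' @rdname accessors
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname accessors
setMethod("samples", "VoltageTrace", function(x) x@samples)
#' @rdname accessors
setMethod("samplingRate", "VoltageTrace", function(x) x@fs)
#' @rdname accessors
setMethod("startTime", "VoltageTrace", function(x) x@t0)
#' @rdname accessors
setMethod("timeStamps", "SweepSeries", function(x) x@timestamps)
#' @rdname accessors
setMethod("timeStamps", "StackSeries", function(x) x@timestamps)
#' @rdname accessors
setMethod("nTimepoints", "SweepSeries", function(x) ncol(x@voltage))
#' @rdname accessors
setMethod("nTimepoints", "StackSeries", function(x) length(x@stacks))

setMethod("show", "VoltageTrace", function(object) {
  n <- length(object@samples)
  cat("VoltageTrace:", n, "samples @", object@fs, "Hz (",
      sprintf("%.2f", n / object@fs), "s ), t0 =", object@t0, "s\n")
})

setMethod("show", "SweepSeries", function(object) {
  cat("SweepSeries:", ncol(object@voltage), "sweeps x",
      nrow(object@voltage), "samples, stim at", object@stimTime, "ms,",
      "span", sprintf("%.1f-%.1f", min(object@timestamps),
                      max(object@timestamps)), "min\n")
})

setMethod("show", "StackSeries", function(object) {
  d <- if (length(object@stacks)) dim(object@stacks[[1L]]) else c(0, 0, 0)
  cat("StackSeries:", length(object@stacks), "timepoints of",
      paste(d, collapse = " x "), "voxels,",
      "t =", paste(range(object@timestamps), collapse = "-"), "min\n")
})
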