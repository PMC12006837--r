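#' Project a z-series to a single image
#'
#' Maximum-intensity projection over z (default), or a sum projection. The
#' max projection is the default because it is what spine-tracking pipelines
#' conventionally use; the sum projection is offered as an alternative
#' reading of "maximal intensity ... summed" acquisition notes.
#'
#' @param stack 3-D numeric array (x, y, z).
#' @param method "max" or "sum".
#' @return 2-D numeric matrix.
#' @examples
#' st <- array(0, c(4, 4, 2)); st[2, 3, 2] <- 7
#' projectZSeries(st)[2, 3]
#' @export
projectZSeries <- function(stack, method = c("max", "sum")) {
  method <- match.arg(method)
  d <- dim(stack)
  if (is.null(d) || length(d) != 3L || any(d == 0))
    stop("'stack' must be a non-empty 3-D array")
  if (method == "max") apply(stack, c(1, 2), max) else
    apply(stack, c(1, 2), sum)
}

# integer-shift translate with zero fill (2-D)
translateImage <- function(img, dx, dy) {
  if (dx == 0 && dy == 0) return(img)
  d <- dim(img)
  out <- matrix(0, d[1], d[2])
  sx <- intersect(seq_len(d[1]), seq_len(d[1]) + dx)
  sy <- intersect(seq_len(d[2]), seq_len(d[2]) + dy)
  out[sx, sy] <- img[sx - dx, sy - dy, drop = FALSE]
  out
}

# integer-pixel shift (dx, dy) maximizing the circular cross-correlation of
# img against ref, restricted to |shift| <= max_shift
xcorrShift <- function(ref, img, max_shift) {
  d <- dim(ref)
  cc <- Re(stats::fft(stats::fft(img) * Conj(stats::fft(ref)),
                      inverse = TRUE))
  sx <- c(0:max_shift, -(max_shift:1))
  ix <- ((sx) %% d[1]) + 1L
  iy <- ((sx) %% d[2]) + 1L
  sub <- cc[ix, iy, drop = FALSE]
  k <- arrayInd(which.max(sub), dim(sub))
  c(dx = sx[k[1]], dy = sx[k[2]])
}

#' Register a series of images by integer-pixel translation
#'
#' Each image is aligned onto the first by maximizing the FFT
#' cross-correlation over integer shifts up to \code{max_shift}; aligned
#' images are zero-padded outside the overlap. Registering already aligned
#' images yields zero shifts.
#'
#' @param images list of 2-D matrices of identical shape.
#' @param max_shift largest shift magnitude searched (px).
#' @return list(aligned = list of matrices, shifts = n x 2 integer matrix of
#'   the estimated (dx, dy) displacement of each image relative to the
#'   first).
#' @examples
#' im <- matrix(0, 32, 32); im[10:12, 20:22] <- 5
#' sh <- spineburst:::translateImage(im, 3, -2)
#' registerSeries(list(im, sh))$shifts
#' @export
registerSeries <- function(images, max_shift = 15) {
  stopifnot(is.list(images), length(images) >= 1)
  d <- dim(images[[1L]])
  if (any(vapply(images, function(i) !identical(dim(i), d), TRUE)))
    stop("all images must share one shape")
  ref <- images[[1L]]
  if (all(ref == 0))
    warning("reference image is all zero; shifts default to zero")
  n <- length(images)
  shifts <- matrix(0L, n, 2, dimnames = list(NULL, c("dx", "dy")))
  aligned <- vector("list", n)
  aligned[[1L]] <- ref
  for (k in seq_len(n)[-1L]) {
    img <- images[[k]]
    if (all(ref == 0)) {
      s <- c(0L, 0L) # already warned once for the reference
    } else if (all(img == 0)) {
      warning("all-zero image at position ", k, "; zero shift assumed")
      s <- c(0L, 0L)
    } else {
      s <- xcorrShift(ref, img, max_shift)
    }
    shifts[k, ] <- s
    aligned[[k]] <- translateImage(img, -s[1], -s[2])
  }
  list(aligned = aligned, shifts = shifts)
}

# sum of a size x size ROI centered at (cx, cy); errors if outside the frame
roiSum <- function(img, cx, cy, size) {
  h <- size %/% 2L
  xs <- (cx - h + 1L):(cx + h)
  ys <- (cy - h + 1L):(cy + h)
  if (min(xs) < 1L || min(ys) < 1L || max(xs) > nrow(img) ||
      max(ys) > ncol(img))
    stop("ROI extends outside the frame")
  sum(img[xs, ys])
}

#' Integrate spine ROIs with background and reference correction
#'
#' Per timepoint and ROI, the raw value is the integrated intensity over a
#' \code{roi_size} x \code{roi_size} square. The per-pixel background
#' \eqn{b(t)} is the mean over the background ROIs divided by the ROI area;
#' every ROI is corrected as \code{raw - area * b(t)}. Global fluorescence
#' fluctuations (bleaching, excitation drift) are then cancelled by the
#' reference factor \eqn{g(t)}: the mean over the reference ROIs of their
#' corrected intensity relative to their own baseline mean. Spine values are
#' divided by \eqn{g(t)} and finally expressed as percent of their baseline
#' mean, which is 100\% by construction.
#'
#' @param images list of registered 2-D images (one per timepoint).
#' @param rois data.frame(role, cx, cy) with roles "spine", "background"
#'   (exactly 3) and "reference" (exactly 4).
#' @param baseline_timepoints integer indices of the baseline timepoints.
#' @param roi_size ROI side length in pixels.
#' @return Object of class \code{"SpineTraces"}: list with matrices
#'   \code{raw}, \code{corrected}, \code{normalized} (timepoints x spines),
#'   vectors \code{b} and \code{g}, logical \code{valid} (FALSE where
#'   g(t) <= 0) and the baseline indices.
#' @export
measureRoiSeries <- function(images, rois, baseline_timepoints,
                             roi_size = 20) {
  stopifnot(is.list(images), all(c("role", "cx", "cy") %in% names(rois)))
  rois$role <- as.character(rois$role)
  n_bg <- sum(rois$role == "background")
  n_ref <- sum(rois$role == "reference")
  if (n_bg != 3L) stop("exactly 3 background ROIs are required")
  if (n_ref != 4L) stop("exactly 4 reference ROIs are required")
  if (!any(rois$role == "spine")) stop("at least one spine ROI is required")
  nt <- length(images)
  if (!all(baseline_timepoints %in% seq_len(nt)))
    stop("baseline timepoints outside the series")
  area <- roi_size^2

  sums <- sapply(seq_len(nrow(rois)), function(r)
    vapply(images, roiSum, 0, cx = rois$cx[r], cy = rois$cy[r],
           size = roi_size))
  sums <- matrix(sums, nrow = nt)
  b <- rowMeans(sums[, rois$role == "background", drop = FALSE]) / area
  corr_all <- sums - area * b
  ref <- corr_all[, rois$role == "reference", drop = FALSE]
  ref_base <- colMeans(ref[baseline_timepoints, , drop = FALSE])
  if (any(ref_base <= 0))
    stop("non-positive baseline reference intensity")
  g <- rowMeans(sweep(ref, 2, ref_base, "/"))
  valid <- g > 0

  raw <- sums[, rois$role == "spine", drop = FALSE]
  spine <- corr_all[, rois$role == "spine", drop = FALSE]
  corrected <- sweep(spine, 1, g, "/")
  corrected[!valid, ] <- NA_real_
  base_mean <- colMeans(corrected[baseline_timepoints, , drop = FALSE])
  normalized <- sweep(corrected, 2, base_mean, "/") * 100
  structure(list(raw = raw, corrected = corrected,
                 normalized = normalized, b = b, g = g, valid = valid,
                 baseline_timepoints = baseline_timepoints),
            class = "SpineTraces")
}

#' Baseline drift quality control
#'
#' Fits an ordinary least-squares line to the normalized baseline values and
#' reports the drift as the absolute fitted change over the baseline,
#' relative to the mean fitted level, in percent. Sessions with drift above
#' the threshold fail QC and are excluded from group summaries.
#'
#' @param values normalized trace values (percent of baseline).
#' @param timestamps timepoint times in minutes (same length).
#' @param baseline_min baseline length in minutes; timepoints with
#'   \code{timestamps < baseline_min} form the baseline.
#' @param threshold maximum tolerated drift percent (default 7).
#' @return list(drift_percent, passed, slope, intercept, n_baseline).
#'   With fewer than 3 baseline points the QC is undefined:
#'   \code{drift_percent} is \code{NA}, \code{passed} is \code{NA}, with a
#'   warning.
#' @examples
#' driftQC(c(100, 102, 104, 106, 108, 110, 112, 114),
#'         timestamps = seq(0, 28, by = 4), baseline_min = 30)
#' @export
driftQC <- function(values, timestamps, baseline_min = 30, threshold = 7) {
  stopifnot(length(values) == length(timestamps))
  ib <- which(timestamps < baseline_min)
  if (length(ib) < 3L) {
    warning("fewer than 3 baseline timepoints; drift QC undefined")
    return(list(drift_percent = NA_real_, passed = NA, slope = NA_real_,
                intercept = NA_real_, n_baseline = length(ib)))
  }
  t <- timestamps[ib]; y <- values[ib]
  fit <- lm(y ~ t)
  co <- coef(fit)
  fitted_ends <- co[1] + co[2] * range(t)
  drift <- abs(diff(fitted_ends)) / mean(co[1] + co[2] * t) * 100
  list(drift_percent = unname(drift), passed = unname(drift <= threshold),
       slope = unname(co[2]), intercept = unname(co[1]),
       n_baseline = length(ib))
}

#' Summarize spine shrinkage across spines and experiments
#'
#' Per spine: mean normalized volume within the analysis window. Per
#' experiment: mean across its spines. Group value: mean +/- SEM across
#' experiments (N = experiments/animals).
#'
#' @param traces list with one element per experiment; each element is a
#'   matrix of normalized values (timepoints x spines) or a
#'   \code{"SpineTraces"} object.
#' @param timestamps timepoint times in minutes (shared across experiments).
#' @param window c(start, end) minutes of the analysis window (inclusive).
#' @return list(mean, sem, n, per_experiment).
#' @export
summarizeShrinkage <- function(traces, timestamps, window) {
  stopifnot(length(window) == 2, window[2] >= window[1])
  iw <- which(timestamps >= window[1] & timestamps <= window[2])
  if (!length(iw)) stop("empty analysis window")
  per_exp <- vapply(traces, function(tr) {
    m <- if (inherits(tr, "SpineTraces")) tr$normalized else as.matrix(tr)
    mean(colMeans(m[iw, , drop = FALSE], na.rm = TRUE))
  }, 0)
  ms <- meanSem(per_exp)
  list(mean = ms$mean, sem = ms$sem, n = ms$n, per_experiment = per_exp)
}

#' Spine density per unit dendrite length
#'
#' @param spine_count number of spines counted.
#' @param dendrite_length_um dendrite length in um (> 0).
#' @param unit_length_um reporting unit (default: per 10 um).
#' @return Density in spines per \code{unit_length_um}.
#' @examples
#' spineDensity(23, 50) # 4.6 per 10 um
#' @export
spineDensity <- function(spine_count, dendrite_length_um,
                         unit_length_um = 10) {
  if (any(dendrite_length_um <= 0)) stop("dendrite length must be > 0")
  spine_count / dendrite_length_um * unit_length_um
}

#' Quantify a spine imaging session from stacks to normalized traces
#'
#' Convenience wrapper: project each timepoint, register the projections,
#' integrate the ROIs and run baseline drift QC per spine.
#'
#' @param series a \linkS4class{StackSeries}.
#' @param rois data.frame(role, cx, cy).
#' @param baseline_min baseline length in minutes.
#' @param roi_size ROI side length (px).
#' @param method projection method ("max" or "sum").
#' @param max_shift registration search radius (px).
#' @param drift_threshold QC threshold in percent.
#' @return list(traces = "SpineTraces", shifts, qc = per-spine drift QC
#'   list, projections).
#' @export
quantifySpineSeries <- function(series, rois, baseline_min = 30,
                                roi_size = 20, method = "max",
                                max_shift = 15, drift_threshold = 7) {
  stopifnot(is(series, "StackSeries"))
  proj <- lapply(series@stacks, projectZSeries, method = method)
  reg <- registerSeries(proj, max_shift = max_shift)
  ts <- timeStamps(series)
  baseline_timepoints <- which(ts < baseline_min)
  traces <- measureRoiSeries(reg$aligned, rois, baseline_timepoints,
                             roi_size = roi_size)
  qc <- apply(traces$normalized, 2, driftQC, timestamps = ts,
              baseline_min = baseline_min, threshold = drift_threshold)
  list(traces = traces, shifts = reg$shifts, qc = qc, projections = proj)
}
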