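## Readers and writers for the standard on-disk forms: traces and sweeps as
## CSV, stack series as multi-page TIFF (one file per timepoint, slice order
## = z) with a JSON sidecar, ground truth as JSON, tables as CSV.

#' Write / read a voltage trace as CSV (time_s, voltage_uV)
#'
#' @param trace a \linkS4class{VoltageTrace}.
#' @param path output CSV path.
#' @return \code{writeTraceCsv}: the path, invisibly. \code{readTraceCsv}: a
#'   \linkS4class{VoltageTrace} (the sampling rate is inferred from the time
#'   column unless given).
#' @export
writeTraceCsv <- function(trace, path) {
  stopifnot(is(trace, "VoltageTrace"))
  n <- length(samples(trace))
  dt <- data.table::data.table(
    time_s = startTime(trace) + (seq_len(n) - 1) / samplingRate(trace),
    voltage_uV = samples(trace))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname writeTraceCsv
#' @param fs sampling rate in Hz; if \code{NULL}, inferred from the first
#'   two time stamps.
#' @export
readTraceCsv <- function(path, fs = NULL) {
  dt <- data.table::fread(path)
  stopifnot(all(c("time_s", "voltage_uV") %in% names(dt)))
  if (is.null(fs)) {
    if (nrow(dt) < 2L) stop("cannot infer fs from a single sample")
    fs <- 1 / (dt$time_s[2L] - dt$time_s[1L])
  }
  VoltageTrace(dt$voltage_uV, fs = fs, t0 = dt$time_s[1L])
}

#' Write / read a stack series as multi-page TIFFs plus a JSON sidecar
#'
#' One 32-bit TIFF per timepoint (pages = z slices). TIFF stores intensities
#' scaled into [0, 1]; the scale factor is recorded in the sidecar and
#' restored on read.
#'
#' @param series a \linkS4class{StackSeries}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return \code{writeStackSeries}: the directory, invisibly;
#'   \code{readStackSeries}: a \linkS4class{StackSeries}.
#' @export
writeStackSeries <- function(series, dir, prefix = "tp") {
  stopifnot(is(series, "StackSeries"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gain <- max(1e-12, max(vapply(series@stacks, max, 0)))
  files <- character(nTimepoints(series))
  for (t in seq_len(nTimepoints(series))) {
    st <- series@stacks[[t]] / gain
    pages <- lapply(seq_len(dim(st)[3]), function(z)
      t(st[, , z])) # TIFF rows = y
    files[t] <- file.path(dir, sprintf("%s_%03d.tif", prefix, t))
    tiff::writeTIFF(pages, files[t], bits.per.sample = 32L)
  }
  meta <- list(timestamps = timeStamps(series), gain = gain,
               pixel_um = series@pixelSize, z_um = series@zStep,
               files = basename(files))
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeStackSeries
#' @export
readStackSeries <- function(dir, prefix = "tp") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_meta.json")),
                              simplifyVector = TRUE)
  stacks <- lapply(meta$files, function(f) {
    pages <- tiff::readTIFF(file.path(dir, f), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(ncol(pages[[1L]]), nrow(pages[[1L]]), length(pages)))
    for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]])
    arr * meta$gain
  })
  StackSeries(stacks, timestamps = meta$timestamps,
              pixelSize = meta$pixel_um, zStep = meta$z_um)
}

#' Write / read fEPSP sweeps as long-format CSV
#'
#' Columns: sweep_id, sweep_min, time_ms, voltage_mV; the stimulus time is
#' stored in a constant stim_ms column.
#'
#' @param sweeps a \linkS4class{SweepSeries}.
#' @param path CSV path.
#' @return \code{writeSweepsCsv}: the path, invisibly; \code{readSweepsCsv}:
#'   a \linkS4class{SweepSeries}.
#' @export
writeSweepsCsv <- function(sweeps, path) {
  stopifnot(is(sweeps, "SweepSeries"))
  ns <- nTimepoints(sweeps); nt <- length(sweeps@time)
  dt <- data.table::data.table(
    sweep_id = rep(seq_len(ns), each = nt),
    sweep_min = rep(timeStamps(sweeps), each = nt),
    time_ms = rep(sweeps@time, ns),
    voltage_mV = as.vector(sweeps@voltage),
    stim_ms = sweeps@stimTime)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname writeSweepsCsv
#' @export
readSweepsCsv <- function(path) {
  dt <- data.table::fread(path)
  need <- c("sweep_id", "sweep_min", "time_ms", "voltage_mV", "stim_ms")
  stopifnot(all(need %in% names(dt)))
  ids <- unique(dt$sweep_id)
  tms <- dt$time_ms[dt$sweep_id == ids[1L]]
  v <- matrix(dt$voltage_mV, nrow = length(tms))
  ts <- dt$sweep_min[match(ids, dt$sweep_id)]
  SweepSeries(v, time = tms, stimTime = dt$stim_ms[1L], timestamps = ts)
}

#' Read an ROI annotation table (role, cx, cy)
#'
#' @param path CSV with columns role, cx, cy; roles must be "spine",
#'   "background" or "reference".
#' @return data.frame(role, cx, cy).
#' @export
readRoiCsv <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  stopifnot(all(c("role", "cx", "cy") %in% names(df)))
  bad <- setdiff(unique(df$role), c("spine", "background", "reference"))
  if (length(bad)) stop("unknown ROI role(s): ", paste(bad, collapse = ", "))
  df
}

#' Write a ground-truth record as a JSON sidecar
#'
#' @param truth list as returned in the \code{truth} element of the
#'   generators.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}
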