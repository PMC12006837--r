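## End-to-end reproducible runs: a single config (R list or YAML file) with
## per-stage parameter blocks, a seed, and an output directory. Unknown
## config keys are rejected; outputs are checksummed into a manifest so a
## rerun with the same config and seed is byte-identical.

stageNames <- c("trace", "spines", "fepsp", "labeling", "ags")

allowedKeys <- function() {
  list(
    top = c("seed", "out_dir", "stages"),
    trace = c(names(formals(simulateTrace)), "detector"),
    detector = names(formals(detectorConfig)),
    spines = c(names(formals(simulateSpineStacks)), "baseline_min",
               "roi_size", "projection", "max_shift", "drift_threshold",
               "analysis_window"),
    fepsp = c(names(formals(simulateFepspSession)), "baseline_window",
              "post_window"),
    labeling = c(names(formals(simulateLabeling)), "anchor_group"),
    ags = names(formals(simulateAgsCohort))
  )
}

checkKeys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown))
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
  invisible(TRUE)
}

#' Validate a pipeline run configuration
#'
#' Rejects unknown keys at every level and applies the same parameter checks
#' the stage functions apply (e.g. a detector block with
#' \code{on_rate <= off_rate} is rejected here, before anything runs).
#'
#' @param config nested list (or path to a YAML file) with elements
#'   \code{seed}, \code{out_dir} and \code{stages}; \code{stages} may contain
#'   blocks \code{trace} (with optional \code{detector} sub-block),
#'   \code{spines}, \code{fepsp}, \code{labeling} and \code{ags}.
#' @return The parsed, validated config list, invisibly.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  ak <- allowedKeys()
  checkKeys(config, ak$top, "config")
  stages <- config$stages %||% list()
  unknown <- setdiff(names(stages), stageNames)
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  for (s in names(stages)) {
    block <- stages[[s]] %||% list()
    checkKeys(block, ak[[s]], paste0("stages$", s))
    if (s == "trace" && !is.null(block$detector)) {
      checkKeys(block$detector, ak$detector, "stages$trace$detector")
      do.call(detectorConfig, block$detector) # parameter sanity
    }
  }
  invisible(config)
}

md5 <- function(paths) {
  h <- tools::md5sum(paths)
  names(h) <- basename(names(h))
  as.list(h)
}

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run the configured pipeline stages and write a checksummed manifest
#'
#' Stages are executed in a fixed order (trace -> spines -> fepsp ->
#' labeling -> ags; only those present in the config). Each stage simulates
#' its input with a seed derived from the run seed, runs the corresponding
#' analysis, and writes its outputs into \code{out_dir}. The manifest records
#' the package version, seed, config hash and the MD5 checksum of every
#' output file; rerunning with an identical config and seed reproduces
#' identical checksums.
#'
#' @param config see \code{\link{validateRunConfig}}; \code{out_dir} may also
#'   be supplied here.
#' @param out_dir output directory (overrides the config entry).
#' @return The manifest list, invisibly. A \code{manifest.json} is written
#'   into \code{out_dir}.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  config <- validateRunConfig(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  stages <- config$stages %||% list()

  cfg_path <- file.path(out_dir, "config.json")
  # the hash covers the scientific configuration, not the output location
  writeJson(config[setdiff(names(config), "out_dir")], cfg_path)
  manifest <- list(package = "spineburst",
                   version = as.character(packageVersion("spineburst")),
                   seed = seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   stages = list())

  runners <- list(trace = runTraceStage, spines = runSpinesStage,
                  fepsp = runFepspStage, labeling = runLabelingStage,
                  ags = runAgsStage)
  offsets <- c(trace = 101L, spines = 202L, fepsp = 303L, labeling = 404L,
               ags = 505L)
  for (s in intersect(stageNames, names(stages))) {
    res <- tryCatch(
      runners[[s]](stages[[s]] %||% list(), out_dir,
                   seed = seed + offsets[[s]]),
      error = function(e) stop("stage '", s, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    manifest$stages[[s]] <- res
  }
  writeJson(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

runTraceStage <- function(block, out_dir, seed) {
  det <- block$detector
  block$detector <- NULL
  block$seed <- block$seed %||% seed
  sim <- do.call(simulateTrace, block)
  cfg <- do.call(detectorConfig, det %||% list())
  res <- detectBurstsFromTrace(sim$trace, cfg)
  f_trace <- file.path(out_dir, "trace.csv")
  f_truth <- file.path(out_dir, "trace_truth.json")
  f_events <- file.path(out_dir, "events.csv")
  f_sum <- file.path(out_dir, "burst_summary.json")
  writeTraceCsv(sim$trace, f_trace)
  writeGroundTruth(sim$truth, f_truth)
  data.table::fwrite(res$events, f_events)
  writeJson(res$summary, f_sum)
  list(n_spikes = length(res$spikes), n_events = nrow(res$events),
       files = md5(c(f_trace, f_truth, f_events, f_sum)))
}

runSpinesStage <- function(block, out_dir, seed) {
  qargs <- block[intersect(names(block),
                           c("baseline_min", "roi_size", "max_shift",
                             "drift_threshold"))]
  win <- block$analysis_window %||% c(80, 90)
  proj <- block$projection %||% "max"
  block <- block[setdiff(names(block),
                         c("baseline_min", "roi_size", "projection",
                           "max_shift", "drift_threshold",
                           "analysis_window"))]
  block$seed <- block$seed %||% seed
  sim <- do.call(simulateSpineStacks, block)
  q <- do.call(quantifySpineSeries,
               c(list(series = sim$series, rois = sim$truth$rois,
                      method = proj), qargs))
  ts <- timeStamps(sim$series)
  passed <- vapply(q$qc, function(x) isTRUE(x$passed), TRUE)
  shr <- summarizeShrinkage(
    list(q$traces$normalized[, passed, drop = FALSE]), ts, win)
  sdir <- file.path(out_dir, "stacks")
  writeStackSeries(sim$series, sdir)
  f_rois <- file.path(out_dir, "rois.csv")
  f_traces <- file.path(out_dir, "spine_traces.csv")
  f_qc <- file.path(out_dir, "spine_qc.json")
  data.table::fwrite(sim$truth$rois, f_rois)
  tr <- data.table::data.table(time_min = ts, q$traces$normalized)
  data.table::fwrite(tr, f_traces)
  writeJson(list(qc = q$qc, n_passed = sum(passed),
                 shrinkage = shr[c("mean", "sem", "n")]), f_qc)
  list(n_spines = ncol(q$traces$normalized), n_passed = sum(passed),
       files = c(md5(c(f_rois, f_traces, f_qc)),
                 md5(list.files(sdir, full.names = TRUE))))
}

runFepspStage <- function(block, out_dir, seed) {
  bw <- block$baseline_window
  pw <- block$post_window
  block <- block[setdiff(names(block), c("baseline_window", "post_window"))]
  block$seed <- block$seed %||% seed
  sim <- do.call(simulateFepspSession, block)
  base_min <- sim$truth$induction_min
  bw <- bw %||% c(base_min - 10, base_min)
  pw <- pw %||% c(base_min + 50, base_min + 60)
  slopes <- measureSlopes(sim$sweeps)
  series <- normalizeSlopes(slopes, timeStamps(sim$sweeps), bw)
  mag <- plasticityMagnitude(series, pw)
  f_sweeps <- file.path(out_dir, "sweeps.csv")
  f_slopes <- file.path(out_dir, "slopes.csv")
  f_sum <- file.path(out_dir, "fepsp_summary.json")
  writeSweepsCsv(sim$sweeps, f_sweeps)
  data.table::fwrite(series, f_slopes)
  writeJson(list(magnitude_pct = mag$magnitude, post_window = pw,
                 baseline_window = bw,
                 true_depression_pct = 100 *
                   sim$truth$params$depression_fraction), f_sum)
  list(n_sweeps = nTimepoints(sim$sweeps), magnitude = mag$magnitude,
       files = md5(c(f_sweeps, f_slopes, f_sum)))
}

runLabelingStage <- function(block, out_dir, seed) {
  anchor <- block$anchor_group
  block$anchor_group <- NULL
  block$seed <- block$seed %||% seed
  if (!is.null(block$effects)) block$effects <- unlist(block$effects)
  sim <- do.call(simulateLabeling, block)
  norm <- normalizeBatch(sim$samples, anchor_group = anchor)
  groups <- split(norm$normalized_pct, norm$group)
  test <- if (length(groups) >= 2 && all(lengths(groups) >= 2))
    anovaOneway(groups) else NULL
  f_tab <- file.path(out_dir, "labeling.csv")
  f_sum <- file.path(out_dir, "labeling_summary.json")
  data.table::fwrite(norm, f_tab)
  writeJson(list(group_means = lapply(groups, function(g) meanSem(g)),
                 anova = if (!is.null(test))
                   test[c("F", "df", "p_value")] else NULL), f_sum)
  list(n_samples = nrow(norm), files = md5(c(f_tab, f_sum)))
}

runAgsStage <- function(block, out_dir, seed) {
  block$seed <- block$seed %||% seed
  if (!is.null(block$groups)) block$groups <- as.data.frame(block$groups)
  cohort <- do.call(simulateAgsCohort, block)
  tabs <- agsIncidenceTables(cohort)
  tests <- lapply(tabs, function(tb) fisherExact(tb)$p_value)
  f_cohort <- file.path(out_dir, "ags_cohort.csv")
  f_sum <- file.path(out_dir, "ags_summary.json")
  data.table::fwrite(cohort, f_cohort)
  writeJson(list(tables = lapply(tabs, as.vector), p_values = tests), f_sum)
  list(n_animals = nrow(cohort), files = md5(c(f_cohort, f_sum)))
}

#' Seized / not-seized contingency tables from a cohort table
#'
#' Builds the 2x2 tables for the study's two planned contrasts: genotype
#' effect under saline (WT-saline vs KO-saline) and treatment effect in the
#' KO (KO-saline vs KO-glyx13). Falls back to all pairwise group contrasts
#' when those groups are absent.
#'
#' @param cohort data.frame(genotype, treatment, seized).
#' @return Named list of 2x2 matrices (rows = groups, cols = seized yes/no).
#' @export
agsIncidenceTables <- function(cohort) {
  stopifnot(all(c("genotype", "treatment", "seized") %in% names(cohort)))
  key <- paste(cohort$genotype, cohort$treatment, sep = ".")
  cnt <- function(k) {
    s <- cohort$seized[key == k]
    c(sum(s), sum(!s))
  }
  pairRow <- function(k1, k2)
    matrix(c(cnt(k1), cnt(k2)), 2, 2, byrow = TRUE,
           dimnames = list(c(k1, k2), c("seized", "not_seized")))
  planned <- list(genotype_saline = c("WT.saline", "KO.saline"),
                  treatment_ko = c("KO.saline", "KO.glyx13"))
  if (all(unlist(planned) %in% key)) {
    lapply(planned, function(p) pairRow(p[1], p[2]))
  } else {
    ks <- unique(key)
    cmb <- utils::combn(ks, 2)
    out <- lapply(seq_len(ncol(cmb)), function(i) pairRow(cmb[1, i],
                                                          cmb[2, i]))
    names(out) <- apply(cmb, 2, paste, collapse = "_vs_")
    out
  }
}

#' Write the canonical synthetic test dataset
#'
#' Writes, under \code{out_dir}: a 10-min extracellular trace with 12 known
#' bursts (CSV + ground-truth JSON), a 25-timepoint 15-spine stack series
#' (TIFFs + ROI CSV + truth JSON; reduced 128 x 128 x 5 frames keep the
#' fixture small), an fEPSP session (CSV), a labeling table (CSV), and an
#' audiogenic-seizure cohort whose per-group seized counts equal the study's
#' reported incidences exactly (2/15, 9/11, 5/16, and 2/15 for the
#' Glyx-13-treated WT group). Regeneration with the same seed is
#' byte-identical.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param which subset of fixtures to write.
#' @return Named list of written paths, invisibly.
#' @export
makeFixtures <- function(out_dir, seed = 1,
                         which = c("trace", "stacks", "fepsp", "labeling",
                                   "ags")) {
  which <- match.arg(which, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if ("trace" %in% which) {
    sim <- simulateTrace(duration = 600, n_bursts = 12, seed = seed + 11L)
    paths$trace <- writeTraceCsv(sim$trace, file.path(out_dir, "trace.csv"))
    paths$trace_truth <- writeGroundTruth(
      sim$truth, file.path(out_dir, "trace_truth.json"))
  }
  if ("stacks" %in% which) {
    sim <- simulateSpineStacks(n_timepoints = 25, frame = c(128, 128),
                               n_z = 5, n_spines = 15, seed = seed + 22L)
    paths$stacks <- writeStackSeries(sim$series,
                                     file.path(out_dir, "stacks"))
    f_rois <- file.path(out_dir, "rois.csv")
    data.table::fwrite(sim$truth$rois, f_rois)
    paths$rois <- f_rois
    paths$stacks_truth <- writeGroundTruth(
      sim$truth[c("volumes", "jitters", "bleach")],
      file.path(out_dir, "stacks_truth.json"))
  }
  if ("fepsp" %in% which) {
    sim <- simulateFepspSession(seed = seed + 33L)
    paths$fepsp <- writeSweepsCsv(sim$sweeps,
                                  file.path(out_dir, "sweeps.csv"))
    paths$fepsp_truth <- writeGroundTruth(
      sim$truth[c("strength", "timestamps_min", "induction_min")],
      file.path(out_dir, "sweeps_truth.json"))
  }
  if ("labeling" %in% which) {
    sim <- simulateLabeling(seed = seed + 44L)
    f <- file.path(out_dir, "labeling.csv")
    data.table::fwrite(sim$samples, f)
    paths$labeling <- f
  }
  if ("ags" %in% which) {
    grp <- data.frame(
      genotype  = c("WT", "KO", "WT", "KO"),
      treatment = c("saline", "saline", "glyx13", "glyx13"),
      seized    = c(2, 9, 2, 5),
      n         = c(15, 11, 15, 16))
    cohort <- do.call(rbind, lapply(seq_len(nrow(grp)), function(i)
      data.frame(genotype = grp$genotype[i], treatment = grp$treatment[i],
                 seized = seq_len(grp$n[i]) <= grp$seized[i])))
    cohort <- cbind(animal = seq_len(nrow(cohort)), cohort)
    f <- file.path(out_dir, "ags_cohort.csv")
    data.table::fwrite(cohort, f)
    paths$ags <- f
  }
  invisible(paths)
}
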