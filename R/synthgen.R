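## Synthetic-data generators. Every generator takes an explicit `seed`,
## draws all randomness from one seeded stream (global RNG state is
## restored afterwards), and returns the generated object together with a
## `truth` record that exactly describes what was simulated.

#' Biphasic extracellular spike template
#'
#' Extracellular somatic spikes are negative-dominant; the template is a
#' negative Gaussian lobe followed by a smaller, broader positive lobe,
#' 1.2 ms total. Gaussian lobes keep the template band-limited so that
#' zero-phase band-pass filtering introduces only negligible ringing.
#'
#' @param fs sampling rate in Hz.
#' @param amplitude peak (absolute) amplitude of the negative lobe, uV.
#' @param total_ms template duration (ms).
#' @param pos_fraction amplitude of the positive lobe relative to the
#'   negative.
#' @return Numeric vector of template samples.
#' @export
spikeTemplate <- function(fs, amplitude = 60, total_ms = 1.2,
                          pos_fraction = 0.3) {
  t <- seq(0, total_ms / 1000, by = 1 / fs)
  -amplitude * exp(-((t - 0.35e-3)^2) / (2 * (0.12e-3)^2)) +
    pos_fraction * amplitude * exp(-((t - 0.85e-3)^2) / (2 * (0.2e-3)^2))
}

# Poisson event times on [0, len) at `rate`, sorted
poissonTimes <- function(rate, len) {
  if (rate <= 0 || len <= 0) return(numeric(0))
  sort(runif(rpois(1L, rate * len), 0, len))
}

# sample `n` non-overlapping burst intervals with >= gap seconds between them
sampleBurstIntervals <- function(n, duration, durations, gap = 2, margin = 5) {
  stopifnot(length(durations) == n)
  avail <- duration - 2 * margin
  if (sum(durations) + (n - 1) * gap > avail)
    stop("requested bursts do not fit into the trace duration")
  slack <- avail - sum(durations) - (n - 1) * gap
  # distribute the slack uniformly between bursts (uniform spacings)
  cuts <- sort(runif(n)) * slack
  starts <- margin + cuts + c(0, cumsum(durations[-n] + gap))
  cbind(start = starts, end = starts + durations)
}

#' Simulate an extracellular CA3 voltage trace with embedded burst epochs
#'
#' Gaussian noise at the acquisition rate with biphasic spike templates
#' inserted at Poisson times: a low background rate outside bursts and a high
#' rate inside declared burst intervals. The returned ground truth holds the
#' exact spike times and burst intervals.
#'
#' Defaults emulate a 10-min slice recording digitized at 25 kHz with
#' disinhibition-driven interictal-like discharges: intra-burst multi-unit
#' rates well above the 8-Hz burst-onset criterion and spikes an order of
#' magnitude above the noise floor.
#'
#' @param duration trace duration in seconds.
#' @param fs sampling rate in Hz (must exceed 2000 Hz so the 300--1000 Hz
#'   band is representable).
#' @param noise_sd Gaussian noise SD in uV.
#' @param spike_amplitude spike peak amplitude in uV (inserted negative-going).
#' @param background_rate background multi-unit rate outside bursts (Hz).
#' @param burst_rate multi-unit rate inside burst intervals (Hz).
#' @param burst_intervals matrix/2-column data with burst start and end times
#'   (s), non-overlapping and inside \code{[0, duration]}; if \code{NULL},
#'   \code{n_bursts} intervals are sampled.
#' @param n_bursts number of bursts to sample when \code{burst_intervals} is
#'   \code{NULL}.
#' @param duration_range range (s) to which sampled burst durations are
#'   clipped; durations are lognormal with median ~1.15 s, mirroring the
#'   ~1.2-s mean event durations typical of disinhibited CA3.
#' @param seed integer seed; identical seed and parameters give bitwise
#'   identical output.
#' @return A list with elements \code{trace} (a \linkS4class{VoltageTrace})
#'   and \code{truth} (list: \code{spike_times}, \code{burst_intervals},
#'   \code{burst_spike_counts}, \code{params}).
#' @examples
#' sim <- simulateTrace(duration = 5, burst_intervals = cbind(1, 3), seed = 1)
#' sim$trace
#' @export
simulateTrace <- function(duration = 600, fs = 25000, noise_sd = 5,
                          spike_amplitude = 60, background_rate = 0.5,
                          burst_rate = 25, burst_intervals = NULL,
                          n_bursts = 12, duration_range = c(0.6, 3),
                          seed = NULL) {
  stopifnot(duration > 0, fs > 2000, noise_sd >= 0, spike_amplitude >= 0,
            background_rate >= 0, burst_rate >= 0)
  withSeed(seed, {
    if (is.null(burst_intervals)) {
      if (n_bursts > 0) {
        durs <- pmin(pmax(rlnorm(n_bursts, log(1.15), 0.4),
                          duration_range[1]), duration_range[2])
        burst_intervals <- sampleBurstIntervals(n_bursts, duration, durs)
      } else {
        burst_intervals <- matrix(numeric(0), 0, 2,
                                  dimnames = list(NULL, c("start", "end")))
      }
    } else {
      burst_intervals <- as.matrix(burst_intervals)
      colnames(burst_intervals) <- c("start", "end")
    }
    validateIntervals(burst_intervals, duration)

    nb <- nrow(burst_intervals)
    burst_spikes <- vector("list", nb)
    for (i in seq_len(nb)) {
      s <- burst_intervals[i, 1]; e <- burst_intervals[i, 2]
      burst_spikes[[i]] <- s + poissonTimes(burst_rate, e - s)
    }
    # background spikes over the complement of the burst intervals
    edges <- c(0, as.vector(t(burst_intervals)), duration)
    bg <- numeric(0)
    for (k in seq(1, length(edges) - 1, by = 2)) {
      s <- edges[k]; e <- edges[k + 1]
      if (e > s) bg <- c(bg, s + poissonTimes(background_rate, e - s))
    }
    spike_times <- sort(c(bg, unlist(burst_spikes)))

    n <- round(duration * fs)
    x <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
    if (length(spike_times) && spike_amplitude > 0) {
      tmpl <- spikeTemplate(fs, spike_amplitude)
      lt <- length(tmpl)
      idx0 <- floor(spike_times * fs) + 1L
      for (i0 in idx0) {
        i1 <- min(i0 + lt - 1L, n)
        x[i0:i1] <- x[i0:i1] + tmpl[seq_len(i1 - i0 + 1L)]
      }
    }
    list(
      trace = VoltageTrace(x, fs = fs, t0 = 0),
      truth = list(
        spike_times = spike_times,
        burst_intervals = burst_intervals,
        burst_spike_counts = vapply(burst_spikes, length, 1L),
        params = list(duration = duration, fs = fs, noise_sd = noise_sd,
                      spike_amplitude = spike_amplitude,
                      background_rate = background_rate,
                      burst_rate = burst_rate, seed = seed)
      )
    )
  })
}

validateIntervals <- function(iv, duration) {
  if (!nrow(iv)) return(invisible(TRUE))
  if (any(iv[, 2] <= iv[, 1]))
    stop("burst intervals must have end > start")
  if (any(iv[, 1] < 0) || any(iv[, 2] > duration))
    stop("burst intervals must lie within [0, duration]")
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2]))
    stop("burst intervals must not overlap")
  invisible(TRUE)
}

#' Simulate an fEPSP recording session with step depression
#'
#' One sweep per stimulus (0.033 Hz, i.e. every 30 s). Each sweep contains a
#' stimulus artifact and a field EPSP modeled as a difference of exponentials
#' whose amplitude (hence initial slope) follows a strength series: 1.0
#' during baseline, stepping to \code{depression_fraction} at the induction
#' time, with multiplicative lognormal sweep noise.
#'
#' @param baseline_min baseline duration in minutes.
#' @param post_min post-induction duration in minutes.
#' @param depression_fraction synaptic strength after induction relative to
#'   baseline, in (0, 1].
#' @param noise_cv coefficient of variation of the multiplicative per-sweep
#'   noise (0 for noise-free).
#' @param sweep_interval_s stimulus interval in seconds.
#' @param fs within-sweep sampling rate (Hz).
#' @param sweep_ms sweep length (ms).
#' @param stim_ms stimulus time within the sweep (ms).
#' @param amplitude_mV peak fEPSP amplitude at baseline (mV, positive number;
#'   the response itself is negative-going).
#' @param tau_rise_ms,tau_decay_ms rise/decay time constants of the
#'   difference-of-exponentials waveform (ms).
#' @param onset_delay_ms synaptic delay between stimulus and fEPSP onset (ms).
#' @param artifact_mV stimulus artifact amplitude (mV).
#' @param seed integer seed.
#' @return list(sweeps = \linkS4class{SweepSeries}, truth = list(strength,
#'   timestamps_min, induction_min, params)).
#' @examples
#' ses <- simulateFepspSession(baseline_min = 5, post_min = 5, seed = 1)
#' ses$sweeps
#' @export
simulateFepspSession <- function(baseline_min = 30, post_min = 60,
                                 depression_fraction = 0.46, noise_cv = 0.05,
                                 sweep_interval_s = 30, fs = 10000,
                                 sweep_ms = 50, stim_ms = 5,
                                 amplitude_mV = 0.3, tau_rise_ms = 2,
                                 tau_decay_ms = 8, onset_delay_ms = 2,
                                 artifact_mV = 1, seed = NULL) {
  stopifnot(baseline_min > 0, post_min > 0,
            depression_fraction > 0, depression_fraction <= 1,
            noise_cv >= 0, tau_decay_ms > tau_rise_ms)
  withSeed(seed, {
    t_min <- seq(0, baseline_min + post_min - 1e-9, by = sweep_interval_s / 60)
    strength <- ifelse(t_min < baseline_min, 1, depression_fraction)
    gain <- if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      rlnorm(length(t_min), -sdlog^2 / 2, sdlog)
    } else rep(1, length(t_min))

    tms <- seq(0, sweep_ms, by = 1000 / fs)
    base_wave <- fepspWaveform(tms, stim_ms, amplitude_mV, tau_rise_ms,
                               tau_decay_ms, onset_delay_ms)
    artifact <- numeric(length(tms))
    ia <- which.min(abs(tms - stim_ms))
    artifact[ia] <- artifact_mV
    artifact[ia + 1L] <- -artifact_mV

    v <- outer(base_wave, strength * gain) + artifact
    list(
      sweeps = SweepSeries(v, time = tms, stimTime = stim_ms,
                           timestamps = t_min),
      truth = list(strength = strength, timestamps_min = t_min,
                   induction_min = baseline_min,
                   params = list(depression_fraction = depression_fraction,
                                 noise_cv = noise_cv,
                                 amplitude_mV = amplitude_mV,
                                 tau_rise_ms = tau_rise_ms,
                                 tau_decay_ms = tau_decay_ms,
                                 onset_delay_ms = onset_delay_ms,
                                 stim_ms = stim_ms, fs = fs, seed = seed))
    )
  })
}

#' Closed-form fEPSP waveform (difference of exponentials)
#'
#' Negative-going waveform with unit reference amplitude
#' \code{amplitude_mV} at its peak, zero before
#' \code{stim_ms + onset_delay_ms}.
#'
#' @inheritParams simulateFepspSession
#' @param t_ms time points (ms).
#' @return numeric vector of voltages (mV).
#' @export
fepspWaveform <- function(t_ms, stim_ms = 5, amplitude_mV = 0.3,
                          tau_rise_ms = 2, tau_decay_ms = 8,
                          onset_delay_ms = 2) {
  tt <- t_ms - stim_ms - onset_delay_ms
  w <- ifelse(tt > 0, exp(-tt / tau_decay_ms) - exp(-tt / tau_rise_ms), 0)
  tpk <- tau_rise_ms * tau_decay_ms / (tau_decay_ms - tau_rise_ms) *
    log(tau_decay_ms / tau_rise_ms)
  peak <- exp(-tpk / tau_decay_ms) - exp(-tpk / tau_rise_ms)
  -amplitude_mV * w / peak
}

# render a 3-D Gaussian blob of given integrated intensity into `vol`
addBlob <- function(vol, center, sigma_xy, sigma_z, integral) {
  d <- dim(vol)
  peak <- integral / ((2 * pi)^1.5 * sigma_xy^2 * sigma_z)
  rx <- max(1L, ceiling(4 * sigma_xy)); rz <- max(1L, ceiling(4 * sigma_z))
  xs <- max(1L, round(center[1]) - rx):min(d[1], round(center[1]) + rx)
  ys <- max(1L, round(center[2]) - rx):min(d[2], round(center[2]) + rx)
  zs <- max(1L, round(center[3]) - rz):min(d[3], round(center[3]) + rz)
  gx <- exp(-((xs - center[1])^2) / (2 * sigma_xy^2))
  gy <- exp(-((ys - center[2])^2) / (2 * sigma_xy^2))
  gz <- exp(-((zs - center[3])^2) / (2 * sigma_z^2))
  vol[xs, ys, zs] <- vol[xs, ys, zs] +
    peak * outer(outer(gx, gy), gz)
  vol
}

# translate a 3-D stack by integer (dx, dy) in-plane, zero fill
translateStack <- function(vol, dx, dy) {
  if (dx == 0 && dy == 0) return(vol)
  d <- dim(vol)
  out <- array(0, d)
  sx <- intersect(seq_len(d[1]), seq_len(d[1]) + dx)
  sy <- intersect(seq_len(d[2]), seq_len(d[2]) + dy)
  out[sx, sy, ] <- vol[sx - dx, sy - dy, , drop = FALSE]
  out
}

#' Simulate a time-lapse spine imaging stack series with known ground truth
#'
#' Each timepoint is a z-series containing a dendrite ridge plus Gaussian
#' spine blobs whose integrated intensities follow a step time course (drop
#' to \code{shrink_fraction} at \code{shrink_onset}), under a global
#' multiplicative bleach drift, integer-pixel translation jitter and optional
#' Poisson shot noise. Defaults reproduce the acquisition geometry of the
#' emulated experiments (512 x 512 x 15 voxels every 4 min, ~15 spines).
#'
#' @param n_timepoints number of timepoints (4-min spacing).
#' @param frame XY frame size in pixels, length-2.
#' @param n_z number of z slices.
#' @param n_spines number of spines.
#' @param spine_sigma in-plane Gaussian sigma of a spine blob (px).
#' @param baseline_volume integrated baseline blob intensity (expected
#'   photon counts; the default corresponds to a bright, well-exposed spine).
#' @param shrink_fraction relative volume after shrinkage, in (0, 1].
#' @param shrink_onset 1-based timepoint index at which volumes step down.
#' @param bleach_per_timepoint fractional multiplicative bleach per timepoint.
#' @param jitter_px maximum absolute in-plane translation jitter per
#'   timepoint (integer pixels; 0 disables).
#' @param shot_noise logical; add Poisson noise per voxel.
#' @param ambient uniform ambient background intensity per voxel.
#' @param timestep_min imaging interval in minutes.
#' @param seed integer seed.
#' @return list(series = \linkS4class{StackSeries}, truth = list with
#'   \code{volumes} (timepoints x spines relative volume), \code{centers},
#'   \code{jitters}, \code{bleach}, \code{rois} (suggested spine, background
#'   and reference ROI centers), \code{params}).
#' @examples
#' sim <- simulateSpineStacks(n_timepoints = 3, frame = c(64, 64), n_z = 3,
#'                            n_spines = 2, seed = 1)
#' sim$series
#' @export
simulateSpineStacks <- function(n_timepoints = 25, frame = c(512, 512),
                                n_z = 15, n_spines = 15, spine_sigma = 1.5,
                                baseline_volume = 20000, shrink_fraction = 0.8,
                                shrink_onset = 9, bleach_per_timepoint = 0.02,
                                jitter_px = 2, shot_noise = TRUE, ambient = 2,
                                timestep_min = 4, seed = NULL) {
  stopifnot(n_timepoints >= 1, length(frame) == 2, n_z >= 1,
            shrink_fraction > 0, shrink_fraction <= 1,
            bleach_per_timepoint >= 0, bleach_per_timepoint < 1,
            jitter_px >= 0)
  roi_half <- 10L
  jit <- as.integer(ceiling(jitter_px))
  margin_x <- roi_half + jit + as.integer(ceiling(4 * spine_sigma)) + 1L
  margin_y <- roi_half + jit + 1L
  y_off <- 16L # spine/background offset from the dendrite axis
  withSeed(seed, {
    ## geometry: horizontal dendrite ridge through the frame center; spines
    ## and background sites offset +/- y_off from it; 4 reference sites on
    ## the ridge itself. All sites share an x grid so ROIs never overlap.
    y_dend <- round(frame[2] / 2)
    z_mid <- ceiling(n_z / 2)
    n_sites <- n_spines + 4L + 3L
    usable <- frame[1] - 2 * margin_x
    min_gap <- roi_half + ceiling(4 * spine_sigma) + 1L
    if (n_sites > 1 && usable / (n_sites - 1) < min_gap)
      stop("spines placed outside frame: frame too small for n_spines")
    if (y_dend + y_off + margin_y > frame[2] ||
        y_dend - y_off - margin_y < 1L)
      stop("spines placed outside frame: frame too small in y")
    xs <- round(seq(margin_x, frame[1] - margin_x, length.out = n_sites))
    site_perm <- sample(n_sites)
    spine_x <- xs[sort(site_perm[seq_len(n_spines)])]
    ref_x <- xs[sort(site_perm[n_spines + 1:4])]
    bg_x <- xs[sort(site_perm[n_spines + 5:7])]
    off <- sample(c(-y_off, y_off), n_spines, replace = TRUE)
    centers <- cbind(x = spine_x, y = y_dend + off,
                     z = pmin(pmax(z_mid + sample(-1:1, n_spines, TRUE), 1L),
                              n_z))
    bg_y <- y_dend + c(-y_off, y_off, -y_off)

    course <- rep(1, n_timepoints)
    if (shrink_onset <= n_timepoints)
      course[shrink_onset:n_timepoints] <- shrink_fraction
    volumes <- matrix(course, n_timepoints, n_spines)
    bleach <- (1 - bleach_per_timepoint)^(seq_len(n_timepoints) - 1)
    jitters <- cbind(dx = integer(n_timepoints), dy = integer(n_timepoints))
    if (jitter_px > 0 && n_timepoints > 1) {
      jitters[-1, 1] <- sample(seq(-jitter_px, jitter_px), n_timepoints - 1,
                               replace = TRUE)
      jitters[-1, 2] <- sample(seq(-jitter_px, jitter_px), n_timepoints - 1,
                               replace = TRUE)
    }

    dend_per_px <- baseline_volume / 60 # ridge intensity per unit x length
    stacks <- vector("list", n_timepoints)
    for (t in seq_len(n_timepoints)) {
      vol <- array(ambient, c(frame[1], frame[2], n_z))
      ## dendrite: Gaussian cross-section in y and z along the full width
      gy <- exp(-((seq_len(frame[2]) - y_dend)^2) / (2 * 2^2))
      gz <- exp(-((seq_len(n_z) - z_mid)^2) / (2 * 1^2))
      ridge <- dend_per_px * outer(rep(1, frame[1]), gy)
      for (z in seq_len(n_z)) vol[, , z] <- vol[, , z] + ridge * gz[z]
      for (s in seq_len(n_spines))
        vol <- addBlob(vol, centers[s, ], spine_sigma, 1,
                       baseline_volume * volumes[t, s])
      vol <- vol * bleach[t]
      vol <- translateStack(vol, jitters[t, 1], jitters[t, 2])
      if (shot_noise)
        vol[] <- rpois(length(vol), pmax(vol, 0))
      stacks[[t]] <- vol
    }
    rois <- rbind(
      data.frame(role = "spine", cx = centers[, 1], cy = centers[, 2]),
      data.frame(role = "background", cx = bg_x, cy = bg_y),
      data.frame(role = "reference", cx = ref_x, cy = y_dend)
    )
    list(
      series = StackSeries(stacks,
                           timestamps = (seq_len(n_timepoints) - 1) *
                             timestep_min),
      truth = list(volumes = volumes, centers = centers, jitters = jitters,
                   bleach = bleach, rois = rois,
                   params = list(n_timepoints = n_timepoints, frame = frame,
                                 n_z = n_z, n_spines = n_spines,
                                 spine_sigma = spine_sigma,
                                 baseline_volume = baseline_volume,
                                 shrink_fraction = shrink_fraction,
                                 shrink_onset = shrink_onset,
                                 bleach_per_timepoint = bleach_per_timepoint,
                                 jitter_px = jitter_px,
                                 shot_noise = shot_noise, ambient = ambient,
                                 seed = seed))
    )
  })
}

#' Simulate a 35S metabolic-labeling experiment
#'
#' Per slice: triplicate CPM draws whose expectation carries a multiplicative
#' group effect and lognormal slice-to-slice noise, an independent protein
#' amount, and a labeling-dose activity. Ground truth records the true
#' effects.
#'
#' @param effects named vector of multiplicative group effects (first group
#'   is the reference); all must be > 0.
#' @param n_per_group slices per group (recycled over groups).
#' @param cv slice-to-slice lognormal coefficient of variation.
#' @param base_rate reference incorporation rate (CPM per mg protein per
#'   unit dose).
#' @param protein_range uniform range of protein amounts (mg).
#' @param triplicate_cv lognormal CV of the triplicate counting replicates.
#' @param dose_cpm nominal activity of the labeling-mix aliquot (CPM).
#' @param dose_cv lognormal CV of the per-batch dose.
#' @param n_batches number of experimental batches (group structure repeated
#'   in each batch).
#' @param seed integer seed.
#' @return list(samples = data.frame(batch, group, cpm1..3, protein_mg,
#'   dose_cpm), truth = list(effects, params)).
#' @export
simulateLabeling <- function(effects = c(WT = 1, KO = 1.15), n_per_group = 8,
                             cv = 0.15, base_rate = 2000,
                             protein_range = c(0.3, 0.7),
                             triplicate_cv = 0.02, dose_cpm = 1e6,
                             dose_cv = 0.05, n_batches = 1, seed = NULL) {
  if (any(effects <= 0)) stop("group effects must be > 0")
  stopifnot(cv >= 0, triplicate_cv >= 0, n_per_group >= 1)
  groups <- names(effects) %||% paste0("g", seq_along(effects))
  withSeed(seed, {
    rows <- list()
    for (b in seq_len(n_batches)) {
      dose <- dose_cpm * lnormNoise(1, dose_cv)
      for (gi in seq_along(effects)) {
        slice_gain <- lnormNoise(n_per_group, cv)
        protein <- runif(n_per_group, protein_range[1], protein_range[2])
        mu <- base_rate * effects[gi] * slice_gain * protein *
          (dose / dose_cpm)
        cpm <- sapply(1:3, function(j) mu * lnormNoise(n_per_group,
                                                       triplicate_cv))
        cpm <- matrix(cpm, n_per_group, 3)
        rows[[length(rows) + 1L]] <- data.frame(
          batch = b, group = groups[gi], cpm1 = cpm[, 1], cpm2 = cpm[, 2],
          cpm3 = cpm[, 3], protein_mg = protein, dose_cpm = dose)
      }
    }
    samples <- do.call(rbind, rows)
    rownames(samples) <- NULL
    list(samples = samples,
         truth = list(effects = effects,
                      params = list(n_per_group = n_per_group, cv = cv,
                                    base_rate = base_rate,
                                    triplicate_cv = triplicate_cv,
                                    n_batches = n_batches, seed = seed)))
  })
}

# multiplicative lognormal noise with unit mean and coefficient of variation cv
lnormNoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, -sdlog^2 / 2, sdlog)
}

#' Simulate an audiogenic-seizure cohort
#'
#' One Bernoulli seizure outcome per animal, with per-group (genotype,
#' treatment) incidence probabilities. Default group structure mirrors the
#' emulated study: saline- or Glyx-13-treated WT and Fmr1 KO mice.
#'
#' @param groups data.frame with columns \code{genotype}, \code{treatment},
#'   \code{p} (seizure probability in [0, 1]) and \code{n} (animals).
#' @param seed integer seed.
#' @return data.frame(animal, genotype, treatment, seized) with the true
#'   probabilities attached as attribute \code{"truth"}.
#' @export
simulateAgsCohort <- function(groups = data.frame(
                                genotype  = c("WT", "KO", "WT", "KO"),
                                treatment = c("saline", "saline",
                                              "glyx13", "glyx13"),
                                p = c(2 / 15, 9 / 11, 2 / 15, 5 / 16),
                                n = c(15, 11, 15, 16)),
                              seed = NULL) {
  stopifnot(all(c("genotype", "treatment", "p", "n") %in% names(groups)))
  if (any(groups$p < 0 | groups$p > 1))
    stop("seizure probability outside [0,1]")
  withSeed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
      data.frame(genotype = groups$genotype[i],
                 treatment = groups$treatment[i],
                 seized = rbinom(groups$n[i], 1, groups$p[i]) == 1)
    }))
    out <- cbind(animal = seq_len(nrow(out)), out)
    attr(out, "truth") <- groups
    out
  })
}
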