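test_that("generators are deterministic under a fixed seed", {
  a <- simulateTrace(duration = 2, seed = 7, burst_intervals = cbind(0.5, 1.2))
  b <- simulateTrace(duration = 2, seed = 7, burst_intervals = cbind(0.5, 1.2))
  expect_identical(samples(a$trace), samples(b$trace))
  expect_identical(a$truth$spike_times, b$truth$spike_times)

  s1 <- simulateSpineStacks(n_timepoints = 3, frame = c(192, 64), n_z = 3,
                            n_spines = 2, seed = 7)
  s2 <- simulateSpineStacks(n_timepoints = 3, frame = c(192, 64), n_z = 3,
                            n_spines = 2, seed = 7)
  expect_identical(s1$series@stacks, s2$series@stacks)

  f1 <- simulateFepspSession(baseline_min = 2, post_min = 2, seed = 7)
  f2 <- simulateFepspSession(baseline_min = 2, post_min = 2, seed = 7)
  expect_identical(f1$sweeps@voltage, f2$sweeps@voltage)

  l1 <- simulateLabeling(seed = 7)
  l2 <- simulateLabeling(seed = 7)
  expect_identical(l1$samples, l2$samples)

  c1 <- simulateAgsCohort(seed = 7)
  c2 <- simulateAgsCohort(seed = 7)
  expect_identical(c1$seized, c2$seized)
})

test_that("generators do not disturb the global RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulateTrace(duration = 1, seed = 3, n_bursts = 0))
  expect_identical(before, .Random.seed)
})

test_that("silent trace: no noise, no spikes, no bursts gives all zeros", {
  sim <- simulateTrace(duration = 1, noise_sd = 0, background_rate = 0,
                       n_bursts = 0, seed = 1)
  expect_true(all(samples(sim$trace) == 0))
  expect_length(sim$truth$spike_times, 0)
  expect_equal(nrow(sim$truth$burst_intervals), 0)
})

test_that("spike counts inside a declared burst follow the Poisson law", {
  # 40 Hz over a 2-s interval: expect ~80 spikes, within 4*sqrt(80)
  sim <- simulateTrace(duration = 10, burst_rate = 40,
                       background_rate = 0.5,
                       burst_intervals = cbind(4, 6), seed = 11)
  n_in <- sum(sim$truth$spike_times >= 4 & sim$truth$spike_times < 6)
  expect_identical(n_in, unname(sim$truth$burst_spike_counts[1]))
  expect_lt(abs(n_in - 80), 4 * sqrt(80))
})

test_that("overlapping or out-of-range burst intervals are rejected", {
  expect_error(simulateTrace(duration = 5, seed = 1,
                             burst_intervals = rbind(c(1, 2), c(1.5, 3))),
               "overlap")
  expect_error(simulateTrace(duration = 5, seed = 1,
                             burst_intervals = cbind(4, 6)),
               "within")
  expect_error(simulateTrace(duration = 5, seed = 1,
                             burst_intervals = cbind(2, 1)),
               "end > start")
})

test_that("spike amplitude scales the inserted waveform linearly", {
  iv <- cbind(0.2, 0.8)
  a <- simulateTrace(duration = 1, noise_sd = 0, spike_amplitude = 30,
                     background_rate = 0, burst_rate = 20,
                     burst_intervals = iv, seed = 5)
  b <- simulateTrace(duration = 1, noise_sd = 0, spike_amplitude = 90,
                     background_rate = 0, burst_rate = 20,
                     burst_intervals = iv, seed = 5)
  expect_equal(samples(b$trace), 3 * samples(a$trace), tolerance = 1e-12)
})

test_that("static noise-free stack series repeats the same volume", {
  sim <- simulateSpineStacks(n_timepoints = 4, frame = c(192, 64), n_z = 3,
                             n_spines = 2, shrink_fraction = 1,
                             bleach_per_timepoint = 0, jitter_px = 0,
                             shot_noise = FALSE, seed = 2)
  expect_identical(sim$series@stacks[[1]], sim$series@stacks[[4]])
})

test_that("blob integral tracks the programmed shrink fraction", {
  sim <- simulateSpineStacks(n_timepoints = 4, frame = c(192, 64), n_z = 5,
                             n_spines = 1, shrink_fraction = 0.8,
                             shrink_onset = 3, bleach_per_timepoint = 0,
                             jitter_px = 0, shot_noise = FALSE, ambient = 0,
                             seed = 2)
  ctr <- sim$truth$centers[1, ]
  box <- function(st) sum(st[(ctr[1] - 8):(ctr[1] + 8),
                             (ctr[2] - 8):(ctr[2] + 8), ])
  pre <- box(sim$series@stacks[[1]])
  post <- box(sim$series@stacks[[4]])
  expect_equal(post / pre, 0.8, tolerance = 1e-3)
  expect_equal(sim$truth$volumes[, 1], c(1, 1, 0.8, 0.8))
})

test_that("stack generator rejects frames too small for the spine count", {
  expect_error(simulateSpineStacks(n_timepoints = 2, frame = c(64, 64),
                                   n_z = 3, n_spines = 10, seed = 1),
               "frame too small")
})

test_that("noise-free fEPSP sessions are exactly reproducible sweep to sweep", {
  s <- simulateFepspSession(baseline_min = 2, post_min = 2,
                            depression_fraction = 1, noise_cv = 0, seed = 1)
  expect_true(all(s$sweeps@voltage == s$sweeps@voltage[, 1]))
  expect_error(simulateFepspSession(baseline_min = 0, post_min = 2),
               "baseline_min")
})

test_that("labeling generator: exact effects when noise-free, errors on bad effect", {
  sim <- simulateLabeling(effects = c(WT = 1, KO = 1.15), cv = 0,
                          triplicate_cv = 0, seed = 1)
  rate <- incorporationRate(as.matrix(sim$samples[c("cpm1", "cpm2", "cpm3")]),
                            sim$samples$protein_mg)
  r <- rate / sim$samples$dose_cpm
  expect_equal(mean(r[sim$samples$group == "KO"]) /
                 mean(r[sim$samples$group == "WT"]), 1.15,
               tolerance = 1e-12)
  expect_error(simulateLabeling(effects = c(WT = 1, KO = 0)), "> 0")
})

test_that("labeling Monte-Carlo: injected effect recovered across replicates", {
  eff <- vapply(1:200, function(s) {
    sim <- simulateLabeling(effects = c(WT = 1, KO = 1.15),
                            n_per_group = 12, cv = 0.1, seed = 1000 + s)
    nb <- normalizeBatch(sim$samples)
    gm <- tapply(nb$normalized_pct, nb$group, mean)
    unname(gm["KO"] / gm["WT"])
  }, 0)
  expect_lt(abs(mean(eff) - 1.15), 0.02)
})

test_that("seizure cohorts honor degenerate and stochastic probabilities", {
  g0 <- data.frame(genotype = "WT", treatment = "none", p = 0, n = 10)
  expect_equal(sum(simulateAgsCohort(g0, seed = 1)$seized), 0)
  g1 <- data.frame(genotype = "KO", treatment = "none", p = 1, n = 10)
  expect_equal(sum(simulateAgsCohort(g1, seed = 1)$seized), 10)
  gb <- data.frame(genotype = "KO", treatment = "none", p = 0.8, n = 1000)
  inc <- mean(simulateAgsCohort(gb, seed = 2)$seized)
  expect_gte(inc, 0.75); expect_lte(inc, 0.85)
  expect_error(simulateAgsCohort(data.frame(genotype = "a", treatment = "b",
                                            p = 1.2, n = 3)),
               "probability")
})
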