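cfg <- detectorConfig()
cfg_win <- detectorConfig(edge_method = "window")

test_that("preprocessing keeps in-band signal and rejects out-of-band signal", {
  fs <- 25000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  z <- preprocessTrace(VoltageTrace(numeric(fs), fs), cfg)
  expect_equal(length(samples(z)), fs / 10)
  expect_true(all(samples(z) == 0))
  expect_equal(samplingRate(z), 2500)

  # expected gains from the designed transfer function |H(f)|^2 (zero-phase
  # filtering applies the squared magnitude response)
  bf <- signal::butter(cfg$filter_order, cfg$band / (fs / 2), type = "pass")
  gain2 <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs * (seq_along(bf$b) - 1))
    Mod(sum(bf$b * z) / sum(bf$a * z))^2
  }
  x50 <- sin(2 * pi * 50 * t)
  y50 <- samples(preprocessTrace(VoltageTrace(x50, fs), cfg))
  r50 <- sqrt(mean(y50^2)) / sqrt(mean(x50^2))
  expect_lt(r50, 0.01) # far below 1% of the input RMS, as designed

  x600 <- sin(2 * pi * 600 * t)
  y600 <- samples(preprocessTrace(VoltageTrace(x600, fs), cfg))
  r600 <- sqrt(mean(y600^2)) / sqrt(mean(x600^2))
  expect_gt(r600, 0.9); expect_lt(r600, 1.1)
  expect_equal(r600, gain2(600), tolerance = 0.01)
})

test_that("preprocessing rejects bands above the decimated Nyquist rate", {
  tr <- VoltageTrace(numeric(10000), fs = 10000)
  expect_error(preprocessTrace(tr, detectorConfig()), "Nyquist")
})

test_that("MAD threshold matches the hand-enumerated example", {
  # x = [1,2,3,4,100]: median 3, |dev| = [2,1,0,1,97], MAD = 1 -> T = 5
  x <- c(1, 2, 3, 4, 100)
  expect_equal(mad(x, constant = 1), 1)
  expect_equal(5 * mad(x, constant = 1), 5)
})

test_that("constant traces yield no spikes with a degenerate-threshold warning", {
  tr <- VoltageTrace(rep(3, 1000), fs = 2500)
  expect_warning(sp <- detectSpikes(tr, cfg), "degenerate")
  expect_length(sp, 0)
  expect_length(detectSpikes(VoltageTrace(rnorm(1000, sd = 1e4), fs = 2500),
                             detectorConfig(mad_factor = 1e6)), 0)
})

test_that("a single inserted template is found within 1 ms (seeded repeats)", {
  hits <- 0L
  for (s in 1:100) {
    sim <- simulateTrace(duration = 1, background_rate = 0, n_bursts = 0,
                         seed = 20000 + s)
    x <- samples(sim$trace)
    tmpl <- spikeTemplate(25000, amplitude = 60)
    i0 <- 12501L
    x[i0:(i0 + length(tmpl) - 1L)] <- x[i0:(i0 + length(tmpl) - 1L)] + tmpl
    sp <- detectSpikes(preprocessTrace(VoltageTrace(x, 25000), cfg), cfg)
    if (length(sp) == 1L && abs(sp - 0.5) <= 1e-3) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("binning follows the half-open 100-ms convention", {
  b <- binSpikes(c(0.05, 0.12, 0.13), span = c(0, 0.2), cfg)
  expect_identical(b$counts, c(1L, 2L))
  expect_identical(binSpikes(numeric(0), c(0, 1), cfg)$counts, rep(0L, 10))
  # spike exactly at a bin edge lands in the later bin
  expect_identical(binSpikes(0.1, c(0, 0.2), cfg)$counts, c(0L, 1L))
  # spikes outside the span are dropped, totals conserved inside
  b2 <- binSpikes(c(-0.5, 0.01, 0.99, 1.5), c(0, 1), cfg)
  expect_equal(sum(b2$counts), 2)
})

test_that("window-convention burst detection matches the hand enumeration", {
  counts <- c(rep(0L, 5), rep(2L, 10), rep(0L, 5))
  ev <- detectBursts(makeBinned(counts), cfg_win)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset, 0.3)
  expect_equal(ev$offset, 1.9)
  expect_equal(ev$duration, 1.6)
  expect_equal(ev$klass, "long")
  # spike-support refinement recovers the true occupied extent instead
  ev2 <- detectBursts(makeBinned(counts), cfg)
  expect_equal(ev2$onset, 0.5)
  expect_equal(ev2$offset, 1.5)
  expect_equal(ev2$klass, "short")
})

test_that("burst onset requires strictly more than the on rate", {
  # constant 4 spikes per 0.5-s window = exactly 8 Hz: no burst
  ev <- detectBursts(makeBinned(rep(c(1L, 1L, 0L, 1L, 1L), 6)), cfg_win)
  expect_equal(nrow(ev), 0)
  expect_equal(nrow(detectBursts(makeBinned(rep(0L, 50)), cfg)), 0)
  # fewer bins than one window: no events
  expect_equal(nrow(detectBursts(makeBinned(c(9L, 9L)), cfg)), 0)
})

test_that("hysteresis: bursts persist at or above the off rate only", {
  # 12 Hz onset, then a stretch at 4 Hz (2 spikes/window) keeps the burst
  # alive; a window below 4 Hz terminates it
  counts <- c(rep(0L, 3), 6L, rep(1L, 8), rep(0L, 10))
  ev <- detectBursts(makeBinned(counts), cfg_win)
  expect_equal(nrow(ev), 1)
  wb <- 5
  cs <- c(0, cumsum(counts))
  nw <- length(counts) - wb + 1
  rate <- (cs[(wb + 1):(length(counts) + 1)] - cs[1:nw]) / 0.5
  iw <- seq(ev$onset / 0.1 + 1, (ev$offset - 0.5) / 0.1 + 1)
  expect_true(all(rate[iw] >= 4))
  expect_gt(max(rate[iw]), 8)
  if (max(iw) < nw) expect_lt(rate[max(iw) + 1], 4)
})

test_that("incremental detector equals the brute-force window enumeration", {
  set.seed(42)
  for (rep in 1:60) {
    counts <- rpois(600, 0.3)
    nb <- sample(1:4, 1)
    for (k in seq_len(nb)) {
      at <- sample(1:570, 1)
      len <- sample(6:30, 1)
      counts[at:(at + len - 1)] <- counts[at:(at + len - 1)] +
        rpois(len, 2.5)
    }
    for (em in c("spikes", "window")) {
      got <- detectBursts(makeBinned(counts),
                          detectorConfig(edge_method = em))
      want <- bruteForceBursts(counts, edge_method = em)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("shifting the counts by whole bins shifts every event time exactly", {
  set.seed(7)
  counts <- rpois(200, 0.2)
  counts[80:110] <- counts[80:110] + rpois(31, 3)
  ev <- detectBursts(makeBinned(counts), cfg)
  k <- 13L
  ev_shift <- detectBursts(makeBinned(c(rep(0L, k), counts)), cfg)
  expect_equal(nrow(ev), nrow(ev_shift))
  expect_equal(ev_shift$onset, ev$onset + k * 0.1)
  expect_equal(ev_shift$offset, ev$offset + k * 0.1)
  # equivalently, shifting t_start translates times continuously
  ev_t0 <- detectBursts(makeBinned(counts, t_start = 2.5), cfg)
  expect_equal(ev_t0$onset, ev$onset + 2.5)
})

test_that("burst summaries count classes at the 1.5-s boundary (long inclusive)", {
  ev <- data.frame(onset = c(0, 5, 10), offset = c(1, 6.5, 12.2),
                   duration = c(1, 1.5, 2.2),
                   klass = c("short", "long", "long"))
  s <- summarizeBursts(ev, analyzed_minutes = 2, cfg)
  expect_equal(s$n_short, 1)
  expect_equal(s$n_long, 2) # duration exactly 1.5 counts as long
  expect_equal(s$mean_duration, mean(c(1, 1.5, 2.2)))
  expect_equal(s$burst_frequency, 1.5)
  s0 <- summarizeBursts(ev[0, ], analyzed_minutes = 2, cfg)
  expect_equal(s0$n_short + s0$n_long, 0)
  expect_true(is.na(s0$mean_duration))
})

test_that("detector configuration rejects inconsistent rates", {
  expect_error(detectorConfig(on_rate = 4, off_rate = 8), "exceed")
  expect_error(detectorConfig(window = 0.55), "integer multiple")
})
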