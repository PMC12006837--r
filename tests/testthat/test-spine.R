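test_that("z projection takes the voxel-wise maximum (or sum on request)", {
  st <- array(0, c(6, 5, 3))
  st[2, 3, 2] <- 7; st[2, 3, 1] <- 3
  p <- projectZSeries(st)
  expect_equal(p[2, 3], 7)
  expect_equal(sum(p != 0), 1)
  expect_equal(projectZSeries(array(4, c(3, 3, 5)))[1, 1], 4)
  expect_equal(projectZSeries(st, method = "sum")[2, 3], 10)
  expect_error(projectZSeries(array(0, c(3, 3, 0))), "non-empty")
})

test_that("registration recovers integer translations exactly", {
  set.seed(1)
  im <- matrix(0, 48, 40)
  im[15:20, 10:14] <- matrix(runif(30, 1, 5), 6)
  im[30:33, 25:30] <- 3
  sh <- spineburst:::translateImage(im, 3, -2)
  reg <- registerSeries(list(im, sh))
  expect_equal(unname(reg$shifts[2, ]), c(3, -2))
  expect_equal(reg$aligned[[2]][5:44, 5:36], im[5:44, 5:36])
  # idempotence: aligned images re-register with zero shifts
  reg2 <- registerSeries(reg$aligned)
  expect_true(all(reg2$shifts == 0))
  # agreement with an exhaustive shift search over many random shifts
  for (k in 1:10) {
    dx <- sample(-6:6, 1); dy <- sample(-6:6, 1)
    shk <- spineburst:::translateImage(im, dx, dy)
    expect_equal(unname(registerSeries(list(im, shk))$shifts[2, ]),
                 exhaustiveShift(im, shk, 6))
    expect_equal(exhaustiveShift(im, shk, 6), c(dx, dy))
  }
  expect_warning(registerSeries(list(matrix(0, 8, 8), matrix(0, 8, 8))),
                 "zero")
})

test_that("registration recovers jitter on noise-free synthetic stacks", {
  sim <- simulateSpineStacks(n_timepoints = 6, frame = c(192, 96), n_z = 3,
                             n_spines = 2, jitter_px = 10,
                             shot_noise = FALSE, seed = 4)
  proj <- lapply(sim$series@stacks, projectZSeries)
  reg <- registerSeries(proj)
  expect_equal(unname(reg$shifts), unname(sim$truth$jitters))
})

# a tiny analytic series: uniform images (plus flat spine and reference
# patches) where every quantity is known in closed form
uniformSeries <- function(levels, spine_extra = 0, ref_extra = 5) {
  lapply(levels, function(v) {
    img <- matrix(v, 80, 120)
    img[31:50, 31:50] <- img[31:50, 31:50] + spine_extra
    for (cy in c(15, 45, 75, 105)) # reference structures
      img[56:75, (cy - 9):(cy + 10)] <- img[56:75, (cy - 9):(cy + 10)] +
        ref_extra
    img
  })
}

uniformRois <- function() {
  data.frame(role = c("spine", "background", "background", "background",
                      "reference", "reference", "reference", "reference"),
             cx = c(40, 15, 15, 15, 65, 65, 65, 65),
             cy = c(40, 15, 65, 105, 15, 45, 75, 105))
}

test_that("ROI arithmetic: background subtraction matches the closed form", {
  # uniform image 10 with a +2 spine patch: raw spine = (10 + 2) * 400,
  # per-pixel background 10 -> corrected = 2 * 400 = 800
  imgs <- uniformSeries(c(10, 10, 10), spine_extra = 2)
  tr <- measureRoiSeries(imgs, uniformRois(), baseline_timepoints = 1:2)
  expect_equal(unname(tr$b), rep(10, 3))
  expect_equal(unname(tr$raw[, 1]), rep(12 * 400, 3))
  expect_equal(unname(tr$corrected[, 1]), rep(800, 3))
  expect_equal(unname(tr$normalized[, 1]), rep(100, 3))
})

test_that("global gain on one timepoint cancels exactly", {
  sim <- simulateSpineStacks(n_timepoints = 5, frame = c(192, 64), n_z = 3,
                             n_spines = 2, jitter_px = 0,
                             shot_noise = FALSE, seed = 5,
                             bleach_per_timepoint = 0.05, shrink_onset = 4)
  proj <- lapply(sim$series@stacks, projectZSeries)
  base <- measureRoiSeries(proj, sim$truth$rois, baseline_timepoints = 1:3)
  for (tp in c(2, 5)) {
    proj2 <- proj
    proj2[[tp]] <- proj2[[tp]] * 1.3
    tr2 <- measureRoiSeries(proj2, sim$truth$rois, baseline_timepoints = 1:3)
    expect_equal(tr2$normalized, base$normalized, tolerance = 1e-12)
  }
  # spatially uniform additive offset also cancels (background subtraction)
  proj3 <- proj
  proj3[[3]] <- proj3[[3]] + 17
  tr3 <- measureRoiSeries(proj3, sim$truth$rois, baseline_timepoints = 1:3)
  expect_equal(tr3$normalized, base$normalized, tolerance = 1e-12)
})

test_that("bleach-only series normalizes to a flat 100% trace", {
  sim <- simulateSpineStacks(n_timepoints = 8, frame = c(192, 64), n_z = 3,
                             n_spines = 2, shrink_fraction = 1,
                             bleach_per_timepoint = 0.2, jitter_px = 0,
                             shot_noise = FALSE, seed = 6)
  q <- quantifySpineSeries(sim$series, sim$truth$rois, baseline_min = 13)
  expect_equal(unname(q$traces$normalized),
               matrix(100, 8, 2), tolerance = 0.005)
})

test_that("ROI roles and geometry are validated", {
  imgs <- uniformSeries(c(1, 1))
  r <- uniformRois()
  expect_error(measureRoiSeries(imgs, r[r$role != "background", ], 1),
               "3 background")
  expect_error(measureRoiSeries(imgs, r[-5, ], 1), "4 reference")
  r2 <- r; r2$cx[1] <- 5
  expect_error(measureRoiSeries(imgs, r2, 1), "outside")
})

test_that("baseline drift QC matches the closed-form OLS values", {
  ts <- seq(0, 30, length.out = 11)
  flat <- driftQC(rep(100, 11), ts, baseline_min = 30.5)
  expect_equal(flat$drift_percent, 0)
  expect_true(flat$passed)
  # 100 -> 110 linearly: drift = 10 / 105 * 100 = 9.5238% -> fail
  up10 <- driftQC(seq(100, 110, length.out = 11), ts, baseline_min = 30.5)
  expect_equal(up10$drift_percent, 1000 / 105, tolerance = 1e-10)
  expect_false(up10$passed)
  # 100 -> 105: drift = 5 / 102.5 * 100 = 4.878% -> pass
  up5 <- driftQC(seq(100, 105, length.out = 11), ts, baseline_min = 30.5)
  expect_equal(up5$drift_percent, 500 / 102.5, tolerance = 1e-10)
  expect_true(up5$passed)
  expect_warning(q <- driftQC(c(100, 101), c(0, 4), baseline_min = 30),
                 "fewer than 3")
  expect_true(is.na(q$passed))
})

test_that("shrinkage summary averages spines, then experiments", {
  ts <- seq(0, 96, by = 4)
  m1 <- matrix(100, 25, 3)
  expect_equal(summarizeShrinkage(list(m1), ts, c(80, 90))$mean, 100)
  m2 <- m1; m2[ts >= 80 & ts <= 90, ] <- rep(c(70, 80, 90), each = 3)
  s <- summarizeShrinkage(list(m1, m2), ts, c(80, 90))
  expect_equal(s$per_experiment, c(100, 80))
  expect_equal(s$mean, 90)
  expect_equal(s$n, 2)
  expect_error(summarizeShrinkage(list(m1), ts, c(200, 210)), "empty")
})

test_that("noise-free shrink series recovers the programmed fraction exactly", {
  sim <- simulateSpineStacks(n_timepoints = 25, frame = c(192, 64), n_z = 3,
                             n_spines = 2, shrink_fraction = 0.8,
                             jitter_px = 0, shot_noise = FALSE, seed = 7)
  q <- quantifySpineSeries(sim$series, sim$truth$rois)
  s <- summarizeShrinkage(list(q$traces$normalized),
                          timeStamps(sim$series), c(80, 90))
  expect_equal(s$mean, 80, tolerance = 0.005)
})

test_that("spine density is count per unit length", {
  expect_equal(spineDensity(23, 50), 4.6)
  expect_equal(spineDensity(0, 30), 0)
  expect_equal(spineDensity(46, 100), spineDensity(23, 50))
  expect_equal(spineDensity(23, 50, unit_length_um = 1), 0.46)
  expect_error(spineDensity(3, 0), "> 0")
})
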