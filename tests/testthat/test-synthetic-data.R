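test_that("ground-truth orientation draws are centered, calibrated and seeded", {
  pred <- intercalationOrientation(calibratedDuplex(), designSpec(6))
  ## zero scatter returns exactly the model orientation
  o0 <- sampleOrientation(pred, 0)
  expect_equal(axisDistance(o0$axis, predictionAxis(pred)), 0,
               tolerance = 1e-9)
  ## seeding contract
  a <- sampleOrientation(pred, 4.5, seed = 99)
  b <- sampleOrientation(pred, 4.5, seed = 99)
  c <- sampleOrientation(pred, 4.5, seed = 100)
  expect_identical(a$axis, b$axis)
  expect_gt(axisDistance(a$axis, c$axis), 1e-6)
  expect_error(sampleOrientation(pred, -1), "sigmaTruth")
  ## Monte-Carlo: per-tangent-component SD of 4.5 degree draws
  ax <- rFisherAxes(10000, predictionAxis(pred), 1 / deg2rad(4.5)^2,
                    seed = 17)
  m <- predictionAxis(pred)
  e1 <- c(1, 0, 0) - m[1] * m; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(m[2] * e1[3] - m[3] * e1[2], m[3] * e1[1] - m[1] * e1[3],
          m[1] * e1[2] - m[2] * e1[1])
  ca <- pmin(1, ax %*% m)
  ang <- acos(ca)
  tn <- sqrt((ax %*% e1)^2 + (ax %*% e2)^2)
  t1 <- ang * (ax %*% e1) / pmax(tn, 1e-15)
  expect_equal(sd(t1) * 180 / pi, 4.5, tolerance = 0.2 / 4.5)
})

test_that("dipole movies have correct baseline, stability and bookkeeping", {
  cam <- cameraModel()
  ## no dyes, no fiducials: frames are baseline + noise only
  empty <- simulateDdiMovie(data.frame(x = numeric(), y = numeric(),
                                       theta = numeric(), phi = numeric()),
                            frames = 5, fov = 40L, bgPhotons = 2, seed = 2)
  expMean <- cam@baseline + 2 * cam@gain / cam@sensitivity
  expect_equal(mean(empty$stack), expMean, tolerance = 0.05)
  ## one stable dye: appearance is stationary (correlation of smoothed
  ## frames against the smoothed leave-one-out mean)
  dye <- data.frame(x = 33 * 160, y = 33 * 160, theta = 65, phi = 120)
  kin <- kineticsParams(bleachHazard = 0, switchProb = 0)
  sim <- simulateDdiMovie(dye, kinetics = kin, frames = 12, fov = 65L,
                          seed = 3)
  st <- sim$stack - cam@baseline
  K <- DipoleOrigami:::smoothMatrix(65L, 1.5)
  sm <- lapply(1:12, function(t) K %*% st[, , t] %*% t(K))
  total <- Reduce(`+`, sm)
  for (t in 1:12) {
    ref <- (total - sm[[t]]) / 11
    cc <- stats::cor(as.numeric(sm[[t]]), as.numeric(ref))
    expect_gte(cc, 0.95)
  }
  expect_equal(nrow(sim$truth$segments), 1L)
  ## orientation segments partition the pre-bleach frames
  kinSw <- kineticsParams(bleachHazard = 0.05, switchProb = 0.3)
  sim2 <- simulateDdiMovie(dye, kinetics = kinSw, frames = 30, fov = 65L,
                           seed = 5)
  segs <- sim2$truth$segments
  segs <- segs[order(segs$start), ]
  expect_equal(segs$start[1], 1L)
  if (nrow(segs) > 1)
    expect_equal(segs$start[-1], segs$end[-nrow(segs)])
  last <- sim2$truth$bleachFrame[1]
  expect_equal(segs$end[nrow(segs)], if (is.na(last)) 31L else last)
  ## overlapping dyes are a layout error
  bad <- data.frame(x = c(3000, 4000), y = c(3000, 3000),
                    theta = c(10, 20), phi = c(0, 0))
  expect_error(simulateDdiMovie(bad, frames = 2, fov = 80L), "layout error")
})

test_that("movie generation is byte-identical for a fixed seed", {
  dye <- data.frame(x = 33 * 160, y = 33 * 160, theta = 65, phi = 120)
  s1 <- simulateDdiMovie(dye, frames = 3, fov = 65L, seed = 42)
  s2 <- simulateDdiMovie(dye, frames = 3, fov = 65L, seed = 42)
  expect_identical(s1$stack, s2$stack)
  p1 <- paintScene(33, frames = 120, seed = 9)
  p2 <- paintScene(33, frames = 120, seed = 9)
  expect_identical(p1$sim$stack, p2$sim$stack)
})

test_that("PAINT binding statistics follow the exponential kinetics", {
  ## no binding: only fiducials present in every frame
  kinOff <- kineticsParams(meanDark = 1e9)
  center <- 32 * 160
  fid <- data.frame(x = center - 3200, y = center + 2800, photons = 20000)
  off <- simulatePaintMovie(data.frame(x = center, y = center,
                                       phiOrigami = 0),
                            kinetics = kinOff, frames = 120,
                            fiducials = fid, fov = 64L, seed = 4)
  expect_null(off$truth$events)
  loc <- localizeFrames(off$stack)
  expect_gt(nrow(loc), 100)
  expect_true(all(sqrt((loc$x_nm - fid$x)^2 + (loc$y_nm - fid$y)^2) < 300))

  ## event counts per site within 3 sigma of the renewal expectation
  kin <- kineticsParams()
  frames <- 1500
  sim <- simulatePaintMovie(data.frame(x = center, y = center,
                                       phiOrigami = 45),
                            kinetics = kin, frames = frames, fov = 64L,
                            drift = FALSE, seed = 6)
  ev <- sim$truth$events
  nEvents <- tapply(ev$frame, ev$site,
                    function(f) sum(diff(sort(f)) > 1) + 1)
  tTotal <- frames * 0.3
  expEv <- tTotal / (kin@meanDark + kin@meanBright)
  sdEv <- sqrt(expEv)
  for (s in names(nEvents))
    expect_lt(abs(nEvents[[s]] - expEv), 3.5 * sdEv)

  ## truth/stack consistency: bright events leave a signal well above the
  ## background noise in their frame
  cam <- cameraModel()
  full <- ev[ev$fraction > 0.9, ][1:10, ]
  for (r in seq_len(nrow(full))) {
    fr <- sim$stack[, , full$frame[r]]
    px <- ceiling(full$x[r] / 160); py <- ceiling(full$y[r] / 160)
    w <- fr[(px - 1):(px + 1), (py - 1):(py + 1)]
    expect_gt(max(w), cam@baseline + 3 * cam@readNoise / cam@sensitivity)
  }
})

test_that("zero-drift fiducial scatter matches the precision estimate", {
  p <- paintScene(0, frames = 300, seed = 13)
  ## rebuild without drift
  sim <- simulatePaintMovie(data.frame(x = p$center, y = p$center,
                                       phiOrigami = 0),
                            frames = 300, drift = FALSE,
                            fiducials = p$fid, fov = 64L, seed = 13)
  loc <- localizeFrames(sim$stack)
  fl <- loc[sqrt((loc$x_nm - p$fid$x)^2 + (loc$y_nm - p$fid$y)^2) < 300, ]
  empSd <- sqrt((sd(fl$x_nm)^2 + sd(fl$y_nm)^2) / 2)
  predSd <- median(fl$uncertainty_nm)
  expect_gt(empSd / predSd, 0.5)
  expect_lt(empSd / predSd, 2)
})
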