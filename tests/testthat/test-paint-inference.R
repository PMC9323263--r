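## ADU frame from an expected-photon frame without noise.
aduFrame <- function(photons, cam = cameraModel()) {
  cam@baseline + photons * cam@gain / cam@sensitivity
}

test_that("localization is exact on noiseless spots and empty on blanks", {
  cam <- cameraModel()
  ## spot offset (+0.3, -0.7) px from a pixel center
  target <- c((20 - 0.5 + 0.3) * 160, (24 - 0.5 - 0.7) * 160)
  ph <- matrix(0.01, 48, 48)
  ph <- DipoleOrigami:::stampGaussian(ph, target[1] - 24 * 160,
                                      target[2] - 24 * 160,
                                      210, 2000, 160)
  loc <- localizeFrames(aduFrame(ph), cam)
  expect_equal(nrow(loc), 1)
  expect_lt(abs(loc$x_nm - target[1]), 0.01 * 160)
  expect_lt(abs(loc$y_nm - target[2]), 0.01 * 160)
  ## blank frames produce zero rows
  blank <- array(aduFrame(matrix(1, 48, 48)), c(48, 48, 2))
  expect_equal(nrow(localizeFrames(blank, cam)), 0)
})

test_that("empirical localization scatter matches the precision estimator", {
  cam <- cameraModel()
  set.seed(23)
  ph <- matrix(0.5, 32, 32)
  ph <- DipoleOrigami:::stampGaussian(ph, 40, -55, 1.3 * 160, 1000, 160)
  xs <- c(); preds <- c()
  for (r in 1:200) {
    noisy <- applyCamera(ph, cam)
    loc <- localizeFrames(noisy, cam, k = 4, initSigma = 1.3 * 160)
    if (nrow(loc) == 1) {
      xs <- c(xs, loc$x_nm)
      preds <- c(preds, loc$uncertainty_nm)
    }
  }
  expect_gt(length(xs), 150)
  expect_equal(sd(xs), mean(preds), tolerance = 0.25)
})

test_that("drift correction removes injected drift and averages fiducials", {
  ## synthetic fiducial tracks: two beads, independent noise, linear drift
  nF <- 800
  set.seed(24)
  drift <- cbind(0.3 * (seq_len(nF) - 1), -0.1 * (seq_len(nF) - 1))
  noise <- 2
  mkTrack <- function(f, x0, y0) data.frame(
    fiducial = f, frame = seq_len(nF),
    x_nm = x0 + drift[, 1] + rnorm(nF, 0, noise),
    y_nm = y0 + drift[, 2] + rnorm(nF, 0, noise))
  tracks <- rbind(mkTrack(1, 1000, 1000), mkTrack(2, 6000, 2000))
  table <- tracks[, c("frame", "x_nm", "y_nm")]
  table$sigma_nm <- 210; table$intensity_photon <- 5000
  table$offset_photon <- 1; table$uncertainty_nm <- noise
  dc <- driftCorrect(table, tracks, nF)
  ## corrected fiducial positions: residual RMS below 2x the per-frame
  ## shot-noise floor (two beads averaged: noise/sqrt(2))
  res1 <- dc$table[seq_len(nF), ]
  rms <- sqrt(mean((res1$x_nm - mean(res1$x_nm))^2 +
                   (res1$y_nm - mean(res1$y_nm))^2))
  expect_lt(rms, 2 * noise)
  ## estimated drift tracks the injected drift
  est <- dc$drift
  expect_lt(sd(est[, 1] - drift[, 1]), 1.5)
  ## residuals of the two beads are anti-correlated (shared correction)
  resA <- dc$table$x_nm[seq_len(nF)]
  resB <- dc$table$x_nm[nF + seq_len(nF)]
  expect_lt(cor(resA, resB), 0)
  ## zero drift: correction is a no-op up to smoothing noise
  tr0 <- rbind(mkTrack(1, 1000, 1000)[, ], mkTrack(2, 6000, 2000))
  tr0$x_nm <- tr0$x_nm - drift[rep(seq_len(nF), 2), 1]
  tr0$y_nm <- tr0$y_nm - drift[rep(seq_len(nF), 2), 2]
  tb0 <- tr0[, c("frame", "x_nm", "y_nm")]
  tb0$sigma_nm <- 210; tb0$intensity_photon <- 5000
  tb0$offset_photon <- 1; tb0$uncertainty_nm <- noise
  dc0 <- driftCorrect(tb0, tr0, nF)
  expect_lt(max(abs(dc0$table$x_nm - tb0$x_nm)), 3 * noise)
  ## fiducial gaps longer than the window are an error
  gap <- tracks[tracks$frame <= 100 | tracks$frame > 400, ]
  expect_error(driftCorrect(table, gap, nF, window = 25), "gap")
})

test_that("super-resolution rendering conserves counts and shifts with data", {
  tab <- data.frame(x_nm = c(10, 10, 52, 200), y_nm = c(10, 11, 48, 200))
  img <- renderSr(tab, pixel = 5)
  expect_equal(sum(img), nrow(tab))
  ## translating all rows shifts the image by the same offset
  tab2 <- tab; tab2$x_nm <- tab2$x_nm + 50
  img2 <- renderSr(tab2, pixel = 5, xlim = range(tab$x_nm) + c(-5, 5) + 50,
                   ylim = range(tab$y_nm) + c(-5, 5))
  expect_equal(unname(img2[, 1:ncol(img2)]), unname(img[, 1:ncol(img)]))
  expect_error(renderSr(tab, pixel = 0), "pixel")
})

test_that("site clustering recovers centroids and rejects sparse noise", {
  layout <- defaultOrigamiLayout()
  set.seed(25)
  locs <- do.call(rbind, lapply(seq_len(nrow(layout@sites)), function(s)
    data.frame(x_nm = layout@sites[s, 1] + rnorm(50, 0, 3),
               y_nm = layout@sites[s, 2] + rnorm(50, 0, 3))))
  locs$intensity_photon <- 5000; locs$uncertainty_nm <- 3
  cs <- clusterSites(locs)
  expect_equal(nrow(cs), 8)
  D <- sqrt(outer(cs$x, layout@sites[, 1], "-")^2 +
            outer(cs$y, layout@sites[, 2], "-")^2)
  expect_lt(max(apply(D, 2, min)), 3)
  ## single site
  one <- data.frame(x_nm = rnorm(30, 0, 3), y_nm = rnorm(30, 0, 3))
  expect_equal(nrow(clusterSites(one)), 1)
  ## uniform sparse noise: no dense cluster
  sparse <- data.frame(x_nm = runif(25, -500, 500),
                       y_nm = runif(25, -500, 500))
  expect_error(clusterSites(sparse), "cluster")
})

test_that("pattern registration recovers rotation, identity and mirror poses", {
  layout <- defaultOrigamiLayout()
  rotSites <- function(a, mirror = FALSE) {
    s <- layout@sites
    if (mirror) s[, 1] <- -s[, 1]
    th <- a * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    s %*% t(R)
  }
  mkCents <- function(s) data.frame(x = s[, 1] + 300, y = s[, 2] - 120,
                                    count = 20)
  r345 <- registerPattern(mkCents(rotSites(345)), layout)
  expect_equal(r345@phiOrigami, 345, tolerance = 0.5)
  expect_false(r345@mirror)
  expect_true(r345@registered)
  expect_equal(r345@matched, 8L)
  r0 <- registerPattern(mkCents(rotSites(0)), layout)
  expect_true(abs(r0@phiOrigami) < 0.5 || abs(r0@phiOrigami - 360) < 0.5)
  ## reflected then rotated: mirror recovered, angle agrees with the
  ## brute-force pose oracle
  cm <- mkCents(rotSites(123, mirror = TRUE))
  rm <- registerPattern(cm, layout)
  expect_true(rm@mirror)
  oracle <- brutePose(as.matrix(cm[, c("x", "y")]), layout@sites, res = 0.1)
  expect_true(oracle$mirror)
  expect_equal(rm@phiOrigami, oracle$angle, tolerance = 0.5)
  expect_equal(rm@phiOrigami, 123, tolerance = 0.5)
  expect_error(registerPattern(mkCents(rotSites(0))[1:2, ], layout),
               "at least 3")
})

test_that("registration cost is unambiguous across 36 exact rotations", {
  layout <- defaultOrigamiLayout()
  for (a in seq(0, 350, by = 10)) {
    th <- a * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    cents <- layout@sites %*% t(R)
    costs <- vapply(seq(0, 359, by = 1), function(g)
      DipoleOrigami:::poseCost(cents, layout@sites, g, FALSE)$cost,
      numeric(1))
    trueCost <- DipoleOrigami:::poseCost(cents, layout@sites, a, FALSE)$cost
    away <- abs(((seq(0, 359, by = 1) - a + 180) %% 360) - 180) >= 5
    expect_true(all(costs[away] > trueCost))
  }
})

test_that("localization + drift correction commute with field translation", {
  p <- paintScene(70, frames = 150, seed = 26)
  loc <- localizeFrames(p$sim$stack)
  ft <- identifyFiducials(loc, 150)
  dc <- driftCorrect(loc, ft, 150)
  shifted <- loc
  shifted$x_nm <- shifted$x_nm + 1000
  shifted$y_nm <- shifted$y_nm - 500
  ftS <- identifyFiducials(shifted, 150)
  dcS <- driftCorrect(shifted, ftS, 150)
  expect_equal(dcS$table$x_nm - dc$table$x_nm,
               rep(1000, nrow(loc)), tolerance = 1e-9)
  expect_equal(dcS$table$y_nm - dc$table$y_nm,
               rep(-500, nrow(loc)), tolerance = 1e-9)
})
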