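## Builds a master image containing rendered dipole patterns at given pixel
## positions on a constant background.
masterWith <- function(positions, thetas, phis, fov = 200L,
                       photons = 50000, bg = 10) {
  lib <- sharedLibrary()
  img <- matrix(bg, fov, fov)
  for (i in seq_len(nrow(positions))) {
    pat <- renderDipole(thetas[i], phis[i], 550, lib@optics,
                        photons = photons)@pixels
    ix <- positions[i, 1] + (-25:25); iy <- positions[i, 2] + (-25:25)
    img[ix, iy] <- img[ix, iy] + pat
  }
  img
}

test_that("ROI extraction finds isolated dipoles and applies the overlap rule", {
  lib <- sharedLibrary()
  ## blank frame: nothing found
  blank <- matrix(rpois(150^2, 10), 150, 150)
  expect_equal(nrow(extractROIs(blank, lib)), 0)
  ## five well-separated dipoles recovered within 2 px
  set.seed(14)
  pos <- rbind(c(40, 40), c(40, 150), c(100, 95), c(160, 45), c(155, 160))
  img <- masterWith(pos, thetas = c(0, 30, 60, 90, 45),
                    phis = c(0, 50, 120, 200, 300))
  noisy <- matrix(rpois(length(img), img), nrow(img), ncol(img))
  rois <- extractROIs(noisy, lib)
  expect_equal(nrow(rois), 5)
  D <- sqrt(outer(rois$x, pos[, 1], "-")^2 + outer(rois$y, pos[, 2], "-")^2)
  expect_lt(max(apply(D, 2, min)), 2.01)
  ## two dipoles 10 px apart: both discarded, the isolated one kept
  pos2 <- rbind(c(60, 60), c(60, 70), c(150, 150))
  img2 <- masterWith(pos2, thetas = c(90, 90, 40), phis = c(0, 90, 10))
  noisy2 <- matrix(rpois(length(img2), img2), nrow(img2), ncol(img2))
  rois2 <- extractROIs(noisy2, lib)
  expect_equal(nrow(rois2), 1)
  expect_lt(sqrt((rois2$x - 150)^2 + (rois2$y - 150)^2), 2.01)
})

test_that("time-series segmentation finds switches and bleaches", {
  lib <- sharedLibrary()
  pat1 <- renderDipole(70, 40, 550, lib@optics, photons = 5000)@pixels
  pat2 <- renderDipole(20, 200, 550, lib@optics, photons = 5000)@pixels
  bg <- 2
  mk <- function(pat) matrix(rpois(51^2, pat + bg), 51, 51)
  set.seed(15)
  ## constant-orientation noiseless stack: one segment
  const <- simplify2array(lapply(1:20, function(t) pat1 + bg))
  s <- segmentTimeSeries(const)
  expect_equal(nrow(s), 1)
  expect_equal(s$start, 1)
  expect_equal(s$end, 21)
  expect_equal(s$reason, "end")
  ## switch at frame 40 of 100
  stack <- simplify2array(c(lapply(1:39, function(t) mk(pat1)),
                            lapply(40:100, function(t) mk(pat2))))
  s2 <- segmentTimeSeries(stack)
  expect_equal(nrow(s2), 2)
  expect_lte(abs(s2$end[1] - 40), 1)
  expect_equal(s2$reason, c("switch", "end"))
  ## bleach at frame 60: last segment ends there with reason bleach
  stack3 <- simplify2array(c(lapply(1:59, function(t) mk(pat1)),
                             lapply(60:80, function(t)
                               matrix(rpois(51^2, bg), 51, 51))))
  s3 <- segmentTimeSeries(stack3)
  expect_equal(s3$reason[nrow(s3)], "bleach")
  expect_lte(abs(s3$end[nrow(s3)] - 60), 1)
})

test_that("segment summation is linear and background subtracted", {
  lib <- sharedLibrary()
  pat <- renderDipole(55, 10, 550, lib@optics, photons = 5000)@pixels
  stack <- simplify2array(lapply(1:10, function(t) pat + 7))
  ## border-median background estimation also removes the faint pattern
  ## tail light on the border, so agreement is to a small fraction of peak
  one <- sumSegment(stack, list(start = 1, end = 2))
  expect_lt(max(abs(one@pixels - pat)), 0.01 * max(pat))
  ten <- sumSegment(stack, list(start = 1, end = 11))
  expect_lt(max(abs(ten@pixels - 10 * pat)), 0.01 * max(10 * pat))
  ## linearity: the 10-frame sum equals 10x the 1-frame sum exactly
  expect_equal(ten@pixels, 10 * one@pixels, tolerance = 1e-9)
  expect_error(sumSegment(stack, list(start = 5, end = 5)), "empty")
  ## summing raises SNR at least as sqrt(n)/2 over a single frame
  set.seed(16)
  noisy <- simplify2array(lapply(1:10, function(t)
    matrix(rpois(51^2, pat + 7), 51, 51)))
  snr <- function(img) {
    sig <- img - median(img)
    max(sig) / sd(as.numeric(sig[1:8, 1:8]))
  }
  s1 <- snr(noisy[, , 1] - 7)
  s10 <- snr(sumSegment(noisy, list(start = 1, end = 11))@pixels)
  expect_gte(s10, sqrt(10) / 2 * s1)
})

test_that("dipole fitting is exact on templates and accurate under noise", {
  lib <- sharedLibrary()
  ## self-match on an exact library template
  tmpl <- renderDipole(40, 125, 600, lib@optics, photons = 5000)
  fit <- fitDipole(tmpl, lib, refine = FALSE)
  expect_equal(fit$theta, 40)
  expect_equal(fit$phi, 125)
  expect_equal(fit$defocus, 600)
  expect_gt(fit$score, 0.9999)
  expect_true(fit$accepted)
  ## recovery under Poisson noise at the default budget (worked example
  ## scenario: theta 35, phi 77, 550 nm defocus)
  set.seed(18)
  errs <- replicate(50, {
    img <- renderDipole(35, 77, 550, lib@optics, photons = 5000)@pixels
    noisy <- matrix(rpois(51^2, img + 2), 51, 51)
    f <- fitDipole(noisy, lib)
    c(axisDistance(axisFromAngles(35, 77),
                   axisFromAngles(f$theta, f$phi)),
      abs(f$defocus - 550))
  })
  expect_lte(median(errs[1, ]), 3)
  expect_lte(median(errs[2, ]), 50)
  expect_error(fitDipole(matrix(0, 31, 31), lib), "side")
})

test_that("coarse stage equals exhaustive correlation over the library", {
  lib <- sharedLibrary()
  set.seed(19)
  for (rep in 1:20) {
    th <- runif(1, 0, 90); ph <- runif(1, 0, 360)
    df <- sample(lib@defocusGrid, 1)
    img <- renderDipole(th, ph, df, lib@optics, photons = 3000)@pixels
    v <- as.numeric(matrix(rpois(51^2, img + 2), 51, 51))
    ## brute force: materialize every template and correlate directly
    best <- c(-2, NA, NA, NA)
    for (i in seq_along(lib@defocusGrid)) {
      T <- lib@basis[[i]] %*% lib@quad
      Tc <- sweep(T, 2, colMeans(T))
      vc <- v - mean(v)
      sc <- as.numeric(crossprod(Tc, vc)) /
        (sqrt(colSums(Tc^2)) * sqrt(sum(vc^2)))
      j <- which.max(sc)
      if (sc[j] > best[1]) best <- c(sc[j], i, j, 0)
    }
    nTheta <- length(lib@thetaGrid)
    wantTheta <- lib@thetaGrid[(best[3] - 1) %% nTheta + 1]
    wantPhi <- lib@phiGrid[(best[3] - 1) %/% nTheta + 1]
    wantDef <- lib@defocusGrid[best[2]]
    got <- fitDipole(matrix(v, 51, 51), lib, refine = FALSE)
    expect_equal(got$theta, wantTheta)
    expect_equal(got$phi, wantPhi)
    expect_equal(got$defocus, wantDef)
    expect_equal(got$score, best[1], tolerance = 1e-9)
  }
})

test_that("fits are phi-equivariant, canonical and improve with photons", {
  lib <- sharedLibrary()
  set.seed(20)
  img <- renderDipole(55, 32, 550, lib@optics, photons = 8000)@pixels
  noisy <- matrix(rpois(51^2, img + 2), 51, 51)
  f0 <- fitDipole(noisy, lib)
  rot <- t(noisy)[, 51:1]                   # 90 degree rotation
  f90 <- fitDipole(rot, lib)
  dphi <- abs(((f90$phi - f0$phi - 90 + 180) %% 360) - 180)
  expect_lt(min(dphi, abs(dphi - 180)), 2)  # antipodal-aware
  expect_lte(f0$theta, 90)
  expect_lte(f90$theta, 90)
  ## median recovery error is non-increasing in the photon budget
  meds <- vapply(c(500, 2000, 5000, 20000), function(N) {
    errs <- replicate(12, {
      im <- renderDipole(35, 77, 550, lib@optics, photons = N)@pixels
      nz <- matrix(rpois(51^2, im + 2), 51, 51)
      f <- fitDipole(nz, lib)
      axisDistance(axisFromAngles(35, 77), axisFromAngles(f$theta, f$phi))
    })
    median(errs)
  }, numeric(1))
  expect_true(all(diff(meds) <= 0.5))       # monotone up to MC jitter
  expect_lt(meds[4], meds[1])
})
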