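test_that("axis clustering matches a brute-force single-linkage oracle", {
  set.seed(21)
  ## two bundles 60 degrees apart
  a <- rFisherAxes(6, axisFromAngles(30, 90), 400)
  b <- rFisherAxes(6, axisFromAngles(90, 90), 400)
  axes <- rbind(a, b)
  lab <- clusterAxes(axes, 20)
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:6])), 1)
  expect_equal(length(unique(lab[7:12])), 1)
  ## all axes within 5 degrees form one cluster
  expect_equal(unique(clusterAxes(rFisherAxes(8, c(0, 0, 1), 2000), 20)), 1L)
  ## agreement with the oracle on random small samples (up to labeling)
  for (seed in 1:5) {
    set.seed(seed)
    axes <- rbind(rFisherAxes(4, axisFromAngles(20, 0), 300),
                  rFisherAxes(4, axisFromAngles(80, 200), 300),
                  rFisherAxes(4, axisFromAngles(60, 90), 300))
    got <- clusterAxes(axes, 20)
    want <- bruteSingleLinkage(axes, 20)
    ## same partition: co-membership matrices agree
    expect_identical(outer(got, got, "=="), outer(want, want, "=="))
  }
})

test_that("Kent moment fit recovers isotropic Fisher dispersion", {
  ## kappa = 200 corresponds to a per-axis tangent SD of 4.05 degrees
  ax <- rFisherAxes(10000, axisFromAngles(40, 120), 200, seed = 42)
  fit <- kentFit(ax)
  expect_equal(fit@sigmaX, 4.05, tolerance = 0.15 / 4.05)
  expect_equal(fit@sigmaY, 4.05, tolerance = 0.15 / 4.05)
  expect_equal(fit@kappa, 200, tolerance = 0.1)
  expect_lt(axisDistance(fit@gamma1, axisFromAngles(40, 120)), 0.2)
  ## frame is orthonormal (validity) and antipodal input gives the same fit
  fit2 <- kentFit(-ax)
  expect_equal(abs(sum(fit2@gamma1 * fit@gamma1)), 1, tolerance = 1e-9)
})

test_that("Kent fit handles near-degenerate and anisotropic samples", {
  ## tightly concentrated sample: mean within the jitter scale
  ax <- rFisherAxes(50, c(0, 0, 1), 1 / deg2rad(0.01)^2, seed = 7)
  fit <- kentFit(ax)
  expect_lt(axisDistance(fit@gamma1, c(0, 0, 1)), 0.01)
  ## all identical is degenerate
  same <- matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE)
  expect_error(kentFit(same), "identical")
  expect_error(kentFit(ax[1:2, ]), "at least 3")
  ## anisotropic: known major axis and SDs
  mean <- axisFromAngles(50, 200)
  major <- c(0, 0, 1)
  ax <- rKentAxes(4000, mean, sigmaX = 10, sigmaY = 3, major = major,
                  seed = 9)
  fit <- kentFit(ax)
  expect_equal(fit@sigmaX, 10, tolerance = 0.15)
  expect_equal(fit@sigmaY, 3, tolerance = 0.15)
  ## recovered major tangent axis within 5 degrees of truth
  majTrue <- major - sum(major * mean) * mean
  majTrue <- majTrue / sqrt(sum(majTrue^2))
  ang <- acos(min(1, abs(sum(fit@gamma2 * majTrue)))) * 180 / pi
  expect_lt(ang, 5)
  expect_gt(fit@beta, 0)
  expect_gt(fit@kappa, 2 * fit@beta)
})

test_that("dispersion sigma is the geometric mean of the cone SDs", {
  fitIso <- kentFit(rFisherAxes(2000, c(0, 0, 1), 1 / deg2rad(4.5)^2,
                                seed = 3))
  s <- dispersionSigma(fitIso)
  expect_equal(s, 4.5, tolerance = 0.1)
  expect_true(s >= fitIso@sigmaY && s <= fitIso@sigmaX)
  fitAniso <- kentFit(rKentAxes(4000, c(0, 0, 1), 16, 4, seed = 4))
  expect_equal(dispersionSigma(fitAniso),
               sqrt(fitAniso@sigmaX * fitAniso@sigmaY))
  expect_equal(dispersionSigma(fitAniso), 8, tolerance = 0.5)
})

test_that("Kent frame is equivariant under rotations", {
  ax <- rKentAxes(500, axisFromAngles(30, 40), 8, 3, seed = 12)
  fit <- kentFit(ax)
  th <- deg2rad(53)
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  fitR <- kentFit(ax %*% t(R))
  expect_equal(abs(sum(fitR@gamma1 * (R %*% fit@gamma1))), 1,
               tolerance = 1e-9)
  expect_equal(abs(sum(fitR@gamma2 * (R %*% fit@gamma2))), 1,
               tolerance = 1e-9)
  expect_equal(fitR@sigmaX, fit@sigmaX, tolerance = 1e-9)
  expect_equal(fitR@sigmaY, fit@sigmaY, tolerance = 1e-9)
})

test_that("sigma estimates converge to the generating dispersion", {
  errs <- vapply(c(10, 100, 1000), function(n) {
    s <- vapply(1:20, function(seed)
      dispersionSigma(kentFit(rFisherAxes(n, c(0, 0, 1),
                                          1 / deg2rad(4.5)^2,
                                          seed = 1000 + n + seed))),
      numeric(1))
    abs(mean(s) - 4.5)
  }, numeric(1))
  expect_lt(errs[3], 0.25)
  expect_lt(errs[2], 0.6)
  expect_true(errs[3] <= errs[1] + 0.1)
})

test_that("contamination by destabilized (switching) orientations inflates sigma", {
  sig <- vapply(c(0, 0.25, 0.5), function(f) {
    set.seed(31)
    n <- 400
    nSwitch <- round(f * n)
    stable <- rFisherAxes(n - nSwitch, c(0, 0, 1), 1 / deg2rad(4.5)^2)
    axes <- if (nSwitch > 0)
      rbind(stable, rFisherAxes(nSwitch, c(0, 0, 1), 1 / deg2rad(12)^2))
    else stable
    dispersionSigma(kentFit(axes))
  }, numeric(1))
  expect_true(all(diff(sig) > 0))
})

test_that("circular-linear regression recovers the model line", {
  b <- 5:10
  wrapped <- (285.7 - 35.7 * b) %% 360
  fit <- circularLinearFit(b, wrapped)
  expect_equal(fit$slope, -35.7, tolerance = 1e-9)
  expect_equal(fit$intercept, 285.7, tolerance = 1e-9)
  expect_false(fit$ambiguous)
  ## constant series
  cf <- circularLinearFit(5:9, rep(77, 5))
  expect_equal(cf$slope, 0, tolerance = 1e-12)
  ## noisy line, 100 seeds: the OLS slope error is Gaussian with
  ## SD = 5 / sqrt(sum((b - mean(b))^2)); coverage of the +/- 2 degree
  ## window must match that sampling distribution (within 3 binomial SEs),
  ## and the estimator must be unbiased
  slopes <- vapply(1:100, function(seed) {
    set.seed(seed)
    noisy <- (wrapped + rnorm(6, 0, 5)) %% 360
    circularLinearFit(b, noisy)$slope
  }, numeric(1))
  seSlope <- 5 / sqrt(sum((b - mean(b))^2))
  cover <- 2 * pnorm(2 / seSlope) - 1
  ok <- abs(slopes + 35.7) <= 2
  expect_gte(mean(ok), cover - 3 * sqrt(cover * (1 - cover) / 100))
  expect_equal(mean(slopes), -35.7, tolerance = 3.5 * seSlope / 10)
  expect_error(circularLinearFit(5:6, c(1, 2)), "at least 3")
})

test_that("orientation deltas reproduce the printed stretching changes", {
  gc0 <- list(theta = 14.5, phi = 253.6)
  gc1 <- list(theta = 76.0, phi = 273.1)
  gc8 <- list(theta = 80.8, phi = 190.0)
  d01 <- deltaOrientation(gc0, gc1)
  expect_equal(d01$dTheta, 61.5)
  d18 <- deltaOrientation(gc1, gc8)
  expect_equal(d18$dPhi, -83.1)
  expect_equal(d18$dTheta, 4.8)
  same <- deltaOrientation(gc1, gc1)
  expect_equal(same$dTheta, 0)
  expect_equal(same$dPhi, 0)
  ## dPhi is the signed smallest difference
  expect_equal(deltaOrientation(list(theta = 0, phi = 350),
                                list(theta = 0, phi = 10))$dPhi, 20)
})

test_that("condition summaries report the dominant cluster", {
  set.seed(8)
  main <- rFisherAxes(30, axisFromAngles(30, 90), 1 / deg2rad(4)^2)
  minor <- rFisherAxes(5, axisFromAngles(120, 90), 1 / deg2rad(4)^2)
  cs <- conditionSummary(rbind(main, minor), "8TT")
  expect_equal(cs$n_clusters, 2)
  expect_equal(cs$n_axes, 35)
  expect_equal(cs$theta_mean, 30, tolerance = 2)
  expect_equal(cs$sigma, 4, tolerance = 1.2)
})
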