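## Synthetic experiment generator: defocused dipole movies and DNA-PAINT
## movies with gold-bead fiducials, stage drift, EMCCD noise and full
## ground-truth tables, so every inference stage can be tested against known
## truth without any real data.

#' Construct kinetics parameters
#'
#' Defaults emulate a 3 nM imager concentration at 300 ms PAINT frames
#' (mean bright time ~1.5 frames, mean dark time ~50 frames per docking
#' site) and clean, slowly-switching dipoles in the 2 s channel.
#'
#' @param meanBright mean PAINT binding (bright) time, s.
#' @param meanDark mean dark time per docking site, s.
#' @param paintPhotons expected photons per fully-bright PAINT frame.
#' @param dipolePhotons expected photons per dipole frame.
#' @param bleachHazard per-dipole-frame bleaching probability.
#' @param switchProb per-dipole-frame orientation-switch probability.
#' @return a [KineticsParams-class].
#' @export
kineticsParams <- function(meanBright = 0.6, meanDark = 15,
                           paintPhotons = 5000, dipolePhotons = 5000,
                           bleachHazard = 0.003, switchProb = 0.002) {
  new("KineticsParams", meanBright = meanBright, meanDark = meanDark,
      paintPhotons = paintPhotons, dipolePhotons = dipolePhotons,
      bleachHazard = bleachHazard, switchProb = switchProb)
}

#' Construct an EMCCD camera model
#'
#' @param gain electron-multiplying gain (100 default).
#' @param readNoise read noise SD, output electrons.
#' @param sensitivity output electrons per ADU.
#' @param baseline baseline offset, ADU.
#' @param exposureDipole,exposurePaint exposures, s.
#' @return a [CameraModel-class].
#' @export
cameraModel <- function(gain = 100, readNoise = 30, sensitivity = 60,
                        baseline = 100, exposureDipole = 2,
                        exposurePaint = 0.3) {
  new("CameraModel", gain = gain, readNoise = readNoise,
      sensitivity = sensitivity, baseline = baseline,
      exposureDipole = exposureDipole, exposurePaint = exposurePaint)
}

#' Apply EMCCD shot noise, multiplication noise and read noise
#'
#' Photoelectrons are Poisson; electron multiplication follows the standard
#' gamma approximation Gamma(shape = n, scale = gain); Gaussian read noise
#' and the baseline offset are added and the result converted to ADU.
#'
#' @param photons matrix of expected photons per pixel.
#' @param camera a [CameraModel-class].
#' @return matrix of ADU counts (continuous; quantized on TIFF export).
#' @export
applyCamera <- function(photons, camera) {
  dm <- dim(photons)
  n <- stats::rpois(length(photons), as.numeric(photons))
  out <- numeric(length(n))
  pos <- n > 0L
  out[pos] <- stats::rgamma(sum(pos), shape = n[pos], scale = camera@gain)
  out <- out + stats::rnorm(length(n), 0, camera@readNoise)
  array(camera@baseline + out / camera@sensitivity, dm)
}

#' Default asymmetric docking-site layout
#'
#' Eight docking sites in an L-plus-offset arrangement spanning the ~90 x 70
#' nm origami rectangle. The pattern has no nontrivial rotational symmetry
#' (including under mirroring), so registration of the super-resolved
#' pattern is unambiguous; all pairwise spacings are >= 10 nm.
#'
#' @return an [OrigamiLayout-class].
#' @export
defaultOrigamiLayout <- function() {
  sites <- rbind(c(-40, -28), c(-12, -33), c(14, -25), c(38, -32),
                 c(-37, -3), c(-42, 24), c(3, 6), c(27, 14))
  colnames(sites) <- c("x", "y")
  new("OrigamiLayout", width = 90, height = 70, sites = sites,
      dyeXY = c(15, -10))
}

## Orientation center axis of a model prediction: intercalation predictions
## carry the equatorial wrap angle with phi = 90, which axisFromAngles maps
## to the correct YZ direction for the full circle.
predictionAxis <- function(prediction) {
  axisFromAngles(prediction@thetaModel, prediction@phiModel)
}

#' Draw a ground-truth orientation about a model prediction
#'
#' Adds isotropic Kent (Fisher) scatter with per-axis angular SD
#' \code{sigmaTruth} around the geometric-model orientation, giving the
#' statistical pipeline a known truth distribution.
#'
#' @param prediction a [ModelPrediction-class].
#' @param sigmaTruth per-axis angular SD, degrees (0 = exactly the model).
#' @param seed optional integer seed (draw is reproducible given the seed).
#' @return list with \code{theta}, \code{phi} (degrees) and \code{axis}.
#' @export
sampleOrientation <- function(prediction, sigmaTruth, seed = NULL) {
  if (sigmaTruth < 0) stop("sigmaTruth must be >= 0")
  center <- predictionAxis(prediction)
  ax <- if (sigmaTruth == 0) center
        else as.numeric(rFisherAxes(1, center, 1 / deg2rad(sigmaTruth)^2,
                                    seed = seed))
  ang <- anglesFromAxis(ax)
  list(theta = ang$theta, phi = ang$phi, axis = ax)
}

#' Simulate a defocused dipole movie
#'
#' Each frame is the sum of the defocused patterns of the unbleached dyes at
#' their current orientations, fiducial spots and a constant photon
#' background, passed through the EMCCD noise chain. Orientations are
#' piecewise constant: per frame each dye may bleach (hazard) or switch to a
#' fresh Kent draw about its condition center. Dye positions are snapped to
#' pixel centers (position is not the measurand in this channel).
#'
#' @param dyes data.frame with columns \code{x}, \code{y} (nm, FOV origin at
#'   the corner), \code{theta}, \code{phi} (initial orientation, degrees),
#'   \code{centerTheta}, \code{centerPhi}, \code{sigmaTruth} (switch
#'   redraw distribution; defaults to the initial orientation with 0 SD).
#' @param optics an [OpticsConfig-class].
#' @param camera a [CameraModel-class].
#' @param kinetics a [KineticsParams-class].
#' @param frames number of frames (>= 1).
#' @param fov field-of-view side, pixels.
#' @param defocus stage defocus, nm.
#' @param fiducials data.frame with \code{x}, \code{y} (nm), \code{photons};
#'   NULL for none.
#' @param bgPhotons background photons per pixel per frame.
#' @param seed integer RNG seed.
#' @return list with \code{stack} (fov x fov x frames array, ADU),
#'   \code{truth} (list: \code{segments} data.frame (dye, start, end, theta,
#'   phi), \code{dyes} with pixel-snapped positions, \code{bleachFrame}).
#' @export
simulateDdiMovie <- function(dyes, optics = opticsConfig(),
                             camera = cameraModel(),
                             kinetics = kineticsParams(), frames = 100,
                             fov = 128L, defocus = 550,
                             fiducials = NULL, bgPhotons = 2, seed = 1) {
  if (frames < 1) stop("need at least one frame")
  set.seed(seed)
  side <- 51L
  pitch <- optics@pixelPitch
  ndye <- nrow(dyes)
  if (ndye >= 2L) {
    d <- as.matrix(stats::dist(dyes[, c("x", "y")]))
    diag(d) <- Inf
    if (min(d) < side * pitch)
      stop("layout error: dyes closer than one ROI (",
           side * pitch, " nm)")
  }
  if (ndye > 0) {
    if (is.null(dyes$sigmaTruth)) dyes$sigmaTruth <- 0
    if (is.null(dyes$centerTheta)) { dyes$centerTheta <- dyes$theta
                                     dyes$centerPhi <- dyes$phi }
  }
  ## snap to pixel centers (pixel i covers [(i-1)*pitch, i*pitch))
  px <- as.integer(floor(dyes$x / pitch)) + 1L
  py <- as.integer(floor(dyes$y / pitch)) + 1L
  half <- (side - 1L) %/% 2L
  if (ndye > 0 && (any(px <= half) || any(px > fov - half) ||
                   any(py <= half) || any(py > fov - half)))
    stop("dye ROI extends beyond the field of view")

  basis <- if (ndye > 0) dipoleBasis(optics, defocus, side) else NULL
  pattern <- function(theta, phi) {
    I <- as.numeric(basis$B %*% as.numeric(quadCoef(theta, phi)))
    I[I < 0] <- 0
    matrix(kinetics@dipolePhotons * I / sum(I), side, side)
  }
  pats <- lapply(seq_len(ndye),
                 function(i) pattern(dyes$theta[i], dyes$phi[i]))
  curTheta <- dyes$theta; curPhi <- dyes$phi
  alive <- rep(TRUE, ndye)
  segStart <- rep(1L, ndye)
  segs <- NULL
  bleachFrame <- rep(NA_integer_, ndye)
  stack <- array(0, c(fov, fov, frames))

  for (t in seq_len(frames)) {
    if (t > 1L && ndye > 0) for (i in seq_len(ndye)) {
      if (!alive[i]) next
      if (stats::runif(1) < kinetics@bleachHazard) {
        segs <- rbind(segs, data.frame(dye = i, start = segStart[i], end = t,
                                       theta = curTheta[i], phi = curPhi[i]))
        alive[i] <- FALSE
        bleachFrame[i] <- t
      } else if (stats::runif(1) < kinetics@switchProb) {
        segs <- rbind(segs, data.frame(dye = i, start = segStart[i], end = t,
                                       theta = curTheta[i], phi = curPhi[i]))
        ax <- rFisherAxes(1, axisFromAngles(dyes$centerTheta[i],
                                            dyes$centerPhi[i]),
                          1 / deg2rad(max(dyes$sigmaTruth[i], 1e-3))^2)
        ang <- anglesFromAxis(as.numeric(ax))
        curTheta[i] <- ang$theta; curPhi[i] <- ang$phi
        pats[[i]] <- pattern(curTheta[i], curPhi[i])
        segStart[i] <- t
      }
    }
    fr <- matrix(bgPhotons, fov, fov)
    if (ndye > 0) for (i in seq_len(ndye)) {
      if (!alive[i]) next
      fr[(px[i] - half):(px[i] + half), (py[i] - half):(py[i] + half)] <-
        fr[(px[i] - half):(px[i] + half), (py[i] - half):(py[i] + half)] +
        pats[[i]]
    }
    if (!is.null(fiducials)) for (f in seq_len(nrow(fiducials))) {
      fr <- stampGaussian(fr, fiducials$x[f] - (fov / 2) * pitch,
                          fiducials$y[f] - (fov / 2) * pitch,
                          210, fiducials$photons[f], pitch)
    }
    stack[, , t] <- fr
  }
  stack <- applyCamera(stack, camera)
  if (ndye > 0) for (i in seq_len(ndye)) {
    if (alive[i])
      segs <- rbind(segs, data.frame(dye = i, start = segStart[i],
                                     end = frames + 1L,
                                     theta = curTheta[i], phi = curPhi[i]))
  }
  dyes$px <- px; dyes$py <- py
  dyes$xSnap <- (px - 0.5) * pitch; dyes$ySnap <- (py - 0.5) * pitch
  list(stack = stack,
       truth = list(segments = segs, dyes = dyes,
                    bleachFrame = bleachFrame, defocus = defocus))
}

## Random-walk plus linear stage drift, nm, frames x 2.
makeDrift <- function(frames, sigmaStep = 0.5, linear = c(0.05, 0.02),
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  steps <- cbind(stats::rnorm(frames, 0, sigmaStep),
                 stats::rnorm(frames, 0, sigmaStep))
  drift <- apply(steps, 2, cumsum) +
    outer(seq_len(frames) - 1L, linear)
  drift - matrix(drift[1, ], frames, 2, byrow = TRUE)
}

#' Simulate a DNA-PAINT movie
#'
#' Imager binding at each docking site alternates exponential dark and
#' bright intervals in continuous time; bright emitters are rendered as
#' integrated-Gaussian spots (photons scaled by the bright fraction of each
#' frame) at drifted positions, fiducials are always on, and the EMCCD
#' noise chain is applied per frame.
#'
#' @param origamis data.frame with columns \code{x}, \code{y} (nm, template
#'   center in FOV coordinates), \code{phiOrigami} (degrees), and optional
#'   \code{mirror} (logical).
#' @param layout an [OrigamiLayout-class].
#' @param kinetics a [KineticsParams-class].
#' @param optics an [OpticsConfig-class] (green channel: set
#'   \code{wavelength} accordingly; only the pixel pitch matters here).
#' @param camera a [CameraModel-class].
#' @param frames number of frames (>= 100).
#' @param drift frames x 2 drift trajectory in nm, or NULL to generate the
#'   default random-walk + linear drift, or FALSE for no drift.
#' @param fiducials data.frame with \code{x}, \code{y} (nm), \code{photons}.
#' @param fov field-of-view side, pixels.
#' @param psfSigma in-focus PSF Gaussian SD, nm.
#' @param bgPhotons background photons per pixel per frame.
#' @param seed integer RNG seed.
#' @return list with \code{stack} (ADU array), \code{truth} (list:
#'   \code{events} data.frame (origami, site, frame, fraction, x, y),
#'   \code{drift}, \code{sites} true undrifted site positions,
#'   \code{fiducials}).
#' @export
simulatePaintMovie <- function(origamis, layout = defaultOrigamiLayout(),
                               kinetics = kineticsParams(),
                               optics = opticsConfig(wavelength = 580),
                               camera = cameraModel(), frames = 5000,
                               drift = NULL, fiducials = NULL, fov = 64L,
                               psfSigma = 210, bgPhotons = 1, seed = 1) {
  if (frames < 100) stop("need at least 100 frames")
  set.seed(seed)
  pitch <- optics@pixelPitch
  exposure <- camera@exposurePaint
  if (isFALSE(drift)) drift <- matrix(0, frames, 2)
  if (is.null(drift)) drift <- makeDrift(frames)
  if (nrow(drift) < frames) stop("drift trajectory shorter than the movie")

  ## absolute docking-site positions per origami
  siteTab <- NULL
  for (i in seq_len(nrow(origamis))) {
    s <- layout@sites
    if (isTRUE(origamis$mirror[i])) s[, 1] <- -s[, 1]
    a <- deg2rad(origamis$phiOrigami[i])
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    sr <- s %*% t(R)
    siteTab <- rbind(siteTab, data.frame(
      origami = i, site = seq_len(nrow(s)),
      x = sr[, 1] + origamis$x[i], y = sr[, 2] + origamis$y[i]))
  }

  ## continuous-time binding events per site
  tTotal <- frames * exposure
  evList <- list()
  ne <- 0L
  for (r in seq_len(nrow(siteTab))) {
    t <- 0
    while (t < tTotal) {
      t0 <- t + stats::rexp(1, 1 / kinetics@meanDark)
      t1 <- t0 + stats::rexp(1, 1 / kinetics@meanBright)
      if (t0 >= tTotal) break
      f0 <- floor(t0 / exposure) + 1
      f1 <- min(floor(min(t1, tTotal - 1e-12) / exposure) + 1, frames)
      for (f in f0:f1) {
        lo <- (f - 1) * exposure; hi <- f * exposure
        frac <- (min(t1, hi) - max(t0, lo)) / exposure
        if (frac > 0) {
          ne <- ne + 1L
          evList[[ne]] <- c(siteTab$origami[r], siteTab$site[r], f, frac,
                            siteTab$x[r], siteTab$y[r])
        }
      }
      t <- t1
    }
  }
  events <- if (ne == 0L) NULL else {
    m <- do.call(rbind, evList)
    data.frame(origami = as.integer(m[, 1]), site = as.integer(m[, 2]),
               frame = as.integer(m[, 3]), fraction = m[, 4],
               x = m[, 5], y = m[, 6])
  }

  center <- (fov / 2) * pitch
  stack <- array(0, c(fov, fov, frames))
  evByFrame <- if (is.null(events)) list()
               else split(events, events$frame)
  for (t in seq_len(frames)) {
    fr <- matrix(bgPhotons, fov, fov)
    ev <- evByFrame[[as.character(t)]]
    if (!is.null(ev)) for (e in seq_len(nrow(ev))) {
      fr <- stampGaussian(fr, ev$x[e] + drift[t, 1] - center,
                          ev$y[e] + drift[t, 2] - center,
                          psfSigma, kinetics@paintPhotons * ev$fraction[e],
                          pitch)
    }
    if (!is.null(fiducials)) for (f in seq_len(nrow(fiducials))) {
      fr <- stampGaussian(fr, fiducials$x[f] + drift[t, 1] - center,
                          fiducials$y[f] + drift[t, 2] - center,
                          psfSigma, fiducials$photons[f], pitch)
    }
    stack[, , t] <- fr
  }
  stack <- applyCamera(stack, camera)
  list(stack = stack,
       truth = list(events = events, drift = drift[seq_len(frames), ,
                                                   drop = FALSE],
                    sites = siteTab, fiducials = fiducials))
}
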