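## Dipole-channel inference: ROI extraction from a master image, time-series
## segmentation at orientation switches / bleaching, frame summation, and
## orientation + defocus estimation by template-library matching with local
## refinement.

#' Build a dipole template library
#'
#' Renders the six quadratic basis images per defocus plane and precomputes
#' the normalized-correlation statistics of every (theta, phi) template on
#' the angular grid, so the coarse search is an exhaustive correlation over
#' the whole library at negligible cost.
#'
#' @param optics an [OpticsConfig-class].
#' @param thetaStep,phiStep angular grid steps, degrees.
#' @param defocusGrid defocus planes, nm (200-1000 nm by 50 nm default).
#' @param side template side, pixels (odd).
#' @return a [DipoleLibrary-class].
#' @export
makeDipoleLibrary <- function(optics = opticsConfig(), thetaStep = 5,
                              phiStep = 5,
                              defocusGrid = seq(200, 1000, by = 50),
                              side = 51L) {
  thetaGrid <- seq(0, 90, by = thetaStep)
  phiGrid <- seq(0, 360 - phiStep, by = phiStep)
  ang <- expand.grid(theta = thetaGrid, phi = phiGrid)
  Q <- t(quadCoef(ang$theta, ang$phi))          # 6 x nAngles
  npix <- as.numeric(side)^2
  basis <- vector("list", length(defocusGrid))
  tmean <- vector("list", length(defocusGrid))
  tsd <- vector("list", length(defocusGrid))
  for (i in seq_along(defocusGrid)) {
    bas <- dipoleBasis(optics, defocusGrid[i], side)
    B <- bas$B
    basis[[i]] <- B
    mB <- colMeans(B)
    M <- crossprod(B)
    tm <- as.numeric(mB %*% Q)
    tss <- colSums(Q * (M %*% Q))
    tmean[[i]] <- tm
    tsd[[i]] <- sqrt(pmax(tss - npix * tm^2, 1e-300))
  }
  new("DipoleLibrary", basis = basis, defocusGrid = defocusGrid,
      thetaGrid = thetaGrid, phiGrid = phiGrid, quad = Q,
      templateMean = tmean, templateSd = tsd, side = as.integer(side),
      optics = optics)
}

## Basis matrix at an arbitrary defocus: linear interpolation between the
## library's defocus planes (clamped to the grid range).
interpBasis <- function(library, defocus) {
  dg <- library@defocusGrid
  if (defocus <= dg[1]) return(library@basis[[1]])
  k <- length(dg)
  if (defocus >= dg[k]) return(library@basis[[k]])
  i <- findInterval(defocus, dg)
  w <- (defocus - dg[i]) / (dg[i + 1] - dg[i])
  (1 - w) * library@basis[[i]] + w * library@basis[[i + 1]]
}

## Mean-subtracted normalized correlation of an image vector with a
## template vector.
nccVec <- function(v, t) {
  vc <- v - mean(v); tc <- t - mean(t)
  s <- sqrt(sum(vc^2) * sum(tc^2))
  if (s < 1e-300) return(0)
  sum(vc * tc) / s
}

#' Fit dipole orientation and defocus to a summed pattern
#'
#' Two stages: an exhaustive normalized cross-correlation over the library's
#' (theta, phi, defocus) grid, then Nelder-Mead refinement of the continuous
#' correlation (with the basis interpolated across defocus) started at the
#' coarse optimum. Correlation after mean subtraction makes the fit
#' invariant to amplitude scaling and constant background, so only the three
#' physical parameters are searched. The result is reported with the
#' antipodal representative theta in [0, 90].
#'
#' @param image a [DipoleImage-class] or plain matrix matching the library
#'   side.
#' @param library a [DipoleLibrary-class].
#' @param tauAccept acceptance threshold on the correlation score.
#' @param refine logical; skip the refinement stage if FALSE.
#' @return list with \code{theta}, \code{phi}, \code{defocus}, \code{score},
#'   \code{accepted}.
#' @export
fitDipole <- function(image, library, tauAccept = 0.7, refine = TRUE) {
  px <- if (is(image, "DipoleImage")) image@pixels else image
  if (nrow(px) != library@side || ncol(px) != library@side)
    stop("image side does not match the library template side")
  v <- as.numeric(px)
  npix <- length(v)
  vbar <- mean(v)
  vc <- v - vbar
  vnorm <- sqrt(sum(vc^2))
  if (vnorm < 1e-300) stop("image has no contrast")

  best <- c(score = -2, i = NA, j = NA)
  for (i in seq_along(library@defocusGrid)) {
    proj <- as.numeric(crossprod(library@basis[[i]], v))   # 6-vector
    num <- as.numeric(proj %*% library@quad) -
      npix * vbar * library@templateMean[[i]]
    sc <- num / (vnorm * library@templateSd[[i]])
    j <- which.max(sc)
    if (sc[j] > best["score"]) best <- c(score = sc[j], i = i, j = j)
  }
  nTheta <- length(library@thetaGrid)
  jj <- as.integer(best["j"])
  theta <- library@thetaGrid[(jj - 1L) %% nTheta + 1L]
  phi <- library@phiGrid[(jj - 1L) %/% nTheta + 1L]
  defocus <- library@defocusGrid[as.integer(best["i"])]
  score <- as.numeric(best["score"])

  if (refine) {
    dg <- range(library@defocusGrid)
    obj <- function(p) {
      d <- min(max(p[3], dg[1]), dg[2])
      B <- interpBasis(library, d)
      t <- as.numeric(B %*% as.numeric(quadCoef(p[1], p[2])))
      -nccVec(v, t)
    }
    op <- stats::optim(c(theta, phi, defocus), obj, method = "Nelder-Mead",
                       control = list(maxit = 400, reltol = 1e-8))
    ca <- canonicalizeAngles(op$par[1], op$par[2])
    theta <- ca$theta; phi <- ca$phi
    defocus <- min(max(op$par[3], dg[1]), dg[2])
    score <- -op$value
  }
  list(theta = theta, phi = phi, defocus = defocus, score = score,
       accepted = score >= tauAccept)
}

## Orientation-isotropic template (average over dipole orientations) at one
## defocus: the matched filter used for detection.
isotropicTemplate <- function(library, defocus = stats::median(library@defocusGrid)) {
  B <- interpBasis(library, defocus)
  matrix(as.numeric(B %*% c(1, 1, 1, 0, 0, 0) / 3),
         library@side, library@side)
}

## FFT cross-correlation of an image with a (smaller, odd-sided) kernel,
## zero-padded, returning a map the size of the image with the kernel
## centered.
xcorr2 <- function(img, kern) {
  n <- dim(img); m <- dim(kern)
  N <- n + m
  A <- matrix(0, N[1], N[2]); A[seq_len(n[1]), seq_len(n[2])] <- img
  K <- matrix(0, N[1], N[2])
  K[seq_len(m[1]), seq_len(m[2])] <- kern[m[1]:1, m[2]:1]
  cc <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) /
    prod(N)
  h <- (m - 1L) %/% 2L
  cc[h[1] + seq_len(n[1]), h[2] + seq_len(n[2])]
}

#' Detect dipole ROIs in a master image
#'
#' Matched-filter detection: the master image (background subtracted) is
#' correlated with the orientation-averaged dipole template, whose
#' autocorrelation has a single sharp peak per emitter even though the
#' defocused patterns themselves are multi-lobed. Local maxima above
#' median + k * MAD of the correlation map become ROI centers; ROIs that
#' would overlap (centers closer than one ROI side) are discarded, as are
#' ROIs extending beyond the image.
#'
#' @param master 2D master image (typically the sum of initial frames).
#' @param library a [DipoleLibrary-class] (provides the matched filter and
#'   the ROI side).
#' @param k detection threshold in robust SDs of the correlation map.
#' @return data.frame with columns \code{x}, \code{y} (pixel indices of ROI
#'   centers); zero rows when nothing is found.
#' @export
extractROIs <- function(master, library, k = 8) {
  side <- library@side
  half <- (side - 1L) %/% 2L
  bg <- stats::median(master)
  kern <- isotropicTemplate(library)
  cc <- xcorr2(master - bg, kern - mean(kern))
  thr <- stats::median(cc) + k * stats::mad(cc)
  n <- dim(master)
  cand <- NULL
  ## local maxima in a 5x5 neighborhood above threshold
  for (i in 3:(n[1] - 2)) for (j in 3:(n[2] - 2)) {
    w <- cc[(i - 2):(i + 2), (j - 2):(j + 2)]
    if (cc[i, j] > thr && cc[i, j] == max(w))
      cand <- rbind(cand, c(i, j, cc[i, j]))
  }
  if (is.null(cand)) return(data.frame(x = integer(), y = integer()))
  ## merge plateau duplicates closer than 6 px (same emitter), keep brighter
  ord <- order(-cand[, 3])
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (a in seq_len(nrow(cand))) {
    if (!keep[a]) next
    if (a < nrow(cand)) for (b in (a + 1):nrow(cand)) {
      if (keep[b] &&
          sqrt(sum((cand[a, 1:2] - cand[b, 1:2])^2)) < 6) keep[b] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  ## overlap rule: any two ROIs closer than one side are both discarded
  nc <- nrow(cand)
  ok <- rep(TRUE, nc)
  if (nc >= 2L) for (a in 1:(nc - 1)) for (b in (a + 1):nc) {
    if (sqrt(sum((cand[a, 1:2] - cand[b, 1:2])^2)) < side) {
      ok[a] <- FALSE; ok[b] <- FALSE
    }
  }
  cand <- cand[ok, , drop = FALSE]
  ## ROIs must fit inside the image
  inb <- cand[, 1] > half & cand[, 1] <= n[1] - half &
         cand[, 2] > half & cand[, 2] <= n[2] - half
  cand <- cand[inb, , drop = FALSE]
  data.frame(x = as.integer(cand[, 1]), y = as.integer(cand[, 2]))
}

#' Cut an ROI stack out of a movie
#'
#' @param movie 3D array (x, y, frame) or list of frames.
#' @param center length-2 pixel index of the ROI center.
#' @param side ROI side, pixels (odd).
#' @return side x side x frames array.
#' @export
roiStack <- function(movie, center, side = 51L) {
  if (is.list(movie)) movie <- simplify2array(movie)
  half <- (side - 1L) %/% 2L
  movie[(center[1] - half):(center[1] + half),
        (center[2] - half):(center[2] + half), , drop = FALSE]
}

roiBorderStats <- function(frame) {
  n <- nrow(frame)
  border <- c(frame[1, ], frame[n, ], frame[, 1], frame[, n])
  c(baseline = stats::median(border), noise = stats::mad(border))
}

#' Segment a dipole ROI time series
#'
#' Splits the series at orientation changes and truncates at bleaching.
#' A switch is declared when the correlation of a frame against the running
#' segment sum drops for two consecutive frames; bleaching when the
#' background-subtracted mean ROI intensity falls below 3x the photometric
#' noise floor. Two correlation gates are combined: the mean-subtracted
#' normalized correlation of lightly smoothed frames (robust, but dominated
#' by the shared donut-shaped envelope of all defocused patterns) must drop
#' below 0.95, and the correlation of the radial-residual images (the
#' azimuthal anisotropy that actually encodes orientation; uninformative
#' only for near-axial dipoles, which the first gate covers) must drop
#' below \code{tauSwitch}.
#'
#' @param stack side x side x frames ROI array.
#' @param tauSwitch switch threshold on the radial-residual correlation.
#' @return data.frame with columns \code{start}, \code{end} (half-open
#'   frame interval), \code{meanIntensity}, \code{reason} (switch, bleach or
#'   end).
#' @export
segmentTimeSeries <- function(stack, tauSwitch = 0.8) {
  nf <- dim(stack)[3]
  side <- dim(stack)[1]
  ## correlate lightly smoothed frames: the defocused pattern is wide, so a
  ## 1.5 px blur raises the per-pixel SNR of single frames without washing
  ## out orientation differences
  K <- smoothMatrix(side, 1.5)
  blur <- function(m) K %*% m %*% t(K)
  c0 <- (side + 1) / 2
  rIdx <- round(sqrt(outer((seq_len(side) - c0)^2,
                           (seq_len(side) - c0)^2, "+")))
  radialResid <- function(m) {
    mu <- tapply(m, rIdx, mean)
    m - matrix(mu[as.character(rIdx)], side, side)
  }
  ## background-subtracted mean intensity per frame
  m <- numeric(nf)
  for (t in seq_len(nf)) {
    fr <- stack[, , t]
    m[t] <- mean(fr) - roiBorderStats(fr)["baseline"]
  }
  ## photometric noise floor of the per-frame mean intensity
  noise <- stats::mad(diff(m)) / sqrt(2)
  bright <- m > 3 * max(noise, 1e-12)
  bleachAt <- if (all(bright)) nf + 1L else which(!bright)[1]
  if (bleachAt == 1L)
    return(data.frame(start = integer(), end = integer(),
                      meanIntensity = numeric(), reason = character()))
  segs <- NULL
  s <- 1L
  S <- blur(stack[, , 1])
  low <- 0L
  t <- 2L
  while (t < bleachAt) {
    bt <- blur(stack[, , t])
    rBlur <- nccVec(as.numeric(bt), as.numeric(S))
    rRad <- nccVec(as.numeric(radialResid(bt)),
                   as.numeric(radialResid(S)))
    if (rBlur < 0.95 && rRad < tauSwitch) low <- low + 1L else low <- 0L
    if (low >= 2L) {
      cut <- t - 1L                     # first low frame starts the new state
      segs <- rbind(segs, data.frame(start = s, end = cut,
                                     meanIntensity = mean(m[s:(cut - 1L)]),
                                     reason = "switch"))
      s <- cut
      S <- blur(stack[, , cut] + stack[, , t])
      low <- 0L
    } else if (low == 0L) {
      S <- S + blur(stack[, , t])
    }
    t <- t + 1L
  }
  lastEnd <- bleachAt
  reason <- if (bleachAt <= nf) "bleach" else "end"
  segs <- rbind(segs, data.frame(start = s, end = lastEnd,
                                 meanIntensity = mean(m[s:(lastEnd - 1L)]),
                                 reason = reason))
  segs
}

#' Sum a segment of an ROI stack
#'
#' Pixelwise sum of the segment's frames with the summed border median
#' subtracted (the photometric background of the summed pattern).
#'
#' @param stack side x side x frames ROI array.
#' @param segment one row of [segmentTimeSeries()] output (or a list with
#'   \code{start}, \code{end}).
#' @return a [DipoleImage-class] (defocus unknown, set to NA).
#' @export
sumSegment <- function(stack, segment) {
  if (segment$end <= segment$start) stop("empty segment")
  idx <- segment$start:(segment$end - 1L)
  S <- apply(stack[, , idx, drop = FALSE], c(1, 2), sum)
  S <- S - roiBorderStats(S)["baseline"]
  new("DipoleImage", pixels = pmax(S, 0), pixelPitch = NA_real_,
      defocus = NA_real_, photons = sum(S))
}
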