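## Vectorial forward model of a fixed-dipole emitter near a glass/water
## interface imaged through a high-NA oil objective with defocus.
##
## Route: the dipole's plane-wave spectrum is propagated through the
## interface (Fresnel transmission, including the supercritical/evanescent
## components allowed by NA > n_sample), apodized for an aplanatic
## objective, given the defocus phase, and transformed from the back focal
## plane to the image plane with an FFT; the intensity is the squared field
## magnitude summed over the two transverse polarization components.
##
## The image intensity is a quadratic form in the dipole-moment components,
## so six real basis images (xx, yy, zz, xy, xz, yz) per defocus reproduce
## any orientation by linear combination; this is what the template library
## caches.

#' Construct an imaging configuration
#'
#' @param na numerical aperture (default 1.49, TIRF oil objective).
#' @param nImmersion immersion oil / coverslip index (1.515).
#' @param nSample sample medium index (1.33, aqueous buffer).
#' @param wavelength emission wavelength in nm (670 for the red channel).
#' @param pixelPitch camera pixel pitch at the sample in nm (16 um EMCCD
#'   pixel behind 100x magnification = 160 nm).
#' @param emitterHeight dye height above the coverslip, nm.
#' @param pupilN FFT grid side (numerical accuracy/speed knob).
#' @return an [OpticsConfig-class].
#' @export
opticsConfig <- function(na = 1.49, nImmersion = 1.515, nSample = 1.33,
                         wavelength = 670, pixelPitch = 160,
                         emitterHeight = 5, pupilN = 256L) {
  new("OpticsConfig", na = na, nImmersion = nImmersion, nSample = nSample,
      wavelength = wavelength, pixelPitch = pixelPitch,
      emitterHeight = emitterHeight, pupilN = as.integer(pupilN))
}

fftshift2 <- function(m) {
  n <- nrow(m)
  h <- n %/% 2
  idx <- c((h + 1):n, 1:h)
  m[idx, idx]
}

## Back-focal-plane Cartesian field components for unit dipoles along
## x, y, z. Returns a list of six complex N x N matrices Ex.px .. Ey.pz.
bfpFields <- function(optics, defocus) {
  N <- optics@pupilN
  lambda <- optics@wavelength
  n1 <- optics@nSample; n2 <- optics@nImmersion
  k0 <- 2 * pi / lambda
  dx <- optics@pixelPitch
  dk <- 2 * pi / (N * dx)
  idx <- (seq_len(N) - 1L) - N %/% 2
  kx <- matrix(idx * dk, N, N)
  ky <- t(kx)
  kr <- sqrt(kx^2 + ky^2)
  ## anti-aliased aperture: boundary cells weighted by fractional coverage
  ## (one-cell linear ramp) so the Cartesian sampling of the sharp pupil
  ## edge converges at second rather than first order
  mask <- pmin(1, pmax(0, (k0 * optics@na - kr) / dk + 0.5))
  ## angles in the immersion medium (real) and the sample medium (complex
  ## beyond the critical angle)
  st2 <- pmin(kr / (k0 * n2), 1)
  ct2 <- sqrt(pmax(0, 1 - st2^2))
  st1 <- n2 * st2 / n1
  ct1 <- sqrt(as.complex(1 - st1^2))      # +i sqrt(st1^2-1) when supercritical
  cpsi <- ifelse(kr > 0, kx / pmax(kr, 1e-300), 1)
  spsi <- ifelse(kr > 0, ky / pmax(kr, 1e-300), 0)
  ## Fresnel transmission sample -> immersion
  ts <- 2 * n1 * ct1 / (n1 * ct1 + n2 * ct2)
  tp <- 2 * n1 * ct1 / (n2 * ct1 + n1 * ct2)
  ## common factor: emitter-height phase (decaying for evanescent waves),
  ## defocus phase, aplanatic apodization, pupil mask
  amp <- mask * exp(1i * k0 * n1 * ct1 * optics@emitterHeight) *
    exp(1i * k0 * n2 * ct2 * defocus) / sqrt(pmax(ct2, 1e-6))
  ## s/p amplitudes per unit dipole component, then Cartesian image-plane
  ## components (the tube lens maps p -> radial, s -> tangential)
  Es.px <- -ts * spsi;        Ep.px <- tp * ct1 * cpsi
  Es.py <- ts * cpsi;         Ep.py <- tp * ct1 * spsi
  Es.pz <- 0;                 Ep.pz <- -tp * st1
  mk <- function(Ep, Es) list(Ex = amp * (Ep * cpsi - Es * spsi),
                              Ey = amp * (Ep * spsi + Es * cpsi))
  px <- mk(Ep.px, Es.px); py <- mk(Ep.py, Es.py); pz <- mk(Ep.pz, Es.pz)
  list(Ex.px = px$Ex, Ey.px = px$Ey, Ex.py = py$Ex, Ey.py = py$Ey,
       Ex.pz = pz$Ex, Ey.pz = pz$Ey)
}

## Image-plane basis of the quadratic form I(mu) for one defocus.
## Returns list(B = npix x 6 matrix [xx,yy,zz,xy,xz,yz], fullEnergy =
## length-6 quadratic coefficients of the total (uncropped) energy).
dipoleBasis <- function(optics, defocus, side = 51L) {
  side <- as.integer(side)
  if (side %% 2L == 0L) stop("image side length must be odd")
  N <- optics@pupilN
  if (side > N) stop("image side exceeds the pupil grid")
  f <- bfpFields(optics, defocus)
  img <- function(P) fftshift2(stats::fft(fftshift2(P), inverse = TRUE))
  Gx <- list(img(f$Ex.px), img(f$Ey.px))
  Gy <- list(img(f$Ex.py), img(f$Ey.py))
  Gz <- list(img(f$Ex.pz), img(f$Ey.pz))
  c0 <- N %/% 2 + 1L
  h <- (side - 1L) %/% 2L
  rng <- (c0 - h):(c0 + h)
  cross <- function(A, B)
    Re(A[[1]] * Conj(B[[1]]) + A[[2]] * Conj(B[[2]]))
  full <- function(A, B) sum(cross(A, B))
  crop <- function(M) as.numeric(M[rng, rng])
  B <- cbind(xx = crop(cross(Gx, Gx)), yy = crop(cross(Gy, Gy)),
             zz = crop(cross(Gz, Gz)), xy = crop(cross(Gx, Gy)),
             xz = crop(cross(Gx, Gz)), yz = crop(cross(Gy, Gz)))
  fullEnergy <- c(full(Gx, Gx), full(Gy, Gy), full(Gz, Gz),
                  full(Gx, Gy), full(Gx, Gz), full(Gy, Gz))
  list(B = B, fullEnergy = fullEnergy)
}

## Quadratic coefficient vector of a dipole orientation: I = B %*% quadCoef.
quadCoef <- function(theta, phi) {
  mu <- axisFromAngles(theta, phi)
  if (is.null(dim(mu))) mu <- matrix(mu, ncol = 3)
  cbind(mu[, 1]^2, mu[, 2]^2, mu[, 3]^2,
        2 * mu[, 1] * mu[, 2], 2 * mu[, 1] * mu[, 3], 2 * mu[, 2] * mu[, 3])
}

#' Render a defocused dipole image
#'
#' @param theta,phi dipole orientation, degrees (polar from the optical
#'   axis, azimuth from the image X axis).
#' @param defocus defocus distance in nm, within [0, 2000].
#' @param optics an [OpticsConfig-class].
#' @param photons expected photon count (> 0).
#' @param side image side length, pixels (odd; 51 default).
#' @param normalize if TRUE (default) the cropped image sums exactly to
#'   \code{photons}; if FALSE the full (uncropped) image plane carries
#'   \code{photons} and the crop contains whatever fraction falls inside,
#'   which decreases with defocus.
#' @return a [DipoleImage-class].
#' @examples
#' img <- renderDipole(35, 77, defocus = 550)
#' @export
renderDipole <- function(theta, phi, defocus, optics = opticsConfig(),
                         photons = 5000, side = 51L, normalize = TRUE) {
  if (defocus < 0 || defocus > 2000)
    stop("defocus must lie in [0, 2000] nm")
  if (photons <= 0) stop("photons must be positive")
  bas <- dipoleBasis(optics, defocus, side)
  q <- quadCoef(theta, phi)
  I <- as.numeric(bas$B %*% t(q))
  I[I < 0] <- 0                       # clip tiny negative FFT residue
  scale <- if (normalize) sum(I) else sum(bas$fullEnergy * as.numeric(q))
  px <- matrix(photons * I / scale, side, side)
  new("DipoleImage", pixels = px, pixelPitch = optics@pixelPitch,
      defocus = defocus, photons = photons)
}

#' Render an in-focus Gaussian spot
#'
#' Integrated-Gaussian pixel model used for PAINT imagers and fiducial
#' beads: each pixel receives the bivariate normal mass over its area, and
#' the grid is renormalized to the requested photon count.
#'
#' @param x,y spot center relative to the grid center, nm.
#' @param sigma Gaussian SD, nm.
#' @param photons expected photons (> 0).
#' @param side grid side, pixels (odd).
#' @param pixelPitch pixel pitch, nm.
#' @return a [DipoleImage-class] (defocus 0).
#' @export
renderGaussianSpot <- function(x, y, sigma, photons = 1000, side = 15L,
                               pixelPitch = 160) {
  if (sigma <= 0) stop("sigma must be positive")
  if (photons <= 0) stop("photons must be positive")
  side <- as.integer(side)
  if (side %% 2L == 0L) stop("side must be odd")
  h <- (side - 1L) / 2
  edges <- (seq(-h, h + 1L) - 0.5) * pixelPitch
  mx <- diff(stats::pnorm(edges, mean = x, sd = sigma))
  my <- diff(stats::pnorm(edges, mean = y, sd = sigma))
  px <- outer(mx, my)
  px <- photons * px / sum(px)
  new("DipoleImage", pixels = px, pixelPitch = pixelPitch, defocus = 0,
      photons = photons)
}

## Raw (matrix) variant used by the movie simulators: spot centered at
## (x, y) nm in the frame of an arbitrary image, stamped additively.
stampGaussian <- function(img, x, y, sigma, photons, pixelPitch) {
  n <- dim(img)
  cx <- (n[1] + 1) / 2
  ix <- x / pixelPitch + cx
  iy <- y / pixelPitch + cx
  half <- max(5L, ceiling(4 * sigma / pixelPitch))
  i0 <- max(1L, floor(ix) - half); i1 <- min(n[1], floor(ix) + half)
  j0 <- max(1L, floor(iy) - half); j1 <- min(n[2], floor(iy) + half)
  if (i0 > i1 || j0 > j1) return(img)
  ex <- ((i0 - 1):(i1)) + 0.5 - ix   # pixel edges in pixel units
  ey <- ((j0 - 1):(j1)) + 0.5 - iy
  s <- sigma / pixelPitch
  mx <- diff(stats::pnorm(ex, sd = s))
  my <- diff(stats::pnorm(ey, sd = s))
  img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + photons * outer(mx, my)
  img
}
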