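## Angle helpers shared across the package. All user-facing angles are in
## degrees; radians only appear inside numerics.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to [0, 360)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval [0, 360).
#' @export
wrapAngle360 <- function(x) {
  y <- x %% 360
  y[y < 0] <- y[y < 0] + 360
  ## guard against 360 - eps rounding
  y[abs(y - 360) < 1e-12] <- 0
  y
}

#' Signed smallest angular difference
#'
#' Maps a difference of angles to the signed representative in (-180, 180].
#'
#' @param x numeric vector of angle differences in degrees.
#' @return signed differences in (-180, 180].
#' @export
wrapAngle180 <- function(x) {
  y <- wrapAngle360(x)
  y[y > 180] <- y[y > 180] - 360
  y
}

#' Unit axis from spherical angles
#'
#' Spherical convention used throughout: \code{theta} is the polar angle from
#' +Z (the optical axis), \code{phi} the azimuth from +X in the XY plane.
#'
#' @param theta polar angle, degrees.
#' @param phi azimuthal angle, degrees.
#' @return a unit 3-vector (or 3-column matrix for vector input).
#' @export
axisFromAngles <- function(theta, phi) {
  th <- deg2rad(theta); ph <- deg2rad(phi)
  v <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  if (length(theta) == 1L) drop(v) else v
}

#' Spherical angles from a 3-vector
#'
#' @param v unit 3-vector or 3-column matrix of axes.
#' @return list with \code{theta} and \code{phi} in degrees, \code{phi} in
#'   [0, 360).
#' @export
anglesFromAxis <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  n <- sqrt(rowSums(v^2))
  if (any(n < 1e-300)) stop("zero vector has no direction")
  v <- v / n
  theta <- rad2deg(acos(pmin(1, pmax(-1, v[, 3]))))
  phi <- wrapAngle360(rad2deg(atan2(v[, 2], v[, 1])))
  list(theta = theta, phi = phi)
}

#' Geodesic distance between axes
#'
#' Antipodal-aware angular distance between undirected axes (transition
#' dipole moments are only defined up to sign): the angle between the lines,
#' in [0, 90] degrees per pair.
#'
#' @param a,b unit 3-vectors or matching 3-column matrices.
#' @return angular distances in degrees.
#' @export
axisDistance <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  a <- a / sqrt(rowSums(a^2)); b <- b / sqrt(rowSums(b^2))
  d <- abs(rowSums(a * b))
  rad2deg(acos(pmin(1, d)))
}

#' Canonical antipodal representative
#'
#' Returns the representative of an undirected axis with z >= 0 (ties broken
#' by y >= 0, then x >= 0). Idempotent.
#'
#' @param v unit 3-vector or 3-column matrix.
#' @return same shape as input, canonicalized.
#' @export
canonicalizeAxis <- function(v) {
  vec <- is.null(dim(v))
  if (vec) v <- matrix(v, ncol = 3)
  n <- sqrt(rowSums(v^2))
  if (any(n < 1e-300)) stop("zero vector cannot be canonicalized")
  v <- v / n
  flip <- v[, 3] < 0 |
    (v[, 3] == 0 & v[, 2] < 0) |
    (v[, 3] == 0 & v[, 2] == 0 & v[, 1] < 0)
  v[flip, ] <- -v[flip, , drop = FALSE]
  if (vec) drop(v) else v
}

#' Canonical antipodal representative in angles
#'
#' @param theta,phi spherical angles in degrees.
#' @return list with \code{theta} in [0, 90] and \code{phi} in [0, 360).
#' @export
canonicalizeAngles <- function(theta, phi) {
  anglesFromAxis(canonicalizeAxis(axisFromAngles(theta, phi)))
}

## Sequentially unwrap a wrapped angle series assuming |step| < period/2.
## period = 360 for directed angles, 180 for axes (theta and theta+180 are
## the same axis in the equatorial wrap).
unwrapSeries <- function(x, period = 360) {
  if (length(x) < 2L) return(x)
  out <- x
  for (i in 2:length(x)) {
    d <- (x[i] - out[i - 1]) %% period
    if (d > period / 2) d <- d - period
    out[i] <- out[i - 1] + d
  }
  out
}
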