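## Composition of the absolute dye orientation in the origami frame, and the
## equatorial full-circle wrap representation used for the model line.

#' Compose the absolute orientation in the origami frame
#'
#' The dipole fit yields (theta_dipole, phi_dipole) in camera coordinates and
#' the DNA-PAINT registration yields the in-plane template rotation
#' phi_origami; the absolute orientation relative to the template is
#' theta = theta_dipole and phi = phi_dipole - phi_origami (mod 360).
#'
#' @param thetaDipole,phiDipole dipole-fit angles, degrees.
#' @param phiOrigami template in-plane rotation, degrees.
#' @return list with \code{theta}, \code{phi} (degrees, phi in [0, 360)).
#' @examples
#' toOrigamiFrame(35, 77, 345)  # theta 35, phi 92
#' @export
toOrigamiFrame <- function(thetaDipole, phiDipole, phiOrigami) {
  stopifnot(is.finite(thetaDipole), is.finite(phiDipole), is.finite(phiOrigami))
  list(theta = thetaDipole, phi = wrapAngle360(phiDipole - phiOrigami))
}

#' Equatorial full-circle wrap angle
#'
#' For axes close to the YZ plane traversing a full revolution (the
#' intercalation series), the polar angle alone folds at the poles. The wrap
#' angle Theta = atan2(y, z) in [0, 360) parameterizes the full circle: on
#' the phi = 90 branch Theta = theta, on the phi = 270 branch
#' Theta = 360 - theta.
#'
#' @param theta,phi spherical angles in degrees, or \code{theta} may be a
#'   unit 3-vector (then \code{phi} is ignored).
#' @return Theta in degrees, [0, 360).
#' @export
equatorialAngle <- function(theta, phi = NULL) {
  v <- if (length(theta) == 3L && is.null(phi)) theta
       else axisFromAngles(theta, phi)
  if (abs(v[1]) / sqrt(sum(v^2)) >= 0.999)
    stop("axis is (nearly) parallel to X; equatorial wrap angle undefined")
  wrapAngle360(rad2deg(atan2(v[2], v[3])))
}

#' Axis from an equatorial wrap angle
#'
#' Inverse of [equatorialAngle()] for YZ-plane axes.
#'
#' @param Theta wrap angle, degrees.
#' @return unit 3-vector (0, sin Theta, cos Theta).
#' @export
axisFromEquatorial <- function(Theta) {
  t <- deg2rad(Theta)
  c(0, sin(t), cos(t))
}
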