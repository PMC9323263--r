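## Kent (Fisher-Bingham) directional statistics for sets of measured
## transition-dipole axes: antipodal-aware clustering, moment estimation of
## the mean direction and elliptical-cone dispersions, the scalar dispersion
## sigma = sqrt(sigma_x* sigma_y*), circular-linear regression and
## between-condition orientation changes.

#' Cluster axes by geodesic distance
#'
#' Single-linkage agglomerative clustering on the antipodal-aware geodesic
#' distance between axes, cut at a threshold. A sample of dyes can contain
#' more than one stable orientation cluster.
#'
#' @param axes n x 3 matrix of (not necessarily unit) axes.
#' @param threshold geodesic cut height, degrees.
#' @return integer cluster labels (1 = largest cluster).
#' @export
clusterAxes <- function(axes, threshold = 20) {
  if (is.null(dim(axes))) axes <- matrix(axes, ncol = 3)
  n <- nrow(axes)
  if (n < 1L) stop("need at least one axis")
  if (n == 1L) return(1L)
  u <- axes / sqrt(rowSums(axes^2))
  d <- rad2deg(acos(pmin(abs(tcrossprod(u)), 1)))
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  lab <- stats::cutree(hc, h = threshold)
  ## relabel by decreasing cluster size
  ord <- order(-tabulate(lab))
  match(lab, ord)
}

## Align antipodal signs so all axes point into the hemisphere of the
## dominant scatter eigenvector.
alignAxes <- function(axes) {
  u <- axes / sqrt(rowSums(axes^2))
  e <- eigen(crossprod(u) / nrow(u), symmetric = TRUE)$vectors[, 1]
  s <- sign(u %*% e)
  s[s == 0] <- 1
  u * as.vector(s)
}

#' Moment fit of the Kent (Fisher-Bingham) distribution
#'
#' Deterministic moment estimation for a sample of axes: antipodal signs are
#' aligned to the dominant scatter eigenvector; the mean direction gamma1 is
#' the normalized resultant; the tangent-plane second-moment
#' eigen-decomposition gives the major/minor cone axes gamma2, gamma3 and the
#' angular SDs sigma_x* >= sigma_y* (degrees); kappa and beta follow from the
#' standard resultant/eigenvalue moment formulas.
#'
#' @param axes n x 3 matrix of axes, n >= 3, not all identical.
#' @return a [KentFit-class].
#' @examples
#' ax <- rFisherAxes(200, c(0, 0, 1), kappa = 200, seed = 1)
#' kentFit(ax)
#' @export
kentFit <- function(axes) {
  if (is.null(dim(axes))) axes <- matrix(axes, ncol = 3)
  n <- nrow(axes)
  if (n < 3L) stop("Kent fit requires at least 3 axes")
  u <- alignAxes(axes)
  m <- colMeans(u)
  rbar <- sqrt(sum(m^2))
  if (1 - rbar < 1e-12)
    stop("axes are (numerically) all identical; dispersion undefined")
  g1 <- m / rbar

  ## arbitrary tangent basis perpendicular to g1
  ref <- if (abs(g1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  uvec <- ref - sum(ref * g1) * g1
  uvec <- uvec / sqrt(sum(uvec^2))
  vvec <- c(g1[2] * uvec[3] - g1[3] * uvec[2],
            g1[3] * uvec[1] - g1[1] * uvec[3],
            g1[1] * uvec[2] - g1[2] * uvec[1])

  ## log map: tangent coordinates with norm = geodesic angle
  ca <- pmin(1, pmax(-1, u %*% g1))
  ang <- acos(ca)
  tu <- u %*% uvec
  tv <- u %*% vvec
  tn <- sqrt(tu^2 + tv^2)
  scale <- ifelse(tn < 1e-15, 1, ang / tn)
  tc <- cbind(tu, tv) * as.vector(scale)

  S <- crossprod(tc) / n
  es <- eigen(S, symmetric = TRUE)
  sigmaX <- rad2deg(sqrt(max(es$values[1], 1e-20)))
  sigmaY <- rad2deg(sqrt(max(es$values[2], 1e-20)))
  g2 <- es$vectors[1, 1] * uvec + es$vectors[2, 1] * vvec
  g3 <- es$vectors[1, 2] * uvec + es$vectors[2, 2] * vvec
  ## right-handed frame
  cr <- c(g1[2] * g2[3] - g1[3] * g2[2],
          g1[3] * g2[1] - g1[1] * g2[3],
          g1[1] * g2[2] - g1[2] * g2[1])
  if (sum(cr * g3) < 0) g3 <- -g3

  ## standard Kent moment estimators from the resultant and the eigenvalue
  ## split of the second-moment matrix in the fitted frame
  W <- t(rbind(g1, g2, g3) %*% t(u)) # n x 3, coords in fitted frame
  r2 <- mean(W[, 2]^2) - mean(W[, 3]^2)
  r2 <- max(0, min(r2, 2 - 2 * rbar - 1e-12))
  kappa <- 1 / (2 - 2 * rbar - r2) + 1 / (2 - 2 * rbar + r2)
  beta <- 0.5 * (1 / (2 - 2 * rbar - r2) - 1 / (2 - 2 * rbar + r2))
  beta <- max(0, min(beta, kappa / 2 * (1 - 1e-9)))

  new("KentFit", gamma1 = as.numeric(g1), gamma2 = as.numeric(g2),
      gamma3 = as.numeric(g3), kappa = kappa, beta = beta,
      sigmaX = sigmaX, sigmaY = sigmaY, n = as.integer(n))
}

#' Scalar angular dispersion of a Kent fit
#'
#' The single +/- dispersion reported per condition: the geometric mean
#' sigma = sqrt(sigma_x* sigma_y*) of the elliptical-cone SDs (which carries
#' units of degrees, and reduces to the common value for a circular cone).
#'
#' @param fit a [KentFit-class].
#' @return sigma in degrees.
#' @export
dispersionSigma <- function(fit) {
  if (fit@sigmaX <= 0 || fit@sigmaY <= 0)
    stop("dispersions must be positive")
  sqrt(fit@sigmaX * fit@sigmaY)
}

#' Circular-linear regression of the wrap angle on attachment position
#'
#' Sequentially unwraps a wrapped angle series (assuming |step| < period/2
#' between consecutive positions) and fits an ordinary least-squares line.
#' Measured dipole axes are antipodally symmetric, so their wrap angles live
#' on a 180-degree circle; use \code{period = 180} for fitted axes and 360
#' for model predictions with a known branch.
#'
#' @param bValues numeric covariate (attachment positions).
#' @param thetaWraps wrapped angles, degrees.
#' @param period wrap period, 360 (directed) or 180 (axes).
#' @return list with \code{slope} (deg/base), \code{intercept} (degrees,
#'   wrapped), \code{residualSD} (degrees) and \code{ambiguous} (TRUE when a
#'   step came close to period/2 and the unwrap is unreliable).
#' @export
circularLinearFit <- function(bValues, thetaWraps, period = 360) {
  if (length(bValues) < 3L) stop("need at least 3 points")
  ord <- order(bValues)
  b <- bValues[ord]
  un <- unwrapSeries(thetaWraps[ord] %% period, period)
  steps <- diff(un)
  ambiguous <- any(abs(steps) > 0.45 * period)
  fit <- stats::lm(un ~ b)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = wrapAngle360(unname(stats::coef(fit)[1])),
       residualSD = stats::sd(stats::residuals(fit)),
       ambiguous = ambiguous)
}

#' Orientation change between two condition summaries
#'
#' @param a,b lists (or one-row data.frames) with elements/columns
#'   \code{theta} and \code{phi} in degrees.
#' @return list with \code{dTheta} (plain difference theta_b - theta_a) and
#'   \code{dPhi} (signed smallest azimuthal difference, in (-180, 180]).
#' @examples
#' deltaOrientation(list(theta = 14.5, phi = 253.6),
#'                  list(theta = 76.0, phi = 273.1))
#' @export
deltaOrientation <- function(a, b) {
  list(dTheta = b$theta - a$theta,
       dPhi = wrapAngle180(b$phi - a$phi))
}

#' Summarize measured axes per condition
#'
#' Clusters the axes ([clusterAxes()]), fits a Kent distribution to the
#' dominant cluster and tabulates the per-condition summary used in the
#' report stage.
#'
#' @param axes n x 3 matrix of measured axes.
#' @param design condition label.
#' @param clusterThreshold geodesic clustering cut, degrees.
#' @return one-row data.frame with columns design, n_axes, theta_mean,
#'   phi_mean, sigma, sigma_x, sigma_y, kappa, beta, n_clusters.
#' @export
conditionSummary <- function(axes, design = "", clusterThreshold = 20) {
  if (is.null(dim(axes))) axes <- matrix(axes, ncol = 3)
  lab <- clusterAxes(axes, clusterThreshold)
  main <- axes[lab == 1L, , drop = FALSE]
  fit <- kentFit(main)
  mean <- anglesFromAxis(canonicalizeAxis(fit@gamma1))
  data.frame(design = design, n_axes = nrow(axes),
             theta_mean = mean$theta, phi_mean = mean$phi,
             sigma = dispersionSigma(fit), sigma_x = fit@sigmaX,
             sigma_y = fit@sigmaY, kappa = fit@kappa, beta = fit@beta,
             n_clusters = max(lab))
}

## ---------------------------------------------------------------------------
## Samplers
## ---------------------------------------------------------------------------

#' Sample axes from the Fisher (isotropic Kent) distribution
#'
#' Exact inverse-CDF sampling of the von Mises-Fisher distribution on the
#' sphere. For large kappa the per-tangent-component angular SD is
#' 1/sqrt(kappa) radians.
#'
#' @param n number of draws.
#' @param mean unit mean axis.
#' @param kappa concentration (> 0).
#' @param seed optional integer seed (local RNG state).
#' @return n x 3 matrix of unit axes.
#' @export
rFisherAxes <- function(n, mean, kappa, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  mean <- mean / sqrt(sum(mean^2))
  u <- stats::runif(n)
  ## cos(colatitude) about the mean; numerically stable form
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  w <- pmin(1, pmax(-1, w))
  psi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  ## orthonormal frame around the mean
  ref <- if (abs(mean[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * mean) * mean
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mean[2] * e1[3] - mean[3] * e1[2],
          mean[3] * e1[1] - mean[1] * e1[3],
          mean[1] * e1[2] - mean[2] * e1[1])
  outer(w, mean) + outer(s * cos(psi), e1) + outer(s * sin(psi), e2)
}

#' Sample axes with anisotropic (Kent-like) scatter
#'
#' Draws tangent-plane Gaussian deviations with SDs sigmaX/sigmaY (degrees)
#' along the given major axis and maps them to the sphere by the exponential
#' map. For small dispersions this matches the Kent distribution with
#' kappa = (sx^2 + sy^2) / (2 sx^2 sy^2), beta = (sx^2 - sy^2) /
#' (4 sx^2 sy^2) (radians).
#'
#' @param n number of draws.
#' @param mean unit mean axis.
#' @param sigmaX,sigmaY tangent SDs in degrees (sigmaX along \code{major}).
#' @param major optional unit tangent direction of the major axis.
#' @param seed optional integer seed.
#' @return n x 3 matrix of unit axes.
#' @export
rKentAxes <- function(n, mean, sigmaX, sigmaY = sigmaX, major = NULL,
                      seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  mean <- mean / sqrt(sum(mean^2))
  ref <- if (abs(mean[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * mean) * mean
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mean[2] * e1[3] - mean[3] * e1[2],
          mean[3] * e1[1] - mean[1] * e1[3],
          mean[1] * e1[2] - mean[2] * e1[1])
  if (!is.null(major)) {
    major <- major - sum(major * mean) * mean
    major <- major / sqrt(sum(major^2))
    minor <- c(mean[2] * major[3] - mean[3] * major[2],
               mean[3] * major[1] - mean[1] * major[3],
               mean[1] * major[2] - mean[2] * major[1])
    e1 <- major; e2 <- minor
  }
  tx <- stats::rnorm(n, 0, deg2rad(sigmaX))
  ty <- stats::rnorm(n, 0, deg2rad(sigmaY))
  ang <- sqrt(tx^2 + ty^2)
  dirx <- ifelse(ang < 1e-15, 0, tx / pmax(ang, 1e-15))
  diry <- ifelse(ang < 1e-15, 0, ty / pmax(ang, 1e-15))
  outer(cos(ang), mean) +
    outer(sin(ang) * dirx, e1) + outer(sin(ang) * diry, e2)
}
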