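## Idealized B-form duplex geometry and the two geometric orientation models:
## dye intercalation between the flanking base pairs, and two-tether
## stretching across n unpaired bases.

#' Construct helical parameters
#'
#' Defaults are the canonical B-form values used by the geometric models:
#' 35.7 deg/base twist (the value that reproduces the model line over the
#' attachment positions), 0.34 nm/base rise, 0.94 nm backbone radius and a
#' 131.4 deg strand phase offset.
#'
#' @param twist degrees per base step.
#' @param rise nm per base step.
#' @param backboneRadius nm.
#' @param strandPhaseOffset degrees.
#' @param handedness +1 or -1.
#' @return a [HelicalParams-class] object.
#' @examples
#' defaultHelicalParams()
#' @export
defaultHelicalParams <- function(twist = 35.7, rise = 0.34,
                                 backboneRadius = 0.94,
                                 strandPhaseOffset = 131.4,
                                 handedness = 1) {
  new("HelicalParams", twist = twist, rise = rise,
      backboneRadius = backboneRadius, strandPhaseOffset = strandPhaseOffset,
      handedness = handedness)
}

#' Construct a dye attachment design
#'
#' @param b integer attachment position (bases from the common crossover).
#' @param flank5,flank3 flanking base identities at the 5' and 3' side.
#' @param strandSign +1 (5'->3' along +X) or -1 (mirrored strand, along -X).
#' @param n stretching level: number of unpaired adenines opposite the dye.
#' @return a [DesignSpec-class] object.
#' @examples
#' designSpec(8, "T", "T")     # the 8TT design
#' designSpec(6, "G", "C", n = 4)  # 6GC/4
#' @export
designSpec <- function(b, flank5 = "T", flank3 = "T", strandSign = 1, n = 0) {
  new("DesignSpec", b = as.integer(b), flank5 = flank5, flank3 = flank3,
      strandSign = strandSign, n = as.integer(n))
}

#' Parse a design label such as "8TT", "-7GC" or "6GC/3"
#'
#' @param label character label in the bMN, -bMN or bMN/n nomenclature.
#' @return a [DesignSpec-class] object.
#' @export
parseDesign <- function(label) {
  m <- regmatches(label,
                  regexec("^(-?)(\\d+)([ACGT])([ACGT])(?:/(\\d+))?$", label))[[1]]
  if (length(m) == 0L) stop("cannot parse design label: ", label)
  designSpec(as.integer(m[3]), m[4], m[5],
             strandSign = if (m[2] == "-") -1 else 1,
             n = if (m[6] == "") 0L else as.integer(m[6]))
}

#' Label for a design
#'
#' @param design a [DesignSpec-class].
#' @return character label in the bMN(/n) nomenclature.
#' @export
designLabel <- function(design) {
  paste0(if (design@strandSign < 0) "-" else "", design@b,
         design@flank5, design@flank3,
         if (design@n > 0L) paste0("/", design@n) else "")
}

#' Build an idealized B-form duplex
#'
#' Places one representative attachment sugar carbon per nucleotide on a
#' rigid straight helix along +X. Base pair i (0-based) sits at axial
#' position i * rise; its strand-1 carbon at phase angle
#' phase0 + handedness * twist * i and its strand-2 carbon offset by
#' handedness * strandPhaseOffset, both at radius backboneRadius in the YZ
#' plane (phase measured from +Y towards +Z).
#'
#' @param params a [HelicalParams-class].
#' @param basePairCount number of base pairs (>= 2).
#' @param phase0 phase angle of base pair 0, degrees.
#' @return a [DuplexModel-class].
#' @examples
#' buildDuplex(defaultHelicalParams(), 16)
#' @export
buildDuplex <- function(params, basePairCount, phase0 = 0) {
  validObject(params)
  basePairCount <- as.integer(basePairCount)
  if (basePairCount < 2L) stop("basePairCount must be >= 2")
  i <- seq_len(basePairCount) - 1L
  axial <- i * params@rise
  phase <- phase0 + params@handedness * params@twist * i
  r <- params@backboneRadius
  a1 <- deg2rad(phase)
  a2 <- deg2rad(phase + params@handedness * params@strandPhaseOffset)
  coords1 <- cbind(axial, r * cos(a1), r * sin(a1))
  coords2 <- cbind(axial, r * cos(a2), r * sin(a2))
  colnames(coords1) <- colnames(coords2) <- c("x", "y", "z")
  new("DuplexModel", params = params, phase0 = phase0,
      basePairCount = basePairCount, axial = axial,
      phase = wrapAngle360(phase), coords1 = coords1, coords2 = coords2)
}

## Mirror a duplex through the YZ plane (x -> -x). An improper reflection:
## the mirrored helix has opposite handedness. Used for the mirrored-strand
## (-bMN) designs whose 5'->3' direction runs along -X.
mirrorDuplex <- function(duplex) {
  p <- duplex@params
  pm <- defaultHelicalParams(p@twist, p@rise, p@backboneRadius,
                             p@strandPhaseOffset, -p@handedness)
  d <- buildDuplex(pm, duplex@basePairCount, duplex@phase0)
  d@coords1[, 1] <- -d@coords1[, 1]
  d@coords2[, 1] <- -d@coords2[, 1]
  d@axial <- -d@axial
  d
}

checkBpIndex <- function(duplex, bpIndex) {
  if (any(bpIndex < 0L) || any(bpIndex > duplex@basePairCount - 1L))
    stop("base-pair index out of range (0..", duplex@basePairCount - 1L, ")")
}

#' Unit vector across a base pair
#'
#' The unit vector from the strand-1 attachment sugar carbon to the strand-2
#' attachment sugar carbon of one base pair. Both carbons share the base
#' pair's axial position, so the vector lies in the YZ plane.
#'
#' @param duplex a [DuplexModel-class].
#' @param bpIndex 0-based base-pair index.
#' @return unit 3-vector.
#' @export
flankingPairVector <- function(duplex, bpIndex) {
  checkBpIndex(duplex, bpIndex)
  v <- duplex@coords2[bpIndex + 1L, ] - duplex@coords1[bpIndex + 1L, ]
  v / sqrt(sum(v^2))
}

## Full-circle angle of a YZ-plane vector, matching equatorialAngle().
yzAngle <- function(v) unname(wrapAngle360(rad2deg(atan2(v[2], v[3]))))

#' Calibrate the duplex phase origin
#'
#' The angular origin of the helix at the crossover is not fixed by the
#' helical parameters; it is calibrated once so that the intercalation
#' model's equatorial wrap angle at a reference attachment position matches a
#' reference value (default: Theta(b = 5) = 107.2 deg), then held fixed for
#' every design.
#'
#' @param params a [HelicalParams-class].
#' @param bRef reference attachment position.
#' @param thetaRef target wrap angle at \code{bRef}, degrees.
#' @return phase0 in degrees.
#' @export
calibratePhase0 <- function(params, bRef = 5, thetaRef = 107.2) {
  thetaAt <- function(phase0) {
    d <- buildDuplex(params, bRef + 2L, phase0)
    v1 <- flankingPairVector(d, bRef)
    v2 <- flankingPairVector(d, bRef + 1L)
    m <- v1 + v2
    yzAngle(m / sqrt(sum(m^2)))
  }
  t0 <- thetaAt(0)
  s <- wrapAngle180(thetaAt(1) - t0)    # +1 or -1 depending on handedness
  wrapAngle360(s * (thetaRef - t0))
}

#' Build the default calibrated duplex
#'
#' Convenience wrapper: default helical parameters and the calibrated phase
#' origin (see [calibratePhase0()]).
#'
#' @param basePairCount number of base pairs (16 in the template design;
#'   increase for large stretching levels).
#' @param params a [HelicalParams-class].
#' @return a [DuplexModel-class].
#' @export
calibratedDuplex <- function(basePairCount = 16, params = defaultHelicalParams()) {
  buildDuplex(params, basePairCount, calibratePhase0(params))
}

#' Intercalation-model orientation prediction
#'
#' The dye intercalated between base pairs b and b+1 is predicted to lie
#' along the normalized mean of the two flanking-base-pair vectors: a YZ
#' plane direction reported as the equatorial full-circle wrap angle Theta
#' (in \code{thetaModel}) with \code{phiModel} = 90. With the default
#' calibrated duplex, Theta(b) = 285.7 - 35.7 b (mod 360).
#'
#' @param duplex a [DuplexModel-class] (use [calibratedDuplex()] for the
#'   default calibration).
#' @param design a [DesignSpec-class] with \code{n} = 0.
#' @return a [ModelPrediction-class].
#' @examples
#' intercalationOrientation(calibratedDuplex(), designSpec(8, "T", "T"))
#' @export
intercalationOrientation <- function(duplex, design) {
  if (design@n != 0L)
    stop("intercalation model applies to unstretched designs (n = 0)")
  if (design@strandSign < 0) duplex <- mirrorDuplex(duplex)
  b <- design@b
  checkBpIndex(duplex, c(b, b + 1L))
  v1 <- flankingPairVector(duplex, b)
  v2 <- flankingPairVector(duplex, b + 1L)
  m <- v1 + v2
  if (sqrt(sum(m^2)) < 1e-12)
    stop("flanking vectors are antiparallel; mean direction undefined")
  m <- m / sqrt(sum(m^2))
  stopifnot(abs(m[1]) < 1e-9)           # construction: YZ-plane direction
  new("ModelPrediction", thetaModel = yzAngle(m), phiModel = 90,
      stretchX = 0)
}

#' Stretching-model orientation prediction
#'
#' For a dye stretched across n unpaired bases, the model orientation is the
#' vector from the 5' attachment sugar carbon at base pair b to the 3'
#' attachment carbon at base pair b+1+n (both on the dye-bearing strand),
#' reported as plain polar/azimuthal angles. The added axial stretching
#' distance is n * rise; as n grows the vector aligns with the helix axis
#' (phi -> 0, theta -> 90).
#'
#' @param duplex a [DuplexModel-class].
#' @param design a [DesignSpec-class] with \code{n} >= 0.
#' @return a [ModelPrediction-class].
#' @examples
#' stretchingOrientation(calibratedDuplex(), designSpec(6, "G", "C", n = 8))
#' @export
stretchingOrientation <- function(duplex, design) {
  if (design@strandSign < 0) duplex <- mirrorDuplex(duplex)
  b <- design@b
  j <- b + 1L + design@n
  checkBpIndex(duplex, c(b, j))
  v <- duplex@coords1[j + 1L, ] - duplex@coords1[b + 1L, ]
  ang <- anglesFromAxis(v)
  new("ModelPrediction", thetaModel = ang$theta, phiModel = ang$phi,
      stretchX = design@n * duplex@params@rise)
}

#' Axial distance of a number of base steps
#'
#' @param nSteps integer number of base steps (>= 0).
#' @param params a [HelicalParams-class].
#' @return distance in nm (nSteps * rise).
#' @examples
#' axialDistance(8)   # full stretching range
#' axialDistance(5)   # attachment positions b = 5..10
#' @export
axialDistance <- function(nSteps, params = defaultHelicalParams()) {
  if (any(nSteps < 0)) stop("nSteps must be >= 0")
  nSteps * params@rise
}

#' Fit the model line Theta(b)
#'
#' Evaluates the intercalation model over a set of attachment positions,
#' sequentially unwraps the wrapped angle series and fits an ordinary
#' least-squares line. By construction |slope| equals the configured twist.
#'
#' @param duplex a [DuplexModel-class].
#' @param bValues integer vector of at least 2 distinct attachment positions.
#' @param strandSign +1 or -1 (mirrored-strand designs).
#' @return list with \code{slope} (deg/base), \code{intercept} (degrees,
#'   wrapped to [0, 360)) and \code{theta} (the unwrapped series).
#' @examples
#' modelLine(calibratedDuplex(), 5:10)
#' @export
modelLine <- function(duplex, bValues, strandSign = 1) {
  bValues <- as.integer(bValues)
  if (length(unique(bValues)) < 2L)
    stop("need at least 2 distinct attachment positions")
  bValues <- sort(bValues)
  theta <- vapply(bValues, function(b) {
    intercalationOrientation(duplex,
      designSpec(b, strandSign = strandSign))@thetaModel
  }, numeric(1))
  un <- unwrapSeries(theta, 360)
  fit <- stats::lm(un ~ bValues)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = wrapAngle360(unname(stats::coef(fit)[1])),
       theta = un)
}

#' Tabulate geometric-model predictions
#'
#' @param designs list of [DesignSpec-class] objects (or character labels).
#' @param duplex a [DuplexModel-class].
#' @return data.frame with columns design, theta_model_deg, phi_model_deg,
#'   stretch_x_nm.
#' @export
modelPredictionTable <- function(designs, duplex = calibratedDuplex(30)) {
  if (is.character(designs)) designs <- lapply(designs, parseDesign)
  rows <- lapply(designs, function(d) {
    p <- if (d@n == 0L) intercalationOrientation(duplex, d)
         else stretchingOrientation(duplex, d)
    data.frame(design = designLabel(d), theta_model_deg = p@thetaModel,
               phi_model_deg = p@phiModel, stretch_x_nm = p@stretchX)
  })
  do.call(rbind, rows)
}
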