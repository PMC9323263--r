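## ---------------------------------------------------------------------------
## DNA geometry
## ---------------------------------------------------------------------------

#' Helical parameters of an idealized B-form duplex
#'
#' Canonical B-form values are supplied by [defaultHelicalParams()]: a twist
#' of 35.7 degrees per base step, a rise of 0.34 nm per base step, a backbone
#' radius of 0.94 nm and an angular separation of 131.4 degrees between the
#' two strands' sugar carbons across a base pair.
#'
#' @slot twist degrees of helical twist per base step, in (0, 60).
#' @slot rise axial rise per base step, nm, > 0.
#' @slot backboneRadius radial distance of the attachment sugar carbon from
#'   the helix axis, nm, > 0.
#' @slot strandPhaseOffset angular separation of the two strands' sugar
#'   carbons across a base pair, degrees in (0, 360).
#' @slot handedness +1 or -1; sign convention of the phase progression along
#'   the +X helix axis.
#' @export
setClass("HelicalParams", representation(
  twist = "numeric", rise = "numeric", backboneRadius = "numeric",
  strandPhaseOffset = "numeric", handedness = "numeric"
))

setValidity("HelicalParams", function(object) {
  msg <- character()
  if (!(object@twist > 0 && object@twist < 60))
    msg <- c(msg, "twist must lie in (0, 60) degrees per base")
  if (!(object@rise > 0)) msg <- c(msg, "rise must be positive")
  if (!(object@backboneRadius > 0))
    msg <- c(msg, "backboneRadius must be positive")
  if (!(object@strandPhaseOffset > 0 && object@strandPhaseOffset < 360))
    msg <- c(msg, "strandPhaseOffset must lie in (0, 360) degrees")
  if (!(object@handedness %in% c(-1, 1)))
    msg <- c(msg, "handedness must be +1 or -1")
  if (length(msg)) msg else TRUE
})

#' Idealized B-form duplex coordinate model
#'
#' Holds one representative attachment sugar carbon per nucleotide for both
#' strands of a rigid, straight B-form duplex whose axis is +X. Base pair i
#' (0-based) sits at axial position i * rise with phase angle
#' phase0 + handedness * twist * i.
#'
#' @slot params the [HelicalParams-class] used for construction.
#' @slot phase0 phase angle of base pair 0, degrees.
#' @slot basePairCount number of base pairs (>= 2).
#' @slot axial numeric vector, axial positions (nm) of each base pair.
#' @slot phase numeric vector, phase angle (degrees, mod 360) per base pair.
#' @slot coords1,coords2 base_pair_count x 3 matrices of sugar-carbon
#'   coordinates (nm) on strand 1 (the dye-bearing strand, 5'->3' along +X)
#'   and strand 2.
#' @export
setClass("DuplexModel", representation(
  params = "HelicalParams", phase0 = "numeric", basePairCount = "integer",
  axial = "numeric", phase = "numeric",
  coords1 = "matrix", coords2 = "matrix"
))

setValidity("DuplexModel", function(object) {
  n <- object@basePairCount
  if (n < 2L) return("basePairCount must be >= 2")
  if (length(object@axial) != n || length(object@phase) != n ||
      nrow(object@coords1) != n || nrow(object@coords2) != n)
    return("coordinate slots must have one row/element per base pair")
  TRUE
})

#' Design of a dye attachment on the origami template duplex
#'
#' Encodes the bMN / bMN/n nomenclature: the dye sits b bases from the common
#' crossover with flanking bases M (5') and N (3'); strandSign -1 denotes the
#' mirrored-strand designs whose 5'->3' direction runs along -X; n is the
#' stretching level (number of unpaired adenines opposite the dye, 0 = none).
#'
#' @slot b integer attachment position (bases from the common crossover).
#' @slot flank5,flank3 flanking base identities, one of "A","C","G","T".
#' @slot strandSign +1 or -1.
#' @slot n integer stretching level >= 0.
#' @export
setClass("DesignSpec", representation(
  b = "integer", flank5 = "character", flank3 = "character",
  strandSign = "numeric", n = "integer"
))

setValidity("DesignSpec", function(object) {
  msg <- character()
  if (!(object@flank5 %in% c("A", "C", "G", "T")) ||
      !(object@flank3 %in% c("A", "C", "G", "T")))
    msg <- c(msg, "flanking bases must be one of A, C, G, T")
  if (!(object@strandSign %in% c(-1, 1)))
    msg <- c(msg, "strandSign must be +1 or -1")
  if (object@n < 0L) msg <- c(msg, "stretching level n must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Geometric-model orientation prediction
#'
#' @slot thetaModel predicted polar angle, degrees; for intercalation
#'   predictions this is reported on the equatorial full-circle wrap
#'   Theta in [0, 360).
#' @slot phiModel predicted azimuth, degrees in [0, 360).
#' @slot stretchX added axial (X) stretching distance, nm (0 when n = 0).
#' @export
setClass("ModelPrediction", representation(
  thetaModel = "numeric", phiModel = "numeric", stretchX = "numeric"
))

setValidity("ModelPrediction", function(object) {
  msg <- character()
  if (object@phiModel < 0 || object@phiModel >= 360)
    msg <- c(msg, "phiModel must lie in [0, 360)")
  if (object@stretchX < 0) msg <- c(msg, "stretchX must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Optics
## ---------------------------------------------------------------------------

#' Imaging system configuration
#'
#' Defaults describe a TIRF setup: NA 1.49 oil objective (n = 1.515) imaging
#' a dye in aqueous buffer (n = 1.33) a few nm above the coverslip, EMCCD
#' pixels of 16 um imaged at 100x (160 nm at the sample).
#'
#' @slot na numerical aperture (< immersion index).
#' @slot nImmersion immersion/coverslip refractive index.
#' @slot nSample sample medium refractive index.
#' @slot wavelength emission wavelength, nm (Cy5 ~ 670, Cy3B ~ 580).
#' @slot pixelPitch camera pixel pitch referred to the sample, nm.
#' @slot emitterHeight emitter height above the interface, nm.
#' @slot pupilN side length of the Cartesian pupil/FFT grid used by the
#'   forward model (accuracy/speed trade-off).
#' @export
setClass("OpticsConfig", representation(
  na = "numeric", nImmersion = "numeric", nSample = "numeric",
  wavelength = "numeric", pixelPitch = "numeric", emitterHeight = "numeric",
  pupilN = "integer"
))

setValidity("OpticsConfig", function(object) {
  msg <- character()
  if (!(object@na < object@nImmersion))
    msg <- c(msg, "numerical aperture must be smaller than the immersion index")
  if (!(object@nImmersion > 1 && object@nSample > 1))
    msg <- c(msg, "refractive indices must exceed 1")
  if (object@wavelength < 400 || object@wavelength > 900)
    msg <- c(msg, "wavelength must lie in [400, 900] nm")
  if (object@pixelPitch <= 0) msg <- c(msg, "pixelPitch must be positive")
  if (object@emitterHeight < 0) msg <- c(msg, "emitterHeight must be >= 0")
  if (object@pupilN < 64L) msg <- c(msg, "pupilN must be >= 64")
  if (length(msg)) msg else TRUE
})

#' A defocused single-emitter intensity image
#'
#' @slot pixels square intensity matrix with odd side length, all >= 0.
#' @slot pixelPitch pixel pitch at the sample, nm.
#' @slot defocus defocus distance, nm.
#' @slot photons total expected photon count the image is normalized to.
#' @export
setClass("DipoleImage", representation(
  pixels = "matrix", pixelPitch = "numeric", defocus = "numeric",
  photons = "numeric"
))

setValidity("DipoleImage", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (d[1] != d[2] || d[1] %% 2L == 0L)
    msg <- c(msg, "pixel grid must be square with odd side length")
  if (any(object@pixels < -1e-9))
    msg <- c(msg, "pixel intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Template library for dipole orientation fitting
#'
#' Because the image intensity is a quadratic form in the dipole moment
#' components, the library stores six basis images per defocus plane
#' (xx, yy, zz, xy, xz, yz products of field components); any (theta, phi)
#' template is a linear combination. Normalized-correlation statistics over
#' the angular grid are precomputed for the coarse search.
#'
#' @slot basis list (one element per defocus) of npix x 6 basis matrices.
#' @slot defocusGrid defocus planes, nm.
#' @slot thetaGrid,phiGrid angular grid, degrees.
#' @slot quad 6 x nAngles matrix of dipole-moment quadratic coefficients for
#'   the angular grid.
#' @slot templateMean,templateSd per-defocus lists of template means and
#'   mean-subtracted norms over the angular grid (coarse-stage cache).
#' @slot side template side length, pixels.
#' @slot optics the [OpticsConfig-class] used to render the library.
#' @export
setClass("DipoleLibrary", representation(
  basis = "list", defocusGrid = "numeric", thetaGrid = "numeric",
  phiGrid = "numeric", quad = "matrix", templateMean = "list",
  templateSd = "list", side = "integer", optics = "OpticsConfig"
))

## ---------------------------------------------------------------------------
## Synthetic experiments
## ---------------------------------------------------------------------------

#' Origami template layout for DNA-PAINT registration
#'
#' @slot width,height template extent, nm (~90 x 70).
#' @slot sites k x 2 matrix of docking-site coordinates, nm, in the template
#'   frame (centered); pairwise spacing >= 10 nm and no nontrivial rotational
#'   symmetry so registration is unambiguous.
#' @slot dyeXY in-template coordinate of the dye attachment, nm.
#' @export
setClass("OrigamiLayout", representation(
  width = "numeric", height = "numeric", sites = "matrix", dyeXY = "numeric"
))

setValidity("OrigamiLayout", function(object) {
  if (ncol(object@sites) != 2L) return("sites must be a k x 2 matrix")
  if (nrow(object@sites) >= 2L) {
    d <- as.matrix(stats::dist(object@sites))
    diag(d) <- Inf
    if (min(d) < 10 - 1e-9)
      return("docking sites must be spaced at least 10 nm apart")
  }
  TRUE
})

#' Binding/photophysics kinetics for synthetic movies
#'
#' @slot meanBright mean bright (bound) time of a PAINT binding event, s.
#' @slot meanDark mean dark time between binding events per docking site, s
#'   (set by the 3 nM imager concentration in the emulated experiment).
#' @slot paintPhotons expected photons per fully bright PAINT frame.
#' @slot dipolePhotons expected photons per dipole frame.
#' @slot bleachHazard per-dipole-frame bleaching probability.
#' @slot switchProb per-dipole-frame orientation-switch probability.
#' @export
setClass("KineticsParams", representation(
  meanBright = "numeric", meanDark = "numeric", paintPhotons = "numeric",
  dipolePhotons = "numeric", bleachHazard = "numeric", switchProb = "numeric"
))

setValidity("KineticsParams", function(object) {
  msg <- character()
  if (object@meanBright < 0 || object@meanDark < 0 ||
      object@paintPhotons < 0 || object@dipolePhotons < 0)
    msg <- c(msg, "rates and photon budgets must be >= 0")
  if (object@bleachHazard < 0 || object@bleachHazard > 1 ||
      object@switchProb < 0 || object@switchProb > 1)
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' EMCCD camera model
#'
#' Electron multiplication is modeled with the standard gamma approximation:
#' n detected photoelectrons produce Gamma(shape = n, scale = gain) output
#' electrons, plus Gaussian read noise and a baseline offset.
#'
#' @slot gain electron-multiplying gain (>= 1; 100 in the emulated setup).
#' @slot readNoise read noise SD, output electrons.
#' @slot sensitivity analog-to-digital conversion, output electrons per ADU.
#' @slot baseline baseline offset, ADU.
#' @slot exposureDipole dipole-channel exposure, s (2 s default).
#' @slot exposurePaint PAINT-channel exposure, s (0.3 s default).
#' @export
setClass("CameraModel", representation(
  gain = "numeric", readNoise = "numeric", sensitivity = "numeric",
  baseline = "numeric", exposureDipole = "numeric", exposurePaint = "numeric"
))

setValidity("CameraModel", function(object) {
  msg <- character()
  if (object@gain < 1) msg <- c(msg, "gain must be >= 1")
  if (object@exposureDipole <= 0 || object@exposurePaint <= 0)
    msg <- c(msg, "exposures must be positive")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Statistics and registration results
## ---------------------------------------------------------------------------

#' Kent (Fisher-Bingham) moment fit of a set of axes
#'
#' @slot gamma1 mean direction (unit axis).
#' @slot gamma2,gamma3 major and minor tangent axes of the elliptical cone.
#' @slot kappa concentration (> 2 * beta).
#' @slot beta ovalness (>= 0).
#' @slot sigmaX,sigmaY angular SDs along gamma2/gamma3, degrees
#'   (sigmaX >= sigmaY > 0).
#' @slot n sample count.
#' @export
setClass("KentFit", representation(
  gamma1 = "numeric", gamma2 = "numeric", gamma3 = "numeric",
  kappa = "numeric", beta = "numeric", sigmaX = "numeric", sigmaY = "numeric",
  n = "integer"
))

setValidity("KentFit", function(object) {
  msg <- character()
  G <- rbind(object@gamma1, object@gamma2, object@gamma3)
  if (max(abs(G %*% t(G) - diag(3))) > 1e-6)
    msg <- c(msg, "gamma1, gamma2, gamma3 must be orthonormal")
  if (!(object@kappa > 2 * object@beta) || object@beta < 0)
    msg <- c(msg, "require kappa > 2 * beta >= 0")
  if (!(object@sigmaX >= object@sigmaY && object@sigmaY > 0))
    msg <- c(msg, "require sigmaX >= sigmaY > 0")
  if (length(msg)) msg else TRUE
})

#' Result of registering the docking pattern to localization clusters
#'
#' @slot phiOrigami in-plane template rotation, degrees in [0, 360).
#' @slot translation length-2 translation, nm.
#' @slot mirror logical; TRUE if the reflected template matched.
#' @slot rms RMS residual of matched sites, nm.
#' @slot matched number of matched template sites.
#' @slot registered logical; FALSE when the residual exceeded the rejection
#'   threshold.
#' @export
setClass("OrigamiRegistration", representation(
  phiOrigami = "numeric", translation = "numeric", mirror = "logical",
  rms = "numeric", matched = "integer", registered = "logical"
))

setValidity("OrigamiRegistration", function(object) {
  if (object@rms < 0) return("rms residual must be >= 0")
  if (object@phiOrigami < 0 || object@phiOrigami >= 360)
    return("phiOrigami must lie in [0, 360)")
  TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "HelicalParams", function(object) {
  cat(sprintf(
    "HelicalParams: twist %.2f deg/base, rise %.3f nm/base, radius %.3f nm,\n  strand phase offset %.1f deg, handedness %+d\n",
    object@twist, object@rise, object@backboneRadius,
    object@strandPhaseOffset, object@handedness))
})

setMethod("show", "DuplexModel", function(object) {
  cat(sprintf(
    "DuplexModel: %d bp idealized B-form duplex along +X (span %.2f nm), phase0 %.2f deg\n",
    object@basePairCount, max(object@axial), object@phase0))
})

setMethod("show", "DesignSpec", function(object) {
  lab <- designLabel(object)
  cat(sprintf("DesignSpec %s: b=%d, flanks %s/%s, strand %+d, stretching n=%d\n",
              lab, object@b, object@flank5, object@flank3,
              as.integer(object@strandSign), object@n))
})

setMethod("show", "ModelPrediction", function(object) {
  cat(sprintf(
    "ModelPrediction: Theta/theta %.1f deg, phi %.1f deg, stretch_x %.2f nm\n",
    object@thetaModel, object@phiModel, object@stretchX))
})

setMethod("show", "OpticsConfig", function(object) {
  cat(sprintf(
    "OpticsConfig: NA %.2f (oil n=%.3f / sample n=%.3f), lambda %.0f nm,\n  pixel %.0f nm at sample, emitter height %.0f nm\n",
    object@na, object@nImmersion, object@nSample, object@wavelength,
    object@pixelPitch, object@emitterHeight))
})

setMethod("show", "DipoleImage", function(object) {
  cat(sprintf(
    "DipoleImage: %d x %d px (%.0f nm/px), defocus %.0f nm, %.0f photons\n",
    nrow(object@pixels), ncol(object@pixels), object@pixelPitch,
    object@defocus, object@photons))
})

setMethod("show", "DipoleLibrary", function(object) {
  cat(sprintf(
    "DipoleLibrary: %d x %d px templates, theta %s deg, phi %s deg, defocus %s nm\n",
    object@side, object@side,
    paste0(range(object@thetaGrid), collapse = "-"),
    paste0(range(object@phiGrid), collapse = "-"),
    paste0(range(object@defocusGrid), collapse = "-")))
})

setMethod("show", "OrigamiLayout", function(object) {
  cat(sprintf(
    "OrigamiLayout: %.0f x %.0f nm rectangle, %d docking sites, dye at (%.1f, %.1f) nm\n",
    object@width, object@height, nrow(object@sites),
    object@dyeXY[1], object@dyeXY[2]))
})

setMethod("show", "KentFit", function(object) {
  m <- anglesFromAxis(object@gamma1)
  cat(sprintf(
    "KentFit (n=%d): mean theta %.1f deg, phi %.1f deg; sigma_x* %.1f, sigma_y* %.1f, sigma %.1f deg; kappa %.1f, beta %.1f\n",
    object@n, m$theta, m$phi, object@sigmaX, object@sigmaY,
    dispersionSigma(object), object@kappa, object@beta))
})

setMethod("show", "OrigamiRegistration", function(object) {
  cat(sprintf(
    "OrigamiRegistration: phi_origami %.1f deg%s, %d sites matched, RMS %.2f nm%s\n",
    object@phiOrigami, if (object@mirror) " (mirrored)" else "",
    object@matched, object@rms,
    if (object@registered) "" else " [REJECTED]"))
})
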