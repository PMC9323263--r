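# DipoleOrigami

Absolute 3D orientation of single fluorescent dyes tethered to DNA origami
templates, measured by combining two single-molecule imaging channels:

* **Defocused dipole imaging** — a fixed dye near the coverslip, imaged
  ~550 nm out of focus through an NA 1.49 oil objective, produces an
  anisotropic emission pattern that encodes the 3D orientation of its
  transition dipole moment (an axis: `theta` polar, `phi` azimuthal). The
  package implements the vectorial interface PSF (Fresnel transmission
  including supercritical emission, aplanatic apodization, defocus) and
  fits orientations by template-library correlation with continuous
  refinement, treating defocus as a free parameter.
* **DNA-PAINT super-resolution** — transient imager binding to an
  asymmetric docking pattern on the ~90 × 70 nm origami is localized
  frame by frame, drift-corrected with gold-bead fiducials, clustered
  into docking sites, and registered against the known pattern to recover
  the template's in-plane rotation `phi_origami`.

The absolute orientation in the template frame is `theta = theta_dipole`,
`phi = phi_dipole − phi_origami`. Per-condition orientation statistics use
the Kent (Fisher–Bingham) distribution: mean axis, elliptical-cone SDs
`sigma_x*`, `sigma_y*` and the scalar dispersion
`sigma = sqrt(sigma_x* · sigma_y*)`.

Two idealized B-form DNA geometric models predict the measured trends:

* **Intercalation**: a dye intercalated `b` bases from a crossover aligns
  with the mean flanking-base-pair vector; on the equatorial wrap angle,
  `Theta(b) = 285.7° − 35.7°·b (mod 360)` with `phi = 90°` — one phase
  constant calibrated at `b = 5`, everything else predicted.
* **Two-tether stretching**: a dye stretched across `n` unpaired bases
  aligns with the chord between its attachment carbons; the axial
  stretching distance is `n × 0.34 nm` (2.72 nm at `n = 8`), and `phi → 0`
  as `n` grows.

Because no public raw movies exist for this kind of experiment, the package
ships a first-class synthetic-data generator (EMCCD noise chain, binding
kinetics, drift, fiducials, ground-truth tables) so the entire inference
chain is testable end to end against known truth.

## Worked example

```r
library(DipoleOrigami)

## geometric model over the attachment series
duplex <- calibratedDuplex(16)
modelPredictionTable(paste0(5:10, "TT"), duplex)
#>   design theta_model_deg phi_model_deg stretch_x_nm
#> 1    5TT           107.2            90            0
#> 2    6TT            71.5            90            0
#> 3    7TT            35.8            90            0
#> 4    8TT             0.1            90            0
#> 5    9TT           324.4            90            0
#> 6   10TT           288.7            90            0
ml <- modelLine(duplex, 5:10)
#> slope -35.7 deg/base, intercept 285.7 deg

## compose an absolute orientation from the two channels
toOrigamiFrame(35, 77, 345)
#> theta 35 deg, phi 92 deg

## fit a noisy synthetic dipole image
set.seed(1)
lib <- makeDipoleLibrary()
img <- renderDipole(35, 77, defocus = 550, photons = 5000)
noisy <- matrix(rpois(51^2, img@pixels + 2), 51, 51)
fitDipole(noisy, lib)
#> fit: theta 33.9, phi 74.1, defocus 543 nm, score 0.952

## Kent statistics of a set of measured axes
ax <- rFisherAxes(40, axisFromAngles(60, 120), 1 / (4.5 * pi / 180)^2, seed = 2)
kentFit(ax)
#> KentFit (n=40): mean theta 120.8 deg, phi 299.5 deg; sigma_x* 4.8,
#>   sigma_y* 4.1, sigma 4.4 deg; kappa 169.7, beta 12.1
```

The fitted `theta/phi` are within ~3° of the ground truth (35°, 77°) and
the fitted defocus within ~10 nm of the simulated 550 nm; the Kent fit
recovers the generating 4.5° dispersion as `sigma = 4.4°` (the mean axis
is reported up to antipodal sign).

The full pipeline — simulate movies to TIFF, infer orientations, summarize
per design — is driven by one YAML config through `runSimulate()`,
`runInfer()` and `runReport()`, or from a shell via
`inst/scripts/dyeorient.R`.

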