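---
title: "Measuring absolute single-dye orientations on DNA origami: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring absolute single-dye orientations on DNA origami}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DipoleOrigami)
```

## The measurement problem

A fluorophore's transition dipole moment (TDM) is an axis: it is only
defined up to sign, and every statistic in this package treats orientations
as antipodally symmetric axes. When a dye is rigidly held a few nanometres
above a glass/water interface and imaged slightly out of focus through a
high-NA objective, its emission pattern is strongly anisotropic and encodes
the full 3D orientation of the TDM. That gives the polar angle `theta`
(from the optical axis) and the azimuth `phi_dipole` — but only in *camera*
coordinates. To express the orientation relative to the DNA origami
template the dye sits on, the template itself must be oriented: transient
imager binding to an asymmetric docking pattern (DNA-PAINT) reconstructs
the template well below the diffraction limit, and registering the known
pattern yields the in-plane template rotation `phi_origami`. The absolute
orientation is then

```
theta = theta_dipole,    phi = phi_dipole - phi_origami  (mod 360).
```

`toOrigamiFrame(35, 77, 345)` returns `theta = 35, phi = 92` — the worked
example used throughout the tests.

## Geometric models of the duplex

`buildDuplex()` realizes an idealized, rigid B-form duplex along +X: one
representative attachment sugar carbon per nucleotide at radius
`backboneRadius`, phase advancing by `twist` per base pair, strands offset
by `strandPhaseOffset` across a base pair. Defaults
(`defaultHelicalParams()`):

| parameter          | default | units    | why                                                  |
|--------------------|---------|----------|------------------------------------------------------|
| twist              | 35.7    | deg/base | the slope of the model line over the design range     |
| rise               | 0.34    | nm/base  | canonical B-form; all printed distances are multiples |
| backboneRadius     | 0.94    | nm       | canonical B-form backbone radius                      |
| strandPhaseOffset  | 131.4   | deg      | canonical minor/major-groove asymmetry                |

Two models are evaluated on this duplex:

* **Intercalation** (`intercalationOrientation`): a dye intercalated
  between base pairs `b` and `b+1` aligns with the normalized mean of the
  two flanking-base-pair vectors (strand-1 to strand-2 sugar carbon of each
  pair). These vectors are transverse to the helix axis by construction, so
  the prediction lives on the full-circle equatorial wrap angle `Theta`
  with `phi = 90`. With the calibrated phase origin,
  `Theta(b) = 285.7 - 35.7 b (mod 360)`.
* **Stretching** (`stretchingOrientation`): a dye held by two tethers whose
  attachment points are separated by `n` unpaired bases aligns with the
  chord from the 5' attachment carbon (base pair `b`) to the 3' attachment
  carbon (base pair `b+1+n`). The added axial distance is `n * rise`
  (2.72 nm at `n = 8`); as `n` grows the chord aligns with the helix axis,
  so `phi` approaches 0 and `theta` stays near 90.

**Phase-origin calibration.** The helical parameters fix every *relative*
angle but not the absolute angular origin at the crossover, which depends
on molecular details the idealized model does not carry. `calibratePhase0()`
fixes it once, so that `Theta(b = 5) = 107.2`; all other positions
(`b = 6..10`) and all stretching predictions are then parameter-free
predictions. The calibration is a single global constant, never re-tuned
per design.

**Which sugar carbon.** The model places one representative carbon per
nucleotide at the backbone radius. The choice of the specific carbon (C1'
vs C3'/C5') only shifts the phase origin and radius slightly; the phase
shift is absorbed by the calibration and the radius affects `phi` at second
order only. Both are exposed (`backboneRadius`, `phase0`) rather than
hard-coded.

**Mirrored-strand designs.** For designs whose tethered strand runs 5'->3'
along -X, the duplex is reflected through the YZ plane. Reflection is
improper, so the mirrored helix has opposite handedness and the model line
slope flips sign (+35.7 deg/base). No surface-interaction term is modelled:
deviations of near-surface designs from this geometric line are outside
the model's scope.

**Monotone stretching range.** The in-plane angle of the stretching chord
decreases with `n` only in envelope: the transverse component oscillates
with helical phase while the axial component grows. Over the design range
`n = 6..8` the decrease is strict (18.0, 5.1, 1.1 degrees from the helix
axis); for arbitrary `n` beyond the design range it need not be, and the
tests assert monotonicity only on the design range.

## Vectorial optics forward model

`renderDipole()` implements the standard angular-spectrum model of a fixed
dipole at a dielectric interface: the dipole's plane-wave spectrum in the
sample medium (n = 1.33) is transmitted into the immersion medium
(n = 1.515) with Fresnel coefficients — including the supercritical,
evanescent-coupled components that exist because NA = 1.49 exceeds the
sample index — apodized for an aplanatic objective, phase-shifted by the
emitter height and the defocus, and Fourier-transformed to the image
plane. Intensity is the squared field summed over the two transverse
polarization components.

Because intensity is a quadratic form in the dipole components, six basis
images per defocus reproduce any orientation by linear combination; the
template library (`makeDipoleLibrary`) stores only these bases, making the
exhaustive coarse search over ~23000 grid templates a handful of small
matrix products per candidate image.

Numerical choices:

* Cartesian pupil grid of side `pupilN` (default 256) with the aperture
  edge anti-aliased by a one-cell linear coverage ramp; this makes the
  discretization second-order accurate. At `pupilN = 512` the rendered
  image agrees with an independent direct-quadrature evaluation of the same
  integrals (Gauss-Legendre split at the critical angle) to better than
  1e-3 of peak; the default trades a little of that accuracy for speed and
  is far below the shot-noise floor of any fitted image.
* Emitter height 5 nm (dye on a flat origami on glass) — not a measured
  value; configurable.
* Pixel pitch 160 nm at the sample (16 um EMCCD pixel behind 100x);
  emission wavelength 670 nm for the red dye channel; both configurable.

## Dipole-channel inference

Detection correlates the master image with the orientation-averaged
template (a matched filter): defocused patterns are multi-lobed donuts, so
naive local-maxima detection fragments them, while the matched-filter
correlation has a single sharp peak per emitter. ROIs are 51 x 51 px;
overlapping ROIs are discarded outright.

The template fit has no translation degree of freedom, and it is very
sensitive to mis-centering: a one-pixel offset biases `theta` by tens of
degrees toward the equator while still scoring above the acceptance
threshold. The pipeline therefore refines each ROI center over integer
pixel shifts, keeping the center with the best coarse-fit score, before
the continuous refinement. Sub-pixel emitter offsets (which the generator
does not produce, since positions snap to pixel centers) would leave a
residual bias on real data; a translation-aware refinement would be the
natural extension.

Time series are segmented before summation. A switch is declared when, for
two consecutive frames, a frame stops resembling the running segment sum
under *both* of two correlation gates: the smoothed-image correlation
(threshold 0.95; robust but dominated by the common donut envelope) and
the correlation of radial-residual images (threshold `tauSwitch` = 0.8;
this isolates the azimuthal anisotropy that encodes orientation but is
uninformative for near-axial dipoles, which the first gate covers).
Bleaching truncates the series when the background-subtracted mean ROI
intensity falls below 3x the photometric noise floor estimated from the
frame-to-frame differences.

Fitting is two-stage: exhaustive normalized cross-correlation over the
library grid (5 degrees in `theta` and `phi`, 50 nm in defocus over
200-1000 nm), then Nelder-Mead refinement of the continuous correlation
with the basis linearly interpolated across defocus. Mean-subtracted
normalized correlation makes the fit invariant to amplitude and constant
background, so only three physical parameters are searched. Defocus is a
free parameter throughout because the true focal offset of a measured
stack is unknown in practice. Fits are reported with the canonical
antipodal representative (`theta` in [0, 90]) and accepted at score
`tauAccept` = 0.7; both thresholds are exposed, as no principled universal
value exists.

## PAINT-channel inference

Localization is difference-of-Gaussians detection plus an
integrated-Gaussian least-squares fit with inverse-variance (shot-noise)
weights; the per-localization precision uses the Thompson-style estimator
with the 2x EMCCD excess-noise factor. Fiducials are identified as
localization tracks present in most frames; drift is the fiducial-averaged
displacement, gap-interpolated and smoothed with a 25-frame running mean.

A geometric fact dominates the downstream analysis: the whole ~90 x 70 nm
origami is smaller than one camera pixel, so frames in which two docking
sites are bright simultaneously yield a *single* merged localization
between the sites. `filterLocalizations()` therefore keeps a photon band
around the modal single-event brightness (self-calibrated from the
intensity histogram, as in standard PAINT quality control), site centroids
are component-wise medians, and density clusters that still chain
neighbouring sites are split by recursive 2-means (accepted only when both
halves are dense and well separated). Site clustering itself is
density-based (radius 6 nm, 5 points minimum).

Registration searches rotations at 0.5 degree steps and both parities,
aligns translation by iterated nearest-neighbour matching, and scores
poses by capped RMS nearest-neighbour distance plus a penalty per
unmatched template site; the best pose is refined continuously.
Registrations with RMS residual above 10 nm or fewer than 4 matched sites
are rejected rather than reported. The default docking pattern was chosen
by maximizing the pattern's ambiguity margin — the minimum mean
nearest-neighbour distance between the pattern and any rotated and/or
mirrored copy of itself — subject to >= 20 nm site spacing, so that
registration stays unambiguous at realistic centroid noise.

Both channels are processed in the raw camera frame with one consistent
axis convention. Any fixed mirror between the camera frame and the
physical sample frame cancels in `phi = phi_dipole - phi_origami`, because
it affects both terms identically; the synthetic end-to-end tests verify
the composition against ground truth.

## Kent statistics

Sets of measured axes are summarized with the Kent (Fisher-Bingham)
distribution by deterministic moment estimation: antipodal signs are
aligned to the dominant scatter eigenvector, the mean direction is the
normalized resultant, and the tangent-plane second-moment
eigen-decomposition gives the elliptical-cone axes and the angular SDs
`sigma_x* >= sigma_y*` (log-map tangent coordinates, reported in degrees).
Concentration and ovalness come from the standard resultant/eigenvalue
moment formulas. Moment estimation is exact enough in the high-
concentration regime this data lives in (kappa of order 100) and has no
convergence failures, which matters for unattended pipelines.

The scalar dispersion reported per condition is
`sigma = sqrt(sigma_x* sigma_y*)` — the *geometric mean* of the cone SDs.
A plain product would carry squared-degree units and could not be quoted
as a single +/- value in degrees, so the geometric-mean reading is used
and documented prominently.

Samples may contain several stable orientations; axes are clustered by
single-linkage on the antipodal-aware geodesic distance (20 degree cut)
and the dominant cluster is summarized. Each accepted orientation segment
contributes one axis, so a dye with two stable orientations contributes
two axes. A switch in the generator redraws from the same condition
distribution, leaving the marginal dispersion unchanged; dispersion
inflation is therefore tested in its meaningful form — when destabilized
segments carry larger scatter than stable ones, the fitted `sigma` grows
monotonically with the contamination fraction.

## What the synthetic data does and does not emulate

The generator produces dipole movies (2 s frames; piecewise-constant
orientations with Kent scatter about a model prediction, switching at
0.002/frame, bleaching at 0.003/frame, 5000 photons/frame) and PAINT
movies (300 ms frames; per-site alternating exponential dark/bright
intervals; Gaussian spots with photons scaled by the bright fraction of
each frame), plus gold-bead fiducials, random-walk + linear stage drift
(0.5 nm/frame RMS + 0.05 nm/frame), Poisson shot noise, gamma-distributed
electron multiplication (gain 100), Gaussian read noise and a baseline
offset, written as 16-bit multi-page TIFF.

PAINT kinetics defaults (mean bright 0.6 s, mean dark 15 s per site,
5000 photons per bright frame) describe a bright, high-affinity imager and
give roughly 20 binding events per site in a 1000-frame movie; they were
chosen once as a realistic operating point and are configurable. Dipole
positions are snapped to pixel centers — position is not a measurand in
that channel.

Not emulated: triplet blinking and spectral crosstalk (channels are
acquired sequentially), aberrations beyond defocus, out-of-plane origami
tilt (templates are assumed flat on the glass), surface interactions of
near-surface designs, and any sequence-dependent DNA structure. Passing
the synthetic suites therefore demonstrates that the *inference chain* is
correct and well-calibrated under the stated noise model — not that the
geometric models describe any particular real dye, which is exactly the
question real experiments answer.

## Problem sizes used by the test suites

The property suites run at sizes chosen to give stable statistics on a
desktop: 100 random dipoles for orientation recovery (median error well
under the 3 degree bound at the default photon budget), 50 seeds of 40
axes for dispersion recovery, a 6-condition attachment series with 20 dyes
per condition and 1000-frame PAINT movies for the end-to-end slope, and 36
rotations for registration. Larger sizes change none of the conclusions,
only the Monte-Carlo error bars.

## Known limitations

* The moment Kent estimator is biased for small samples (n below ~10) and
  the dominant-cluster summary discards secondary orientation populations.
* Orientation fits for near-axial dipoles (`theta` below ~10 degrees) are
  ill-conditioned in `phi`; the geodesic error metric accounts for this,
  but per-condition `phi` means near the pole are unstable.
* The registration assumes the docking pattern is known exactly; template
  fabrication errors propagate directly into `phi_origami`.
* Overlapping dipole patterns are rejected, not fitted jointly.
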