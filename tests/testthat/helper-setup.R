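## Shared fixtures built once per test session.

.shared <- new.env()

## Default-optics template library (a few seconds to build; reused by the
## dipole-fitting, pipeline and acceptance tests).
sharedLibrary <- function() {
  if (is.null(.shared$lib))
    .shared$lib <- makeDipoleLibrary(opticsConfig())
  .shared$lib
}

## Standard PAINT scene: one origami at the field center plus one fiducial.
paintScene <- function(rotation, frames = 1000, seed = 1, fov = 64L,
                       pitch = 160) {
  center <- fov / 2 * pitch
  fid <- data.frame(x = center - 3200, y = center + 2800, photons = 20000)
  sim <- simulatePaintMovie(
    data.frame(x = center, y = center, phiOrigami = rotation),
    frames = frames, fiducials = fid, fov = fov, seed = seed)
  list(sim = sim, center = center, fid = fid)
}
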