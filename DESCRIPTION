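Package: DipoleOrigami
Title: Absolute 3D Orientation of Single Fluorophores on DNA Origami by
    Defocused Dipole Imaging and DNA-PAINT
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Measures the absolute three-dimensional orientation of single
    fluorescent dyes tethered to DNA origami templates. Combines a vectorial
    forward model of defocused single-dipole emission at a glass/water
    interface, template-library orientation fitting, DNA-PAINT
    super-resolution localization with fiducial drift correction and
    registration of an asymmetric docking pattern, and Kent (Fisher-Bingham)
    directional statistics. Includes idealized B-form DNA geometric models
    for dye intercalation and two-tether stretching, and a synthetic
    microscopy data generator with ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, grDevices, graphics, tools, tiff, yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
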