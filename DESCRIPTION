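Package: contourfill
Title: Contour-Facilitation Filling-In Model of Brightness Perception
Version: 0.1.0
Authors@R:
    person("contourfill", "developers", email = "contourfill@example.org",
           role = c("aut", "cre"))
Description: A neurocomputational filling-in model of achromatic brightness
    perception. Oriented boundary signals are facilitated by collinear and
    parallel high-contrast contours through a recurrent MAX network grounded
    in dendritic inhibition; facilitated low-contrast boundaries are erased
    from the boundary gate, which lets surface feature signals spread across
    the target and produces brightness or darkness assimilation. The package
    ships a parametric generator for the classic test battery (dungeon, cube,
    grating, ring patterns, bullseye, simultaneous brightness contrast,
    White's effect and its variants, Benary's cross, Todorovic's illusion,
    checkerboard contrast and contrast-contrast), the full ON/OFF
    contrast/luminance/filling-in architecture, and an evaluation harness
    that scores the model's directional predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
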