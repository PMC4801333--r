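Package: canaloflow
Title: Quantitative Canalography from Fluorescein Time-Lapse Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Regionally discrete quantification of aqueous humor outflow from
    fluorescein canalogram time-lapse image stacks. Reduces each stack to a
    coarse macropixel grid, fits penalized-spline (GAM) fill curves per
    macropixel to extract half-maximum intensity and time-to-half-max, fits a
    single cyclic tensor-product model over 36 perilimbal regions (12 clock
    hours by 3 rings), and attributes normalized flow (microliters per minute)
    to the four anatomical quadrants. Includes a synthetic canalogram
    generator with analytic ground truth, dot-plot and ring-plot displays,
    and CSV reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    png,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
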