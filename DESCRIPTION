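Package: muellerpc
Title: Depolarization Observables and Automatic Pseudo-Coloring for
    Mueller-Matrix Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-pixel depolarization observables from Mueller-matrix
    images of biological tissues (diattenuation, polarizance, degree of
    spherical purity, the indices of polarimetric purity from the Cloude
    coherency eigen-spectrum, and the depolarization index) and renders
    pseudo-colored RGB images from user-defined region-of-interest class
    statistics, either by two-class Euclidean-distance color mixing or by
    k-class Gaussian class-probability mixing.  Includes a synthetic-scene
    generator producing physically realizable Mueller images with known class
    labels, float-TIFF and array I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
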