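Package: mnscreen
Title: Transdermal Rate Estimation for Metallic Microneedle Arrays from
    Inter-Sheet Impedance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward electrical modelling and decoding tools for estimating
    the transdermal (skin penetration) rate of metallic sheet microneedle
    arrays from pairwise inter-sheet test currents.  Includes a finite-volume
    steady current-conduction solver for a two-layer skin block with
    contact-impedance coupling to equipotential metal sheets, exhaustive
    penetration-state sweeps that build current-interval calibration tables,
    packaged calibration tables for 3x3, 4x4 and 6x6 arrays, and the exact
    and fuzzy combinatorial decoders that recover per-sheet unpenetrated-tip
    counts from measured currents.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
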