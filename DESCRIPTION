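Package: ontshine
Title: Spectral, Anatomical and Visual-Model Analysis of Optic-Nerve-Transmitted Eyeshine
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying optic-nerve-transmitted (ONT) eyeshine in
    small teleost fishes. Provides spectral-curve handling (photon conversion,
    transmittance, band-integrated transmission efficiency, underwater
    attenuation and depth propagation), emission-beam geometry with refraction
    correction, length-weighted axial circular statistics and optic-nerve
    torsion regression, comparative morphometry summaries, a
    Vorobyev-Osorio receptor-noise model of eyeshine conspicuousness
    (chromatic and achromatic just-noticeable differences), seeded synthetic
    data generators for every input kind, and CSV readers/writers plus a
    command-line pipeline tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
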