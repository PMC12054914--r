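Package: windeps
Title: Wind Erosion Modelling and Sand-Fixation Service Mapping with RWEQ
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Raster implementation of the Revised Wind Erosion Equation (RWEQ)
    for mapping potential and actual soil wind erosion, the wind-erosion
    prevention (sand fixation) ecosystem service WEPS = SLR - SL and its
    retention rate, together with geographical-detector attribution of the
    spatial drivers of erosion and a field-validation workflow for
    measured-versus-predicted soil loss. Includes a fully self-contained
    synthetic scene generator (weather stations, soil texture, NDVI, land
    cover, socio-economic surfaces) so the whole pipeline runs and is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
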