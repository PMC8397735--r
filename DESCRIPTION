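Package: paleoemu
Title: Statistical Emulation of Snapshot Climate Simulations for
    Long-Term Paleoclimate Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits per-grid-box linear emulators of coarse-resolution
    climate-model snapshot climatologies (temperature, precipitation,
    total cloud cover) against orbital and greenhouse-gas forcings and a
    categorical surface-type mask, hindcasts monthly climate over the
    late Pleistocene, bilinearly downscales and delta bias-corrects the
    reconstruction against a present-day reference climatology, derives
    bioclimatic variables, and validates the emulation with goodness
    maps, spatial covariance comparisons, and correlations against
    long proxy records. Includes a synthetic-world generator so the
    full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ncdf4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
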