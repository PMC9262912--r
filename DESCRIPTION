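Package: greenfeedback
Title: Seasonal Vegetation-Greening Feedbacks on Near-Surface Temperature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the biophysical effects of seasonal
    vegetation greening on near-surface temperature with paired
    prescribed-leaf-area-index experiments. Provides a minimal gridded
    land-atmosphere column simulator driven by monthly leaf area index
    (LAI), the paired seasonal-control experiment design with
    initial-condition ensembles, a surface-energy-balance decomposition
    that attributes air-temperature changes to albedo, shortwave,
    evapotranspiration, aerodynamic-resistance and air-emissivity
    forcings plus a circulation residual, and seasonal trend, amplitude,
    correlation and phase-space diagnostics on gridded fields.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
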