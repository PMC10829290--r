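Package: preyscape
Title: Linking Predator Space Use to Acoustically Measured Prey Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying the three-dimensional
    movements of a large filter-feeding predator in relation to zooplankton
    prey fields measured by ship-based echosounder surveys. Provides
    echogram cleaning and echo integration to mean volume backscattering
    strength (MVBS) and nautical area scattering coefficient (NASC), a
    distorted-wave Born approximation (DWBA) bent-cylinder target-strength
    model to scale backscatter to volumetric prey density, biologging tag
    processing (tag-detachment filtering, time-at-depth and
    time-at-temperature histograms, spline pseudo-track reconstruction),
    two- and three-dimensional kernel utilisation distributions with
    isopleth areas and volumes, variogram-derived spatial matching of prey
    density to predator locations, and mixed-effects habitat models with
    Akaike-weight model comparison. A synthetic-data module generates
    reef-edge bathymetry, patchy prey fields, forward-modelled echograms
    and simulated shark tracks with known ground truth, so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    broom,
    withr
Config/testthat/edition: 3
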