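Package: edhwheat
Title: Extreme Dry-Heat Indices and Greenhouse-Gas Emission Intensity of Wheat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify how compound dry-heat extremes affect the
    greenhouse-gas emission intensity (GHGI) of wheat systems. Computes annual
    heat-day, dry-day and compound dry-heat day counts from daily climate
    (Hargreaves potential evapotranspiration and a daily aridity index),
    converts CO2, N2O and CH4 fluxes to CO2 equivalents (GWP100), measures the
    sensitivity of yield, net GHG and GHGI to the extreme-day counts with
    detrended 20-year moving-window correlations, tests trends per grid cell
    (OLS) and regionally (Mann-Kendall), attributes yield and emission changes
    across factorial driver scenarios, and derives environment-specific
    no-till/conventional-till recommendation maps from positive-effect
    frequencies. Ships a synthetic gridded data generator with known injected
    couplings so every stage has a ground-truth recovery test, plus CF-style
    NetCDF and long-format CSV readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    ncdf4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
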