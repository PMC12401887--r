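Package: thermoreg
Title: Leaf Thermoregulation Metrics from Paired Leaf/Air Temperature Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes leaf thermoregulation metrics from paired leaf and air
    thermocouple time series recorded in controlled glasshouse experiments:
    the thermal offset (delta-T = T_leaf - T_air), the thermal coupling
    strength (beta, the slope of T_leaf on T_air estimated in 30-minute
    windows), and the resulting thermoregulatory classification
    (limited homeotherm, poikilotherm, megatherm). Also derives leaf
    structural traits (LWC, LDMC, LMA, LD) from raw leaf measurements,
    summarises trait covariation by principal components analysis, computes
    the leaf thermal time constant from a simple energy-balance model, and
    provides fixed-effects treatment-by-biome ANOVA, Tukey-Kramer contrasts
    and nonparametric bootstrap confidence intervals. A seeded synthetic-data
    generator emulates the glasshouse study design (air profiles with
    evaporative-cooler dips, per-plant linear leaf/air coupling,
    biome-clustered traits) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
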