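Package: bloomflux
Title: Subseasonal Chlorophyll Fluctuations and Air-Sea Forcing of the
    Winter-Spring Bloom
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking subseasonal surface-chlorophyll
    fluctuations to atmospheric modulations of upper-ocean vertical
    stability (net heat flux and wind stress) during the winter-spring
    bloom. Provides a Census X-11 style seasonal-trend-irregular
    decomposition for 8-day ocean-colour series, net-growth-rate and
    flux metrics, zero-crossing event detection with lagged composites
    and bin-averaged growth-stability relations, sign-agreement and
    bloom-region maps, gridded and pixel time-series input/output
    (NetCDF and CSV), and a stochastic simulator coupling storm-driven
    atmospheric forcing to a slab mixed-layer phytoplankton model for
    testing the whole chain under known mechanisms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ncdf4,
    pracma,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
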