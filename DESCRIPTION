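Package: tidewave
Title: Wavelet Analysis of Tidally Driven Coastal Plankton Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing high-frequency coastal mooring time series
    of chlorophyll fluorescence, suspended particulate matter, salinity,
    temperature, nitrate and water level. Implements preprocessing to
    relative rates of change (log transform, 3-point smoothing,
    differencing), hourly and daily averaging with dark-only chlorophyll
    means, gap handling and segmentation, the Morlet continuous wavelet
    transform with AR(1) red-noise significance testing, segment-aggregated
    global wavelet spectra, and wavelet coherence with Monte-Carlo
    significance and phase-angle distributions. A synthetic-data generator
    produces tidal water levels from harmonic constituents (M2, S2, N2)
    together with co-varying sediment, phytoplankton, salinity, nitrate,
    temperature and irradiance series with known ground truth, so the whole
    pipeline can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
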