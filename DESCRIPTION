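Package: heterogrow
Title: Heterosis Analysis of Yeast Growth-Rate and Stress-Survival Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying hybrid vigour (heterosis) in microbial
    fitness experiments. Estimates maximum growth rates from microplate
    optical-density time series by selecting, per environment, the OD window
    that maximises the mean Pearson correlation of log OD versus time across
    all cultures, and regressing within it; computes mid-parent and
    best-parent heterosis stratified by cross class; decomposes replicate
    variation into environment, genotype, genotype-by-environment and error
    components with intraclass correlations; analyses agar-patch stress
    assays (intensity-to-cell-count calibration, grower classification,
    survival curves, resampling null distributions, two-sample
    Kolmogorov-Smirnov tests); and includes a synthetic-data generator that
    simulates clade-specific accumulation of recessive deleterious mutations
    and their complementation in hybrids, so that every stage of the
    analysis can be exercised and validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
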