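Package: pamkit
Title: PAM Chlorophyll-Fluorescence Trace Simulation, Quenching Analysis
    and Factorial Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pulse-amplitude-modulated (PAM) chlorophyll
    fluorometry phenotyping experiments. Simulates fluorescence traces for
    light-curve, Kautsky-induction and fast (OJIP) transient protocols with
    known ground-truth parameters; extracts the named fluorescence landmarks
    (F0, FM, FM', F(t), F0'', FM''; FO, FJ, FI, FP); computes PSII quantum
    yields, relative electron transport rates, the non-photochemical and
    photochemical quenching coefficients (NPQ, qE, qI, qP, qL, PQ) and the
    JIP-test specific energy fluxes (ABS/RC, TR0/RC, ET0/RC, DI0/RC, PI_ABS);
    and compares groups in factorial designs with two-way ANOVA, Tukey HSD
    and Duncan multiple range tests, reported as compact letter displays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tibble,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
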