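Package: smileframe
Title: Beauty-Frame Midline, Facial Proportion, and Smile-Framework Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based analysis of frontal facial photographs for
    aesthetic dentistry research. Constructs the canthal-aligned "beauty
    frame" that operationalises the facial midline, computes relative
    facial-midline (RFV) and commissural-midline (RCV) values for the
    nasion, nose tip, philtrum tip, dental midline and mouth midline,
    measures vertical and transverse facial proportions against the
    divine ratio 1.618, classifies the smile framework (smile arc, upper
    lip curvature, smile line, smile width, tooth shape and size), and
    summarises cohorts with the field's standard tests (chi-square /
    Fisher, Mann-Whitney, Pearson, ICC(2,1) reliability). A seeded
    synthetic-cohort generator emulates the statistical structure of a
    photographic study population so the full pipeline is testable
    without patient images.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
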