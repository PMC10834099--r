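Package: ibrkit
Title: Integrated Biomarker Response Indexes (IBR and IBRv2) with Radar Charts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the two composite indexes commonly used to integrate
    multibiomarker responses in ecotoxicological biomonitoring: the revised
    Integrated Biomarker Response (IBR), obtained as the star-plot area of
    standardized, direction-adjusted biomarker scores averaged over all
    distinct circular arrangements of the biomarkers, and the Integrated
    Biological Responses version 2 (IBRv2), obtained as the sum of absolute
    standardized log-ratio deviations from a reference site. Includes
    delimited-file input with validation of the admissibility rules for
    biomarker tables, a deterministic synthetic data generator for
    multi-site enzyme-activity datasets, radar-chart rendering to SVG, PNG
    and PDF, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
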