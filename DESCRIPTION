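Package: healthpipe
Title: Automated Ingestion, Analysis and Reporting of Public Health Indicator Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-command analytics pipeline for unit-level public health
    indicator tables served by paginated CSV REST APIs. Provides robust paginated
    ingestion with exponential-backoff retry, deterministic preprocessing (column
    harmonisation, numeric coercion, aggregate-row removal, median imputation,
    feature derivation) with a row-count audit trail, a pluggable analysis stage
    (z-score normalisation, unweighted composite scoring rescaled to 0-100,
    k-means stratification, Pearson correlation, Welch and paired t-tests), a
    deterministic rule-based narrative engine, and programmatic generation of a
    timestamped Word (OOXML) report with tables and embedded figures. A synthetic
    data generator and in-process mock API make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    MASS,
    yaml,
    jsonlite,
    xml2,
    zip,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    curl,
    withr
Config/testthat/edition: 3
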