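Package: vfmchart
Title: Value-for-Money Charts for Health Technology Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-support tools for prioritizing health technologies
    under a budget constraint using a value-for-money chart: an additive
    points system scores each technology's incremental benefits, pairwise
    trade-off questions elicit the point values, technologies are plotted
    as benefit versus total cost with quality-of-evidence bubble sizes and
    X-factor flags, Pareto-efficiency frontiers identify best-value
    candidates, and an exact 0-1 knapsack solver benchmarks the
    budget-constrained selection.  Includes the illustrative points system
    and 18-technology portfolio used throughout the documentation, a
    synthetic portfolio generator for testing, SVG chart rendering, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
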