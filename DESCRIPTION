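Package: effdisc
Title: Effort Discounting Model Fitting and Comparison for Titration Choice Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing effort-discounting experiments run with a
    titration (adjusting-amount) choice questionnaire. Builds the 2 (effort
    domain) x 3 (reward amount) x 5 (effort intensity) design with its
    30-row descending money ladders, extracts indifference points from
    single-switch choice sequences, fits seven subjective-value discounting
    models (hyperbolic, parabolic, exponential, Myerson-Green hyperboloid,
    Rachlin hyperboloid, two-parameter exponential, two-parameter power
    function) jointly across reward magnitudes by nonlinear least squares,
    compares them with SSE-based AIC, small-sample corrected AICc and BIC,
    and runs the accompanying nonparametric comparison suite (Friedman,
    Wilcoxon signed-rank with Sidak correction, Cochran's Q, McNemar,
    Spearman correlations). Includes a synthetic-cohort generator that
    simulates titration choices with magnitude-dependent parameters and
    cross-domain correlation, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
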