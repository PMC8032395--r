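Package: mvrelease
Title: Statistics and Ideal-Observer Modelling of Multivesicular Glutamate
    Release from Rod Photoreceptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing glutamate-transporter current
    recordings from rod photoreceptor terminals, where release in darkness is
    dominated by coordinated multivesicular events occurring at sub-Poisson
    (Erlang-like) regular intervals. Provides a synthetic-trace generator with
    ground truth, template-matched event detection (Clements-Bekkers),
    interevent-interval and Poisson-count statistics, rundown corrections,
    peri-stimulus histograms and event-triggered averages; generative models of
    rod output (time-dependent Erlang multivesicular release, asynchronous
    Poisson release, and a photocurrent model with thermal and continuous
    noise); and a two-alternative forced-choice ideal-observer analysis with
    Bayes-optimal pooling, psychometric fitting, and detection-threshold sweeps
    linking release statistics to rod-bipolar-cell flash sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
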