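Package: groomr
Title: Automated Long-Term Grooming Detection and Circadian Analysis for
    Single Flies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Video-based classification of Drosophila behavior in
    individual activity-monitor tubes. Segments a single dark fly from
    8-bit grayscale video by background subtraction with periodic
    background refresh, splits the silhouette into core and periphery at
    the per-fly median grayscale, extracts three normalized movement
    features (periphery movement, core movement, centroid displacement),
    labels every analyzed frame as grooming, locomotion or rest with a
    k-nearest-neighbors classifier searched through a k-d tree, and prunes
    spurious grooming labels with a 12-of-15 sliding-window filter.
    Feeding (prolonged proximity to food) and sleep (quiescence of five
    minutes or more) rules extend the output to a five-behavior ethogram,
    which is binned into fraction-of-time series for circadian analysis:
    variance-normalized Lomb-Scargle periodograms with analytic
    significance thresholds, dominant-period extraction, a two-peak
    piecewise-exponential activity model, grooming-shuffling experiments,
    and bootstrap tests of Pearson correlations. A synthetic fly-video and
    ethogram generator provides ground truth so the whole pipeline is
    testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    png,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
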