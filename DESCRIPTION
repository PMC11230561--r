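Package: barqtl
Title: Quantification of Melanic Barring and QTL Mapping in F2 Intercrosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies vertical melanic barring on fish flanks as
    one-dimensional grayscale intensity profiles, calls bars and interbars
    with a run-length thresholding algorithm, derives eleven pigment-level
    and patterning traits, and maps those traits in an F2 intercross with a
    multiple-QTL engine: Haley-Knott regression scans on hidden-Markov
    genotype probabilities, genome-wide permutation significance thresholds,
    iterative cofactor selection with backward elimination, Bayes credible
    intervals for QTL location, and allelic effect estimation at peak
    markers. Includes simulators for barred intensity profiles with known
    segment ground truth and for F2 crosses with planted QTL, so every stage
    is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, tools, png, tiff, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
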