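Package: cttselect
Title: Classical Test Theory Statistics and Goal-Directed Item Selection
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classical test theory statistics for questionnaire construction
    (coefficient alpha, corrected item-total correlations, sum-score predictive
    validity, and their leave-one-item-out variants), stepwise-backward and
    exhaustive item-subset selection under a measurement objective (maximize
    alpha) or a prediction objective (maximize criterion validity), population
    true-score models exhibiting the reliability-versus-alpha paradox, and a
    Likert-item simulator with latent factors and a binary gold-standard
    criterion. Includes a published ten-item depression-questionnaire
    correlation matrix as a worked example.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
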