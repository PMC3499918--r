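Package: recipz
Title: Reciprocal Reading-Speed Scores and Normative Z-Score Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the diagnostic consequences of expressing
    reading speed as seconds per syllable (sec/syll) versus its reciprocal,
    syllables per second (syll/sec). Because the two scores are linked by a
    hyperbola, z-scores computed against normative samples on the two scales
    disagree, and a performance can be classified pathological on one scale
    and normal on the other. The package provides deterministic score
    algebra (reciprocal transforms, z-scores, log scores, cut-off
    classification), a Monte Carlo engine that maps z-scores between scales
    as a function of the normative Mean/SD ratio, an independent numerical
    quadrature oracle for the moments of the positivity-conditioned
    reciprocal-normal distribution, synthetic normative cohorts and pre/post
    treatment designs, and executable checks of the rank-based equivalences
    (percentile complementarity, rank-sum test invariance) and of the
    interaction-term discordance that arises in factorial designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
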