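Package: obmix
Title: Odour-Mixture Summation and Population Coding in Olfactory Bulb
    Calcium Imaging
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of how olfactory bulb output neurons sum binary odour
    mixtures across brain states, from ROI-level calcium fluorescence to
    population decoding. Converts trial fluorescence to delta-F/F and
    windowed response amplitudes; quantifies mixture summation via the
    masking index, fractional deviation from the linear sum, and the
    joint-SEM deviation from linearity; measures population-pattern
    similarity and a correlation-based discriminability index; decodes
    target-odour presence with zero-intercept linear max-margin
    classifiers, including single-odour to mixture cross-generalization;
    and simulates the effect of a saturating (normalising) sublinearity on
    decoding accuracy. A synthetic-session generator with state presets
    (anaesthetised, awake behaving, naive engaged/disengaged) provides
    fully reproducible inputs for every stage, and Go/No-Go behavioural
    metrics (learning curves, lick preference index) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
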