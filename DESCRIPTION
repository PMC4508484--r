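Package: dyadENA
Title: Epistemic Network Analysis of Dyadic Gaze Coordination
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models coordinated referential gaze in collaborating dyads with
    epistemic network analysis (ENA). AOI-labelled fixation streams from an
    instructor and a worker are discretised into 50 ms segments over
    five-phase reference-action sequences, accumulated into cross-person
    co-occurrence networks, normalised to the unit hypersphere and projected
    by singular value decomposition into a low-dimensional space with a
    least-squares node layout. The package implements phase mean networks
    and centroid comparisons, lag-scan gaze alignment with same/different
    recoding and a lag-shifted ENA space, leave-one-dyad-out nearest-centroid
    phase prediction, repair versus no-repair contrasts, and a calibrated
    semi-Markov generator of synthetic dyadic gaze corpora for end-to-end
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'codes.R'
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'discretize.R'
    'descriptives.R'
    'generator.R'
    'expected-alignment.R'
    'ena.R'
    'groups.R'
    'lag.R'
    'predict.R'
    'repair.R'
    'pipeline.R'
    'plots.R'
    'dyadENA-package.R'
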