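Package: perilesion
Title: Spike Detection and Waveform-Turnover Analysis for Chronic
    Multielectrode Recordings Around Electrolytic Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing chronic intracortical multielectrode
    (Utah-array) recordings before and after small electrolytic lesions
    made through the array itself. Implements the full processing chain
    from raw multichannel voltage traces to accepted spike snippets
    (zero-phase Butterworth high-pass filtering, RMS-based threshold
    detection, waveform quality control, event rates); a day-to-day
    waveform-turnover statistic based on per-electrode PCA projections,
    median radii and their change (delta-r), one-dimensional Gaussian
    mixture models with BIC model selection, five-way change
    categorisation and percent match across the array; day-pair group
    construction (pre-pre, pre-post, post-post) with Mood's median test
    and Bonferroni correction; lesion-volume geometry (cone, sphere),
    an exponential volume-duration model, and analytic calculators for
    the lesioning device electronics. A synthetic-recording generator
    emulates a 96-channel array recording a local neuron population
    with Poisson firing, distance-dependent waveform amplitude,
    day-to-day population drift and a parametric lesion, so the whole
    pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    signal,
    minpack.lm,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'RcppExports.R'
    'filter.R'
    'detect.R'
    'geometry.R'
    'groups.R'
    'io.R'
    'mixture.R'
    'perilesion-package.R'
    'physics.R'
    'turnover.R'
    'pipeline.R'
    'template.R'
    'population.R'
    'render.R'
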