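Package: vasoloop
Title: Loop Analysis of Blood Pressure and Volume Homeostasis Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Qualitative and quantitative analysis of the neuroendocrine
    feedback loops that regulate vasomotor tone, blood volume and mean
    arterial pressure through the vasopressin (AVP), atrial natriuretic
    peptide (ANP) and renin-angiotensin-aldosterone (RAAS) systems.
    Provides signed-digraph tools (elementary-cycle enumeration, cycle
    signs, cooperative gauge transformations proving monotonicity,
    candidate-oscillator checks), parameter-free structural influence
    matrices computed as the entrywise sign class of the adjugate of the
    negated interaction matrix, Hill-parameterised ODE realisations of the
    networks with time-scale-separation model reduction, delay
    differential equation simulation of the AVP-ANP-vascular smooth muscle
    loop, and a delay-dependent oscillation-propensity analysis based on
    the distance of the characteristic curve from the origin of the
    complex plane, including critical loop-gain computation and propensity
    surfaces over loop-delay pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'hill.R'
    'signed-graph.R'
    'graph-io.R'
    'fixtures.R'
    'influence.R'
    'model.R'
    'aar.R'
    'aav.R'
    'propensity.R'
    'params.R'
    'reproduce.R'
    'vasoloop-package.R'
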