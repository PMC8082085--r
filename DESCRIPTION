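Package: gonogo
Title: Spike-Train Analysis of Odor-Guided Go/No-Go Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of sorted spike trains recorded from
    olfactory-cortex neurons during odor-guided go/no-go behavior:
    auROC-based response quantification with permutation significance,
    five-type neuron classification, sliding-window response dynamics,
    a Poisson encoding model separating odor-triggered from pre-movement
    activity, population trajectory geometry, linear population decoding,
    and a seeded inhomogeneous-Poisson session simulator with ground-truth
    neuron archetypes for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
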