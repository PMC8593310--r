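Package: multidrive
Title: Simulating Driver Multitasking as Hierarchical Reinforcement Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulator of visual attention allocation in dual-task driving.
    Lane keeping and an in-car visual search task are each modelled as a
    partially observable Markov decision process; a supervisory policy learns,
    by tabular SARSA with softmax exploration, when to glance at the in-car
    display and when to return the eyes to the road. Eye-movement timing
    follows the EMMA model of encoding and saccades. The package reproduces a
    2x2 driving-simulator protocol (speed by search-set size), extracts the
    standard distraction metrics (trial time, SD of lateral offset, lane
    deviations, number and duration of in-car glances) from event traces, and
    computes model-to-human fit indices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    readr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
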