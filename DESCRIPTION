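Package: wmseq
Title: Working-Memory-Limited Motor Sequence Learning Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models and simulation tools for capacity-limited learning of
    movement sequences. Implements the Welford speed-accuracy law relating
    movement time to amplitude and target width, a limited-capacity
    working-memory buffer that writes sequence elements to long-term storage
    in chunks, and a model-free reinforcement-learning instantiation in which
    tabular Q-learning updates pass through a fixed-capacity,
    significance-gated working-memory queue. Also provides the eight-target
    centre-out sequence-learning task (geometry, trial schedules, recall
    scoring, termination detection), its behavioural outcome measures
    (correct recall, movement times, path length, block means, chunk
    increments), a synthetic-cohort generator with age, hand and
    mouse-orientation condition structure, and a grid-search estimator of
    working-memory capacity from recall curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
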