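Package: landmaze
Title: Associative Landmark Learning and Swimming Dynamics in the Morris Water Maze
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates how rats learn to navigate to a hidden platform in the
    Morris water maze from extra-pool landmarks. Couples a Rescorla-Wagner
    associative learner -- competitive cue-usage learning plus independent
    per-cue direction and distance channels -- to an autoregressive random-walk
    swimming model with proportional feedback heading control. Provides the
    trial protocol (acquisition, platform-absent retention probes), scenario
    batteries for cue-salience manipulation, cue removal, stimulus
    generalization, cue misinterpretation and overshadowing, and summary
    metrics (escape latencies, quadrant occupancy, coefficient-of-variation
    contrasts, platform-guess concentration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
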