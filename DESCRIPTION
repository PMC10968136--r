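Package: crowdadapt
Title: Adaptive Cooperative Crowd Motion Simulation over Diffusion Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulation of cooperative crowd movement through
    geometrically varying corridors using adapt-then-combine (ATC) diffusion
    adaptation. Each agent estimates the local corridor width from the chord
    of the circle inscribed between the two walls at its station, derives a
    width-dependent walking speed and a speed-dependent social distance
    (doubled for agents with disabilities, who also walk at half speed),
    composes its velocity from goal-seeking/obstacle-avoidance, a diffusion
    estimate of the network's centre-of-gravity velocity, and a cohesion term,
    and receives a heading advisory relative to the shared target. Includes a
    bottleneck scenario generator, trajectory summaries, a replayable
    location-stream adapter, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
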