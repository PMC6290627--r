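Package: teamdyn
Title: Collective Tactical and Individual Kinematic Metrics from 2-D
    Positional Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes collective tactical behaviour metrics (group centroid
    and derived distances, stretch index and its rate of change, convex-hull
    surface area and hull overlap, team length and width), inter-player
    coordination measures (Hilbert-transform relative phase, circular
    summaries, Approximate Entropy) and individual kinematic metrics (speed,
    five-class pace discretisation, distance covered by pace, occupancy and
    pace heat maps, distance to a point) from fixed-rate 2-D positional
    tracking data such as player tracking in team sports. Includes a
    deterministic synthetic trajectory generator with injected ground truth
    (phase offsets, centroid crossovers, coordination breaks) so every metric
    is testable without external data, plus a scriptable command-line front
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
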