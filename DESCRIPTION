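Package: marmopull
Title: Cooperative Lever-Pulling Sessions: Task Contingencies, Dyadic
    Simulation, Gaze Cones and Peri-Event Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Software re-implementation of an automated cooperative
    lever-pulling paradigm for marmoset dyads. Provides a task engine that
    converts lever-position traces into pull events and enforces the
    Self-Reward and Mutual Cooperation reward contingencies; a dyadic
    point-process simulator that generates fully synthetic sessions (pull
    events, lever traces, 3D facial keypoints, vocalization times, spike
    trains) with known ground truth; session-level performance metrics
    (success rate, rewards per working minute, inter-pull time); 3D
    gaze-target classification from six facial keypoints via a virtual
    gaze cone with bout segmentation; and event-aligned analyses
    (sliding-bin peri-event time histograms with bin-wise rank-sum
    comparison between conditions).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
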