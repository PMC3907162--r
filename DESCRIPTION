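Package: gazerig
Title: Simulated Closed-Loop Control and Analysis of Gaze-Contingent
    Neurophysiology Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A hardware-free, deterministic re-implementation of a
    script-based experiment-control rig for gaze-contingent behavioral
    tasks. Three cooperating endpoints -- a real-time sequencer that
    scores fixation against a forgiveness window, a session controller
    with a six-case dispatch table, and a stimulus presenter with frame
    quantization and TTL timestamping -- run closed-loop trials against
    a simulated subject. A virtual rig generates saccadic gaze traces
    and inhomogeneous-Poisson spike trains for four neuron archetypes,
    multiplexed into a multichannel session recording. Analysis tools
    provide saccade detection, event-aligned rasters, peristimulus time
    histograms, spike-density functions, first-peak response latency
    and preferred-saccade-vector estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
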