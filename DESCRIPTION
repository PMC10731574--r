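Package: reachcomp
Title: Movement Component Decomposition of Upper-Limb Reaching Trials
Version: 0.1.0
Authors@R: person("reachcomp", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Decomposes seated upper-limb reaching trials recorded with a
    simplified 10-marker motion-capture set into named joint, trunk and neck
    component displacements and percent contributions, for forward-reach and
    hand-to-mouth tasks. Marker displacements are calibrated against the
    greater trochanter so whole-body translation cancels, and each task's
    total reach distance decomposes telescopically into shoulder/elbow,
    trunk and compensatory components that sum to the total by construction.
    Includes trial-table and C3D readers, zero-phase Butterworth filtering,
    velocity-threshold reach-window detection, a seated kinematic-chain
    simulator with healthy and stroke strategy presets for synthetic data,
    two-group cohort statistics, and stacked-contribution plots.
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
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
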