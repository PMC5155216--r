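Package: shockmd
Title: Shock-Compression Molecular Dynamics and Reactive Trajectory
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Desk-scale tools for studying shock-driven chemistry in
    iron/dinitrogen/water mixtures of the kind invoked for prebiotic
    ammonia synthesis. Provides a classical molecular-dynamics engine
    with multi-scale shock technique (MSST) cell dynamics, Nose-Hoover
    canonical sampling and distance-constrained (blue-moon) dynamics;
    lifetime-filtered bond detection, molecular speciation and
    formation-event tracking on atomistic trajectories; mean-squared
    displacement and self-diffusion estimators, thermodynamic
    integration of constrained forces, transition-state-theory rates,
    and Rankine-Hugoniot jump-condition diagnostics; plus seeded
    synthetic-trajectory generators (scripted reactive events, Brownian
    walkers, shock profiles) so the full pipeline runs without any
    external data. Trajectories are read and written as extended XYZ.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
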