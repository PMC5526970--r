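Package: phagegame
Title: Competition and Evolution of Lysis-Lysogeny Strategies in Temperate Phages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates pairwise competition between two temperate phage
    variants infecting one bacterial host, using stiff ODE models of the
    buildup/crash/lysogenic-growth dynamics. Treats the competition as a
    two-player zero-sum game whose payoff is the steady-state lysogen share,
    locates the minimax-optimal lysogeny propensity as the saddle point of the
    payoff matrix, runs an iterated evolutionary game over strategies that
    depend on the multiplicity of infection, and provides the analytic
    crash-time approximation for the optimal propensity together with
    parameter-sweep robustness analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
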