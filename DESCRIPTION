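Package: thzpore
Title: Whole-Cell Electroporation and Na+,K+-ATPase Energetics Under
    Terahertz Unipolar Pulse-Train Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic whole-cell simulator coupling an asymptotic
    (Neu-Krassowska) electroporation model, a quasi-static spherical-cell
    potential solver, generalized modified Poisson-Nernst-Planck
    transmembrane ion fluxes with finite effective ion size, and a
    four-state Na+,K+-ATPase cycle model, driven by terahertz unipolar
    picosecond pulse trains. Provides pump current-voltage curve
    generation and weighted least-squares fitting of cycle parameters,
    synthetic fixture generators with analytic oracles, trajectory
    recording, and detectors for pore activation and pump closure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
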