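Package: stemfit
Title: Fractional-Order Equivalent-Circuit Modeling of Plant Stem Bioimpedance
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Evaluates five fractional-order equivalent-circuit models of
    plant-tissue electrical impedance (single- and double-dispersion Cole,
    fractional-order double-shell, and two multi-branch stem models built
    from constant-phase elements), and extracts their parameters from
    impedance spectra by bound-constrained metaheuristic optimization
    (water cycle, flower pollination, cuckoo search, and chicken swarm
    algorithms).  Includes an independent circuit-topology oracle for
    verifying the closed-form impedance expressions, a synthetic spectrum
    generator with proportional complex noise, CSV readers and writers for
    spectra and fit results, and command-line entry points for simulating,
    fitting, and comparing models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
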