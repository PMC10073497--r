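Package: fatiguekit
Title: Stress-Life Fatigue Analysis and Staircase Testing for
    Additively Manufactured Implant Plates
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for stress-life (S-N) fatigue assessment of
    load-bearing implant components such as 3D-printed titanium
    osteosynthesis plates: synthesis of Basquin stress-life curves from
    material-standard minimum properties with a fabrication knock-down
    factor, Goodman and Gerber mean-stress corrections, strain-life
    (Coffin-Manson) transition analysis, a Neuber-type plastic correction
    of over-yield elastic peak stresses on a bilinear hardening law,
    capped fatigue-life prediction per load case, Basquin force-life
    regression with runout censoring policies, a modified staircase
    (up-and-down) fatigue test protocol with a sample-size sufficiency
    test, and a virtual-specimen population simulator for validating the
    protocol end to end without physical testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
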