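Package: evicdsim
Title: Simulation of Extravascular ICD and Leadless Pacemaker Sensing
    Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how asynchronous pacing artefacts from a leadless
    ventricular pacemaker affect ventricular fibrillation (VF) detection by an
    extravascular implantable cardioverter-defibrillator (ICD). Provides a
    seeded synthetic VF electrogram generator, episode looping with smooth
    junctions, a pre-amplifier model and pacing-spike overlay, a generic
    auto-adjusting-sensitivity sensing and interval-based VF detection engine,
    sweep harnesses for detection grids and spike-to-VF ratio response curves,
    an idealized volume-conductor model of inter-device electrode geometry,
    and Monte Carlo estimation of population-level interaction risk from
    implant-distance distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
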