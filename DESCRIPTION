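Package: foilsim
Title: Analytical Simulator for Electron Dual Scattering Foil Systems
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Real-time analytical modeling of the dual scattering foil
    systems used to broaden and flatten clinical electron beams on
    radiotherapy linear accelerators. Transports a monoenergetic electron
    beam through the vacuum exit window, primary foil, air gaps and a
    shaped secondary foil with Fermi-Eyges pencil-beam theory, using
    Moliere multiple-scattering powers with the reduced-Gaussian
    correction and ICRU-35-style electron stopping powers. Computes
    off-axis electron relative fluence/dose profiles, central-axis and
    off-axis bremsstrahlung (X-ray) contamination dose via a Schiff-style
    exponential-integral model with an empirical central-axis calibration,
    combined total relative dose profiles, and flatness metrics against
    objective profiles, supporting foil design through parameter sweeps
    and objective-profile refinement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
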