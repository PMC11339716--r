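Package: cochleabox
Title: Reduced-Order Frequency-Domain Model of Human Cochlear Mechanics with Forward and Reverse Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A two-duct transmission-line ("box") model of the human cochlea
    solved in the frequency domain, for comparing oval-window (forward) and
    round-window (reverse) mechanical stimulation as delivered by active
    middle ear implants.  The basilar membrane is an orthotropic, locally
    reacting partition; the oval window is closed by a stapes footplate
    suspended on the stapedial annular ligament and the round window by a
    clamped elastic membrane, so that otosclerotic fixation and round-window
    ossification can be modelled by stiffening either boundary.  The package
    computes middle ear transfer functions, cochlear input and reverse middle
    ear impedances, window volume-velocity ratios, characteristic-frequency
    maps against the Greenwood place-frequency curve, travelling-wave phase
    profiles, and relative basilar-membrane amplitudes used as a hearing
    threshold proxy across pathology scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
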