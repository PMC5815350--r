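Package: cryosynapse
Title: Quantitative Cryo-Electron Tomography Morphometry of Synapses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of synaptic architecture in cryo-electron
    tomograms: normalized cross-sectional density profiles of the synaptic
    junction with postsynaptic density (PSD) peak position and exponential
    tail metrics (d1, lambda, d2 = d1 + lambda, cleft width); two-cluster
    separation of excitatory-like (thick PSD) and inhibitory-like (thin PSD)
    synapses; synaptic-vesicle detection by spherical-shell template matching
    with 2D ellipse and 3D ellipsoid shape analysis; membrane-attached
    particle morphometry against receptor reference dimensions simulated
    from atomic models; and least-squares landmark registration between
    light-microscope, electron-microscope, and stage coordinate frames.
    Includes phantom generators (synthetic junction slabs, vesicle fields,
    landmark sets, missing-wedge filtering) so every stage is testable with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    mclust,
    bio3d,
    jsonlite
Suggests: testthat (>= 3.0.0), ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
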