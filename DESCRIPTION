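Package: adiposim
Title: Light Propagation and OCT Image Simulation in Adipose Cell Layers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the propagation of focused near-infrared light through
    layered lattices of adipocytes modelled as three-shell dielectric
    cylinders (lipid core, cytoplasm, membrane) immersed in interstitial
    fluid. Provides a convergent Born series full-wave Helmholtz solver and a
    fast unidirectional split-step solver for photonic-jet and hot-spot
    phenomenology, analytic Bouguer-Beer-Lambert transmittance with a
    Mie-estimate scattering coefficient and its inversion to the relative
    refractive index, wave Monte-Carlo synthesis of optical coherence
    tomography A-, B- and C-scans, and the brightness statistics used to
    quantify OCT image inhomogeneity (relative dispersion, windowed
    hot-spot intensity ratios, noise-referenced contrast stretching).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    tiff,
    png,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
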