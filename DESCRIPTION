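Package: holostim
Title: Hologram Synthesis and Analysis for 3D Two-Photon Optogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for all-optical two-photon read/write experiments in
    three dimensions. Synthesizes multi-target spatial-light-modulator
    (SLM) phase holograms with Zernike defocus and spherical-aberration
    compensation, by complex superposition or by a multi-plane
    Gerchberg-Saxton algorithm; simulates the resulting 3D two-photon
    focal field with a Debye/angular-spectrum propagator; calibrates
    SLM-to-imaging coordinates with depth-interpolated affine transforms
    and a diffraction-efficiency model; plans spiral-scan
    photostimulation schedules with an explicit laser power budget;
    removes mesh-grid photostimulation artifacts from calcium-imaging
    movies; and analyzes stimulation-locked calcium responses (event
    detection, responder classification, distance-dependent nonspecific
    activation, orientation selectivity). Includes a synthetic-data
    generator for multi-plane GCaMP movies with ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
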