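Package: microdoppler
Title: Functional Ultrasound MicroDoppler Processing and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for functional ultrasound (fUS) neuroimaging of
    pharmacologically evoked cerebral blood volume (CBV) dynamics. Simulates
    complex IQ Doppler ensembles with low-rank tissue clutter, vessel-confined
    blood signal driven by a piecewise hemodynamic time course, and additive
    noise; separates blood from clutter by singular value decomposition of the
    spatiotemporal Casorati matrix; forms noise-bias-corrected microDoppler
    (power Doppler) images; maps percent CBV change against a baseline window
    with region-of-interest time courses; compares time points with a
    Wilcoxon rank-sum contrast; and analyses simulated local field potentials
    with multitaper spectrograms. A plane-wave delay-and-sum beamformer and a
    channel-data simulator validate the assumed acquisition geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
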