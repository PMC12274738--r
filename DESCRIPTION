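Package: spiralscan
Title: Compound Double-Spiral Resonant Scanning Simulation and Vascular
    Morphometry for Photoacoustic Endoscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs Archimedes, Fermat and compound Archimedes-Fermat
    double-spiral scanning trajectories for resonant MEMS-based
    photoacoustic endoscopy, quantifies their sampling homogeneity and
    laser-energy deposition on a pixel grid, and simulates the full
    imaging chain on synthetic vascular phantoms: per-pulse
    dual-wavelength acquisition, scattered-sample image reconstruction,
    landmark-based rigid stitching, two-wavelength hemoglobin unmixing
    into oxygen saturation and relative total hemoglobin maps, and a
    vessel morphometry suite (total vessel length, branch points, mean
    diameter, tortuosity and box-counting fractal dimension) validated
    against known phantom ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'trajectory.R'
    'waveforms.R'
    'sampling.R'
    'extinction.R'
    'phantom.R'
    'acquire.R'
    'reconstruct.R'
    'rigid.R'
    'unmix.R'
    'skeleton.R'
    'morphometry.R'
    'io.R'
    'pipeline.R'
    'utils.R'
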