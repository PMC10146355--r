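Package: genotoxHCS
Title: High-Content gammaH2AX Genotoxicity Scoring from Two-Channel
    Plate Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end quantification of DNA double-strand-break response
    from 96-well immunofluorescence plates. Sorts two-channel (DAPI/Cy3)
    field images by their acquisition filename convention, segments nuclei
    in the DAPI channel by Otsu auto-thresholding with per-well threshold
    propagation, removes edge-touching objects, subtracts local Cy3
    background with a rolling-ball filter, measures per-nucleus mean
    gammaH2AX fluorescence, pools objects into non-parametric well
    summaries, and scores treated wells against their negative control via
    area-scaled fold change (MoA) and relative nuclei area (RA), yielding a
    genotoxic / non-genotoxic / cytotoxicity-driven false-positive /
    equivocal call. A synthetic plate generator with full ground truth
    stands in for the microscope so the whole pipeline is testable without
    real images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    EBImage,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'genotoxHCS-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'plate_io.R'
    'segmentation.R'
    'background.R'
    'measure.R'
    'wellstats.R'
    'genotox.R'
    'synth.R'
    'pipeline.R'
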