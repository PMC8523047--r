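Package: sarcokinetics
Title: Segmentation, Tracking and Contractile Mechanics of Sarcomeres in
    Beating Cardiomyocyte Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to quantify contractile function of human induced
    pluripotent stem cell-derived cardiomyocytes (hiPSC-CMs) from
    fluorescence movies of z-disc labeled cells. The pipeline segments
    z-discs per frame, procedurally links z-disc pairs into sarcomeres
    with a ghost-point mutual nearest-neighbor rule, tracks z-discs and
    sarcomeres across frames, reconstructs per-sarcomere length, angle
    and position time series with Gaussian-process regression, estimates
    the average deformation gradient of the tracked cell domain from
    fiducial marker pairs, and derives scalar functional metrics
    (sarcomere shortening, orientational order parameter, isotropic and
    oriented contraction). A ground-truthed synthetic movie generator
    (sarcomere chain skeletons rendered as oriented cylinders, sliced,
    projected, blurred and corrupted with multi-octave Perlin noise)
    makes every stage testable without experimental data. Cells are also
    represented as spatial graphs (z-discs as nodes, sarcomeres as
    edges) to support network-distance based spatiotemporal analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    clue,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
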