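Package: gridsight
Title: Stereo Localization of Intraoperative ECoG Electrode Grids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Localizes a small, deformable 64-electrode intraoperative
    electrocorticography (ioECoG) grid in 3D from low-resolution stereo
    grayscale camera frames. Provides a calibrated pinhole stereo camera
    model with undistortion and rectification, a programmatic synthetic-scene
    renderer with projected ground-truth bounding-box and 68-keypoint labels,
    a detection-crop-upscale-pose pipeline with tail-disambiguated electrode
    indexing, disparity-based stereo triangulation, and a relative-pose
    evaluation harness with median outlier filtering, false-positive
    statistics and per-electrode error heatmaps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    clue,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
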