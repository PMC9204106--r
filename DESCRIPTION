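Package: mobigait
Title: Gait-Related Brain-Body Connectivity from Mobile EEG and Body Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mobile brain/body imaging (MoBI) recordings
    collected during walking: synchronization of EEG and wireless body-sensor
    streams, gait-cycle segmentation from ankle accelerometry, velocity and EMG
    Hilbert envelopes standardized to gait-cycle percentage, multi-stage blind
    source separation artifact screening (kurtosis, sample entropy, band-power
    ratio), eLORETA source reconstruction, and frequency-resolved neurokinematic
    and neuromuscular connectivity (NKC/NMC) with group statistics, ANOVAs and
    voxel-wise connectivity images. Includes a synthetic MoBI data generator
    with known ground truth so that every stage of the pipeline can be
    validated without access to human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    data.table,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
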