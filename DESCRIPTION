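Package: netarget
Title: Network-Targeted Optimization of TMS Coil Placement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the whole-brain network engaged by a transcranial magnetic
    stimulation (TMS) coil placement and scores how well it targets the
    pathological network of a psychiatric disorder. Provides a continuous
    proportional coordinate (CPC) system on the scalp surface, a simplified
    induced electric-field model, voxel-wise functional-connectome operators
    for deriving stimulation networks, pathological-network maps built from
    meta-analysis foci, the network targeting accuracy (NTA) score, grid
    search over coil position and orientation, cohort-level validation
    statistics with permutation nulls, and a synthetic-study generator so the
    whole pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Matrix, RNifti, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
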