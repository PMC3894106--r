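Package: tg43dosim
Title: Brachytherapy Source Characterization from 3D Dosimetry via the
    TG-43 Formalism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts AAPM TG-43 source parameters, the radial dose
    function g_L(r) and the 2D anisotropy function F(r, theta), from a
    voxelized 3D dose distribution measured around a cylindrical
    brachytherapy source, such as an optical-CT readout of a radiochromic
    plastic dosimeter with a drilled source channel.  Includes the
    line-source geometry function, region-of-interest construction with
    morphological erosion, source-pose registration by minimizing the
    product of radial-fit and anisotropy residual errors, per-bin
    statistics and comparison tables against a reference source model,
    and a synthetic phantom simulator so the full pipeline can be
    exercised and validated without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
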