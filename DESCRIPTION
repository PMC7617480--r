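Package: cdwi
Title: Cardiac Diffusion-Weighted MRI on High-Performance Gradient Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for spin-echo cardiac diffusion MRI with strong gradients:
    numerical design of moment-nulled (up to third order), Maxwell-compensated
    asymmetric diffusion gradient waveforms that maximize b-value under
    amplitude and slew-rate constraints; a synthetic short-axis left-ventricle
    phantom and complex-valued diffusion-weighted image generator with known
    ground-truth microstructure; and the analysis pipeline from complex images
    to myocardial microstructure maps (phase correction, two-pass rigid
    registration, shell-wise outlier rejection, weighted linear least-squares
    tensor fitting, mean diffusivity, fractional anisotropy, helix angle and
    secondary eigenvector angle) with Bland-Altman and Wilcoxon signed-rank
    comparison of acquisition schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    EBImage,
    RNifti,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
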