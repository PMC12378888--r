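Package: nmrdesk
Title: Processing, Deconvolution and Visualization of 2D and Pseudo-3D NMR Spectra
Version: 0.1.0
Authors@R: person("NMRdesk", "Developers", email = "nmrdesk@example.org",
    role = c("aut", "cre"))
Description: A headless toolchain for two-dimensional and pseudo-3D NMR data:
    reads Bruker time-domain directories and processed spectra in NMRPipe
    (ft2), UCSF Sparky (ucsf) and TopSpin text formats; performs solvent
    suppression, apodization, zero-filling, Fourier transformation with
    quadrature handling and automatic or manual phase correction;
    reconstructs non-uniformly sampled indirect dimensions by iterative soft
    thresholding; picks peaks and deconvolutes spectra into Voigt, Gaussian
    or Lorentzian components, including pseudo-3D fits with shared lineshapes
    and per-plane heights; fits exponential relaxation rates and CEST
    profiles; and renders contour overlays, cross-sections and 3D
    surface/terrace views. Includes a ground-truth synthetic data generator
    so the full pipeline is testable without external datasets, and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
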