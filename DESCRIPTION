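Package: dectlab
Title: Dual-Energy CT Virtual Monochromatic Imaging of Metal Artifacts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale simulation and quantification of metal artifacts
    around orthopaedic hip-stem alloys in dual-energy CT (DECT). Includes
    energy-dependent attenuation of alloys and tissue surrogates via the
    weight-fraction mixture rule, a voxelized hip-stem phantom with
    hydroxyapatite calibration pellets in Gruen zones, a polychromatic
    parallel-beam CT simulator with beam hardening, photon starvation and
    Poisson noise, image-domain two-material basis decomposition with
    virtual monochromatic spectral (VMS) synthesis at 40-190 keV, and the
    measurement stack: Hounsfield-interval artifact volumetry with
    prosthesis subtraction, pellet ROI density and deviation statistics,
    signal-to-noise ratios and paired comparisons of monochromatic versus
    polychromatic images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
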