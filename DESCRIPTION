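Package: fibrilsans
Title: Small-Angle Neutron Scattering Analysis of Wood Cell-Wall Nanostructure
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reduction and model-based analysis of small-angle neutron
    scattering (SANS) data from plant cell walls undergoing fungal or
    chemical deconstruction. Converts 2D detector frames into aligned,
    amorphous and isotropic 1D profiles via anisotropic sector averaging,
    fits a composite empirical model (low-q power law, mid-q unified
    Beaucage level, Gaussian diffraction peak) by weighted least squares,
    derives elementary-fibril spacing from the diffraction peak position
    (d = 2*pi/q0), and estimates parameter uncertainties by chi-square
    profiling. Includes a seeded synthetic-data generator producing
    ground-truth-labelled detector frames and profiles for end-to-end
    validation of the pipeline without any instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
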