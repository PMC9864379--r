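Package: dmsofold
Title: Two-State Analysis of DMSO-Induced Protein Unfolding from NMR and
    DSC Data
Version: 0.1.0
Authors@R:
    person("Gyula", "Fekete", email = "dmsofold@protonmail.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for solvent-induced (DMSO) chemical
    unfolding of small disulfide proteins followed by NMR and differential
    scanning calorimetry.  Converts raw dual-delay HSQC peak-volume
    titrations into viscosity-, dilution- and calibration-corrected
    relative intensities, fits them to a two-state unfolding model to
    extract the m-value, unfolding midpoint and standard free energy of
    unfolding, analyses backbone 15N relaxation data (Lipari-Szabo
    model-free fitting, reduced spectral density mapping, R1*R2 exchange
    screening), extracts melting temperatures from DSC thermograms and
    fits their parabolic dependence on DMSO content.  Seeded synthetic
    data generators for all three data types close the test loop without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
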