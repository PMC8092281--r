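Package: msring
Title: Symmetry-Mismatched Ring Modelling of the Flagellar MS-Ring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid modelling toolkit for cyclic-symmetry protein ring
    assemblies, built around the procedure used to model the periplasmic
    region of the bacterial flagellar MS-ring. Provides an atomic-structure
    data model with PDB/mmCIF input and output, Kabsch superposition and
    cyclic (Cn) symmetry operators, ring construction and resymmetrization,
    density-map simulation, rotational power spectra and symmetry detection
    on MRC/CCP4 maps, rigid-body and hinge fitting of models into density,
    a pipeline that rebuilds the 23 + 11 = 34 subunit two-conformation
    M-ring architecture from a two-domain subunit and template double
    rings, and a validation report (clashes, crosslink distances, tier
    diameters, linker reach, collar strand count). A synthetic-data module
    generates toy subunits, planted rings and noisy maps so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
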