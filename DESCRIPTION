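Package: callusmap
Title: Mechanoregulated Simulation of Secondary Fracture Healing and
    Fixation-Stiffness Characteristic Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Iterative finite-element simulation of secondary bone healing
    in an idealized ovine tibial osteotomy. A linear-elastic hexahedral
    finite-element model of the fractured diaphysis, stabilized by axial and
    translational-shear fixation springs, is solved daily under superimposed
    physiological loading; per-element distortional and dilatational strains
    drive a deterministic tissue-differentiation rule engine (intramembranous
    ossification, chondrogenesis, endochondral ossification,
    revascularization, tissue destruction) with maturation of the initial
    connective tissue. Virtual cantilever bending tests, callus volume and
    callus index quantify healing outcome. A sweep pipeline builds
    characteristic maps of healing outcome versus fixation stiffness,
    classifies qualitative healing regions and compares the maps against a
    packaged table of in-vivo fixation-stiffness literature data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    pracma,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
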