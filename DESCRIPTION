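Package: dryskull
Title: Dry-Skull Bite-Force Estimation and Muscle-Constrained Gape Modelling
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the dry-skull inference chain used in vertebrate
    comparative biomechanics: from reconstructed jaw-adductor muscle geometry
    (volumes, lengths, sagittal and coronal insertion angles, lever arms) to
    muscle contraction forces, resultant forces on the mandible, per-bite-point
    bite forces and mechanical advantage. Also models jaw opening as rigid
    rotation about the jaw-joint axis to locate the gape angles at which
    straight-cylinder muscle proxies reach the optimal-tension (130% of resting
    length) and maximum-tension (170%) strain limits. Includes closed-mesh
    volumetrics (OBJ/PLY), 3D insertion-angle and lever measurement from
    landmarks, a deterministic synthetic jaw generator for round-trip testing,
    and published oviraptorosaur measurement tables as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
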